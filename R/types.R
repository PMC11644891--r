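#' Uniformly sampled signal trace
#'
#' Container for a uniformly sampled amplitude or temperature series.
#'
#' @param samples Numeric vector of finite samples (may be empty).
#' @param fs Sampling rate in Hz (> 0).
#' @return Object of class `signal_trace` with fields `samples` and `fs`.
#' @export
signal_trace <- function(samples, fs) {
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("`fs` must be a single positive number")
  samples <- as.numeric(samples)
  if (length(samples) && !all(is.finite(samples)))
    stop("`samples` must be finite")
  structure(list(samples = samples, fs = as.numeric(fs)),
            class = "signal_trace")
}

#' @export
print.signal_trace <- function(x, ...) {
  cat(sprintf("<signal_trace> %d samples at %g Hz (%.2f s)\n",
              length(x$samples), x$fs,
              if (x$fs > 0) length(x$samples) / x$fs else NA_real_))
  invisible(x)
}

#' @export
length.signal_trace <- function(x) length(x$samples)

#' Detected beat annotation
#'
#' Beat times with the derived inter-beat intervals (IBI) and per-beat rate.
#'
#' @param beat_times Strictly increasing beat times in ms from trace start.
#' @param diagnostics Optional named list of detector counters.
#' @return Object of class `beat_annotation` with fields `beat_times` (ms),
#'   `ibi` (ms, successive differences) and `bpm` (`60000/ibi`).
#' @export
beat_annotation <- function(beat_times, diagnostics = list()) {
  beat_times <- as.numeric(beat_times)
  if (length(beat_times) > 1L && any(diff(beat_times) <= 0))
    stop("`beat_times` must be strictly increasing")
  ibi <- diff(beat_times)
  structure(list(beat_times = beat_times, ibi = ibi, bpm = 60000 / ibi,
                 diagnostics = diagnostics),
            class = "beat_annotation")
}

#' @export
print.beat_annotation <- function(x, ...) {
  cat(sprintf("<beat_annotation> %d beats", length(x$beat_times)))
  if (length(x$ibi))
    cat(sprintf(", mean IBI %.1f ms (%.1f bpm)",
                mean(x$ibi), 60000 / mean(x$ibi)))
  cat("\n")
  invisible(x)
}

# evaluate an expression under a temporary RNG state seeded with `seed`,
# restoring the caller's state afterwards
with_local_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}
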