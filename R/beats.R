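#' Detector state / tuning parameters
#'
#' Thresholding and timing parameters of the adaptive two-threshold beat
#' classifier.  `I1` is the primary acceptance threshold, `I2 = I1/2` the
#' lowered searchback threshold; both adapt from running signal-peak (SPK)
#' and noise-peak (NPK) estimates, `est <- 0.125 * peak + 0.875 * est`,
#' `I1 = NPK + 0.25 (SPK - NPK)`.
#'
#' @param init_rr Initial running RR estimate in ms, used until 2 beats have
#'   been accepted.
#' @param refractory_ms Absolute refractory period: of two candidate peaks
#'   closer than this, only the larger survives.
#' @param twave_window_ms Window after an accepted beat in which a candidate
#'   with less than half the beat's amplitude is rejected as a
#'   T-wave-like after-deflection.
#' @param searchback_factor A searchback with threshold `I2` is triggered
#'   when no beat is found within `searchback_factor * rr_avg`.
#' @param rise_blank_frac Post-beat rise-tracking blanking window as a
#'   fraction of `rr_avg`: sub-beat-amplitude candidates inside it are
#'   ignored outright (they track the rising edge, not noise).
#' @param learn_s Length of the initial segment (s) used to seed SPK/NPK.
#' @return Object of class `detector_state`.
#' @export
detector_state <- function(init_rr = 800, refractory_ms = 200,
                           twave_window_ms = 360, searchback_factor = 1.5,
                           rise_blank_frac = 0.6, learn_s = 2) {
  structure(list(init_rr = init_rr, refractory_ms = refractory_ms,
                 twave_window_ms = twave_window_ms,
                 searchback_factor = searchback_factor,
                 rise_blank_frac = rise_blank_frac, learn_s = learn_s),
            class = "detector_state")
}

# local maxima of x; plateaus (runs of near-equal values, relative
# tolerance) are collapsed to their centre sample
local_peaks <- function(x, rel_tol = 1e-9) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  scale <- max(abs(x), 1e-300)
  tol <- rel_tol * scale
  up <- diff(x) > tol
  dn <- diff(x) < -tol
  # a peak plateau starts after the last rise and ends before the next fall
  peaks <- integer(0)
  last_rise <- NA_integer_
  for (i in seq_len(n - 1L)) {
    if (up[i]) last_rise <- i + 1L
    else if (dn[i] && !is.na(last_rise)) {
      peaks <- c(peaks, as.integer(round((last_rise + i) / 2)))
      last_rise <- NA_integer_
    }
  }
  peaks[x[peaks] > tol]
}

#' Detect beats in the integrated slope-energy envelope
#'
#' Classifies the candidate peaks of the [pulse_chain()] output by the
#' five-rule adaptive scheme: (1) only the larger of two peaks within the
#' 200 ms refractory window survives; (2) an excess of candidate peaks over
#' accepted beats is flagged as suspected baseline-drift artifact (logged,
#' not transformed); (3) a peak within 360 ms of the previous beat with
#' amplitude below half that beat's is rejected as a T-wave-like
#' after-deflection; (4) peaks at or above the adaptive threshold `I1` are
#' accepted as beats, others counted as noise; (5) if no beat is found
#' within 1.5 times the running RR average, the largest rejected peak more
#' than 360 ms after the last beat that clears the lowered threshold `I2`
#' is accepted by searchback.  Beat times are mapped back to trace time by
#' subtracting the chain's analytic group delay.
#'
#' @param x Numeric vector or [signal_trace()]: the output of
#'   [pulse_chain()] (integrated slope energy).
#' @param fs Sampling rate in Hz (taken from `x` if it is a trace).
#' @param state A [detector_state()].
#' @param n_window Integration window length used in the chain (for delay
#'   compensation).
#' @param compensate_delay Subtract the chain group delay from beat times.
#' @return A [beat_annotation()]; its `diagnostics` field counts peaks
#'   handled by each rule.
#' @export
detect_beats <- function(x, fs = 200, state = detector_state(),
                         n_window = 30L, compensate_delay = TRUE) {
  if (inherits(x, "signal_trace")) { fs <- x$fs; x <- x$samples }
  x <- as.numeric(x)
  if (length(x) < n_window) {
    warning("trace shorter than one integration window; no beats detected")
    return(beat_annotation(numeric(0)))
  }
  ms_per <- 1000 / fs
  pk_idx <- local_peaks(x)
  diag <- list(candidates = length(pk_idx), rule1_suppressed = 0L,
               twave_rejected = 0L, noise_peaks = 0L,
               searchback_accepted = 0L, blanked = 0L,
               baseline_artifact_flag = FALSE)
  if (!length(pk_idx)) return(beat_annotation(numeric(0), diag))
  pk_t <- (pk_idx - 1L) * ms_per
  pk_a <- x[pk_idx]

  # rule 1: suppress peaks within the refractory window of a larger peak
  keep <- rep(TRUE, length(pk_idx))
  for (i in seq_along(pk_idx)) {
    near <- which(abs(pk_t - pk_t[i]) <= state$refractory_ms & seq_along(pk_t) != i)
    if (any(pk_a[near] > pk_a[i] |
            (pk_a[near] == pk_a[i] & near < i)))
      keep[i] <- FALSE
  }
  diag$rule1_suppressed <- sum(!keep)
  pk_t <- pk_t[keep]; pk_a <- pk_a[keep]

  # seed thresholds from the learning segment (beats there are still scored)
  li <- x[seq_len(min(length(x), round(state$learn_s * fs)))]
  spk <- max(li); npk <- mean(li)
  if (spk <= 0) return(beat_annotation(numeric(0), diag))
  thr <- function() npk + 0.25 * (spk - npk)

  beats_t <- numeric(0); beats_a <- numeric(0)
  rej_t <- numeric(0); rej_a <- numeric(0)   # searchback candidates
  ibis <- numeric(0)
  rr_avg <- state$init_rr

  accept <- function(tt, aa) {
    if (length(beats_t)) {
      ibis <<- c(ibis, tt - beats_t[length(beats_t)])
      if (length(ibis) > 8L) ibis <<- ibis[(length(ibis) - 7L):length(ibis)]
      rr_avg <<- mean(ibis)
    }
    beats_t <<- c(beats_t, tt); beats_a <<- c(beats_a, aa)
    spk <<- 0.125 * aa + 0.875 * spk
  }

  for (i in seq_along(pk_t)) {
    tt <- pk_t[i]; aa <- pk_a[i]
    last_t <- if (length(beats_t)) beats_t[length(beats_t)] else -Inf
    last_a <- if (length(beats_a)) beats_a[length(beats_a)] else Inf

    # rule 5: searchback over rejected peaks if the expected beat is overdue
    if (is.finite(last_t) && tt - last_t > state$searchback_factor * rr_avg) {
      win <- which(rej_t > last_t + state$twave_window_ms & rej_t < tt &
                     rej_a >= thr() / 2)
      if (length(win)) {
        j <- win[which.max(rej_a[win])]
        accept(rej_t[j], rej_a[j])
        diag$searchback_accepted <- diag$searchback_accepted + 1L
        last_t <- beats_t[length(beats_t)]
        last_a <- beats_a[length(beats_a)]
      }
    }

    dt <- tt - last_t
    if (dt < state$refractory_ms) next
    if (dt < state$rise_blank_frac * rr_avg && aa < last_a) {
      # rule 3 inside the blanking window; other sub-beat peaks are
      # rise-tracking artifacts and are ignored outright
      if (dt < state$twave_window_ms && aa < 0.5 * last_a)
        diag$twave_rejected <- diag$twave_rejected + 1L
      else diag$blanked <- diag$blanked + 1L
      next
    }
    if (dt < state$twave_window_ms && aa < 0.5 * last_a) {
      diag$twave_rejected <- diag$twave_rejected + 1L
      npk <- 0.125 * aa + 0.875 * npk
      next
    }
    if (aa >= thr()) {
      accept(tt, aa)
    } else {
      npk <- 0.125 * aa + 0.875 * npk
      diag$noise_peaks <- diag$noise_peaks + 1L
      rej_t <- c(rej_t, tt); rej_a <- c(rej_a, aa)
    }
  }

  # trailing searchback: expected beat overdue at end of record
  end_t <- (length(x) - 1L) * ms_per
  if (length(beats_t) &&
      end_t - beats_t[length(beats_t)] > state$searchback_factor * rr_avg) {
    last_t <- beats_t[length(beats_t)]
    win <- which(rej_t > last_t + state$twave_window_ms & rej_a >= thr() / 2)
    if (length(win)) {
      j <- win[which.max(rej_a[win])]
      accept(rej_t[j], rej_a[j])
      diag$searchback_accepted <- diag$searchback_accepted + 1L
    }
  }

  # rule 2 diagnostic: many more candidates than beats suggests baseline
  # drift artifacts upstream
  diag$baseline_artifact_flag <-
    diag$candidates > 2L * max(1L, length(beats_t))

  delay <- if (compensate_delay)
    chain_group_delay(fs, n_window)$total else 0
  beat_annotation(beats_t - delay, diag)
}

#' Extract beats from a raw pulse-wave trace
#'
#' The full preprocessing path: resample to the 200 Hz filter design rate
#' (polyphase resampling), optionally wavelet-denoise, run the
#' low-pass/high-pass/derivative/square/integrate chain and the adaptive
#' peak classifier, and compensate the chain group delay.
#'
#' @param trace A [signal_trace()].
#' @param denoise Apply [wt_denoise()] before the chain (default `TRUE`).
#' @param plan [wavelet_plan()] used when `denoise = TRUE`.
#' @param n_window Integration window length at 200 Hz.
#' @param state A [detector_state()].
#' @return A [beat_annotation()] with times in ms of the original trace.
#' @export
extract_beats <- function(trace, denoise = TRUE, plan = wavelet_plan(),
                          n_window = 30L, state = detector_state()) {
  stopifnot(inherits(trace, "signal_trace"))
  x <- resample_trace(trace, 200)
  if (denoise) x <- signal_trace(wt_denoise(x, plan), 200)
  env <- pulse_chain(x$samples, n_window = n_window)
  detect_beats(env, fs = 200, state = state, n_window = n_window)
}

#' Resample a trace to a target rate
#'
#' Rational-factor polyphase resampling (via the signal package); identity
#' when the rates already match.
#'
#' @param trace A [signal_trace()].
#' @param fs_out Target sampling rate in Hz.
#' @return A [signal_trace()] at `fs_out`.
#' @export
resample_trace <- function(trace, fs_out = 200) {
  stopifnot(inherits(trace, "signal_trace"))
  if (trace$fs == fs_out) return(trace)
  fr <- as.integer(round(trace$fs * 1000)); fo <- as.integer(round(fs_out * 1000))
  g <- gcd_int(fr, fo)
  p <- fo %/% g; q <- fr %/% g
  y <- signal::resample(trace$samples, p, q)
  signal_trace(as.numeric(y), fs_out)
}

gcd_int <- function(a, b) if (b == 0L) a else gcd_int(b, a %% b)

#' Score detected beats against ground truth
#'
#' Greedy one-to-one matching of detected beat times to true beat times
#' within a tolerance window; reports sensitivity (true beats found),
#' positive predictivity (detections that are true) and F1.
#'
#' @param detected Numeric vector of detected beat times (ms) or a
#'   [beat_annotation()].
#' @param truth Numeric vector of true beat times in ms.
#' @param tol_ms Matching tolerance in ms.
#' @return Named list: `tp`, `fn`, `fp`, `sensitivity`, `ppv`, `f1`.
#' @export
score_beats <- function(detected, truth, tol_ms = 100) {
  if (inherits(detected, "beat_annotation")) detected <- detected$beat_times
  used <- rep(FALSE, length(detected))
  tp <- 0L
  for (bt in truth) {
    d <- abs(detected - bt)
    d[used] <- Inf
    if (length(d) && min(d) <= tol_ms) {
      used[which.min(d)] <- TRUE
      tp <- tp + 1L
    }
  }
  fn <- length(truth) - tp
  fp <- length(detected) - tp
  sens <- if (length(truth)) tp / length(truth) else NA_real_
  ppv <- if (length(detected)) tp / length(detected) else NA_real_
  f1 <- if (isTRUE(sens + ppv > 0)) 2 * sens * ppv / (sens + ppv) else 0
  list(tp = tp, fn = fn, fp = fp, sensitivity = sens, ppv = ppv, f1 = f1)
}
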