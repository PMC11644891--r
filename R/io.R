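# CSV / JSON / serial-text interfaces

#' Write / read a signal trace as 2-column CSV
#'
#' Column layout `time_s,value`; the sampling rate is recovered from the
#' median spacing of the time column on read.
#'
#' @param trace A [signal_trace()].
#' @param path File path.
#' @return `write_trace` returns `path` invisibly; `read_trace` returns a
#'   [signal_trace()].
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "signal_trace"))
  t <- (seq_along(trace$samples) - 1L) / trace$fs
  utils::write.csv(data.frame(time_s = t, value = trace$samples),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop("trace file not found: ", path)
  d <- utils::read.csv(path)
  if (!all(c("time_s", "value") %in% names(d)))
    stop("expected columns time_s,value in ", path)
  if (nrow(d) < 2L) stop("trace file has fewer than 2 samples")
  fs <- 1 / stats::median(diff(d$time_s))
  signal_trace(d$value, fs)
}

#' Write / read a beat annotation as CSV
#'
#' Columns `beat_time_ms,ibi_ms,bpm` (interval columns are `NA` for the
#' first beat).
#'
#' @param ann A [beat_annotation()].
#' @param path File path.
#' @export
write_beats <- function(ann, path) {
  stopifnot(inherits(ann, "beat_annotation"))
  utils::write.csv(data.frame(beat_time_ms = ann$beat_times,
                              ibi_ms = c(NA, ann$ibi),
                              bpm = c(NA, ann$bpm)),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_beats
#' @export
read_beats <- function(path) {
  if (!file.exists(path)) stop("beat file not found: ", path)
  beat_annotation(utils::read.csv(path)$beat_time_ms)
}

#' Write / read a labeled feature cohort as CSV
#'
#' Header `HR,MR,SDNN,RMSSD,pNN50,CV,TO,label`; an optional `split` column
#' (`train`/`test`) carries the partition.
#'
#' @param cohort A [labeled_cohort()].
#' @param path File path.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "labeled_cohort"))
  d <- as.data.frame(cohort$features)
  d$label <- cohort$labels
  d$split <- ifelse(seq_len(nrow(d)) %in% cohort$train_idx, "train", "test")
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  d <- utils::read.csv(path, check.names = FALSE)
  need <- c(feature_names(), "label")
  if (!all(need %in% names(d)))
    stop("expected columns ", paste(need, collapse = ","), " in ", path)
  if ("split" %in% names(d)) {
    tr <- which(d$split == "train"); te <- which(d$split == "test")
  } else {
    tr <- seq_len(nrow(d)); te <- integer(0)
  }
  labeled_cohort(as.matrix(d[feature_names()]), d$label, tr, te)
}

#' Parse the S/B/Q serial text stream
#'
#' The acquisition firmware emits newline-delimited ASCII records, a
#' one-letter prefix followed by a decimal integer: `S` pulse-wave samples,
#' `B` per-beat pressure/BPM values, `Q` inter-beat intervals (ms).
#' Malformed lines are skipped with a counted warning.
#'
#' @param lines Character vector of serial lines.
#' @param fs Sampling rate of the `S` samples in Hz.
#' @return List with `trace` (a [signal_trace()] from the S records), `ibi`
#'   (numeric, Q records), `bpm` (numeric, B records) and `n_skipped`.
#' @export
parse_serial_stream <- function(lines, fs = 500) {
  lines <- trimws(as.character(lines))
  lines <- lines[nzchar(lines)]
  ok <- grepl("^[SBQ]-?[0-9]+$", lines)
  if (!any(ok)) stop("no parseable serial records in stream")
  n_skipped <- sum(!ok)
  if (n_skipped)
    warning(sprintf("skipped %d malformed serial line(s)", n_skipped))
  lines <- lines[ok]
  prefix <- substr(lines, 1L, 1L)
  value <- as.numeric(substring(lines, 2L))
  list(trace = signal_trace(value[prefix == "S"], fs),
       ibi = value[prefix == "Q"],
       bpm = value[prefix == "B"],
       n_skipped = n_skipped)
}

#' Serialize to the S/B/Q protocol
#'
#' Emits S records (pulse-wave samples, rounded to integers as on the
#' wire), then B, then Q; the per-prefix sequences round-trip through
#' [parse_serial_stream()].
#'
#' @param parsed List with elements `trace` (or `samples`), `bpm`, `ibi` as
#'   returned by [parse_serial_stream()].
#' @return Character vector of serial lines.
#' @export
write_serial <- function(parsed) {
  s <- if (inherits(parsed$trace, "signal_trace")) parsed$trace$samples
       else parsed$samples
  c(if (length(s)) paste0("S", format(round(s), scientific = FALSE, trim = TRUE)),
    if (length(parsed$bpm)) paste0("B", format(round(parsed$bpm), scientific = FALSE, trim = TRUE)),
    if (length(parsed$ibi)) paste0("Q", format(round(parsed$ibi), scientific = FALSE, trim = TRUE)))
}
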