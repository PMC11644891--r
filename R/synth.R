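#' Pulse-wave simulation configuration
#'
#' Parameters of the synthetic pulse-wave generator.  Defaults emulate a
#' wearable photoplethysmography recording from a transported animal at the
#' acquisition rate of 500 Hz: Gaussian pulse templates on a slow baseline
#' drift (motion/respiration), 50 Hz power-line interference, white sensor
#' noise and an optional low secondary bump 300 ms after each beat that
#' plays the role of a T-wave-like after-deflection.
#'
#' @param fs Sampling rate in Hz.
#' @param duration Record length in seconds.
#' @param beat_rate_bpm Mean beat rate in beats/min.
#' @param hrv_sd Standard deviation of the beat-interval jitter in ms.
#' @param pulse_amp Amplitude of the pulse template (arbitrary units).
#' @param pulse_width Gaussian width (sigma) of the pulse template, seconds.
#' @param baseline_amp,baseline_freq Amplitude and frequency (Hz) of the
#'   sinusoidal baseline drift.
#' @param powerline_amp,powerline_freq Amplitude and frequency (Hz) of the
#'   power-line interference.
#' @param noise_sd Standard deviation of additive white noise.
#' @param twave_frac Relative amplitude (in `[0, 1)`) of the secondary bump
#'   placed 300 ms after each beat; 0 disables it.
#' @param seed RNG seed.
#' @return Object of class `pulse_sim_config`.
#' @export
pulse_sim_config <- function(fs = 500, duration = 60, beat_rate_bpm = 80,
                             hrv_sd = 30, pulse_amp = 1, pulse_width = 0.03,
                             baseline_amp = 0.3, baseline_freq = 0.25,
                             powerline_amp = 0.1, powerline_freq = 50,
                             noise_sd = 0.05, twave_frac = 0.2, seed = 1L) {
  num1 <- function(v, nm, lo = -Inf) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < lo)
      stop(sprintf("`%s` must be a single finite number%s", nm,
                   if (is.finite(lo)) sprintf(" >= %g", lo) else ""))
    as.numeric(v)
  }
  cfg <- list(
    fs = num1(fs, "fs"), duration = num1(duration, "duration"),
    beat_rate_bpm = num1(beat_rate_bpm, "beat_rate_bpm"),
    hrv_sd = num1(hrv_sd, "hrv_sd", 0),
    pulse_amp = num1(pulse_amp, "pulse_amp", 0),
    pulse_width = num1(pulse_width, "pulse_width"),
    baseline_amp = num1(baseline_amp, "baseline_amp", 0),
    baseline_freq = num1(baseline_freq, "baseline_freq", 0),
    powerline_amp = num1(powerline_amp, "powerline_amp", 0),
    powerline_freq = num1(powerline_freq, "powerline_freq", 0),
    noise_sd = num1(noise_sd, "noise_sd", 0),
    twave_frac = num1(twave_frac, "twave_frac", 0),
    seed = as.integer(seed))
  if (cfg$fs <= 0 || cfg$duration <= 0)
    stop("`fs` and `duration` must be positive")
  if (cfg$beat_rate_bpm <= 0) stop("`beat_rate_bpm` must be positive")
  if (cfg$pulse_width <= 0) stop("`pulse_width` must be positive")
  if (cfg$twave_frac >= 1) stop("`twave_frac` must be in [0, 1)")
  structure(cfg, class = "pulse_sim_config")
}

#' Simulate a pulse-wave trace with known beat times
#'
#' Schedules beats from the mean rate with Gaussian interval jitter
#' (intervals floored at 300 ms), places one Gaussian pulse template per
#' beat (plus the optional secondary bump), and adds baseline drift,
#' power-line interference and white noise.  Identical seeds give
#' bitwise-identical output.
#'
#' @param cfg A [pulse_sim_config()].
#' @return List with `trace` (a [signal_trace()]) and `truth` (list with
#'   `beat_times` in ms, strictly increasing).
#' @export
simulate_pulse_wave <- function(cfg = pulse_sim_config()) {
  if (!inherits(cfg, "pulse_sim_config")) stop("`cfg` must be a pulse_sim_config")
  with_local_seed(cfg$seed, {
    n <- round(cfg$fs * cfg$duration)
    t <- (seq_len(n) - 1L) / cfg$fs            # seconds
    mean_ibi <- 60000 / cfg$beat_rate_bpm      # ms
    # schedule beats; first beat 1 s in, stop half a mean interval early
    bt <- 1000
    repeat {
      nxt <- bt[length(bt)] + max(300, stats::rnorm(1, mean_ibi, cfg$hrv_sd))
      if (nxt > cfg$duration * 1000 - mean_ibi / 2) break
      bt <- c(bt, nxt)
    }
    x <- numeric(n)
    add_bump <- function(x, centre_ms, amp, width_s) {
      if (amp == 0) return(x)
      c0 <- centre_ms / 1000
      i <- which(t >= c0 - 4 * width_s & t <= c0 + 4 * width_s)
      x[i] <- x[i] + amp * exp(-(t[i] - c0)^2 / (2 * width_s^2))
      x
    }
    for (b in bt) {
      x <- add_bump(x, b, cfg$pulse_amp, cfg$pulse_width)
      if (cfg$twave_frac > 0)
        x <- add_bump(x, b + 300, cfg$twave_frac * cfg$pulse_amp,
                      1.6 * cfg$pulse_width)
    }
    if (cfg$baseline_amp > 0)
      x <- x + cfg$baseline_amp * sin(2 * pi * cfg$baseline_freq * t)
    if (cfg$powerline_amp > 0)
      x <- x + cfg$powerline_amp * sin(2 * pi * cfg$powerline_freq * t)
    if (cfg$noise_sd > 0)
      x <- x + stats::rnorm(n, 0, cfg$noise_sd)
    list(trace = signal_trace(x, cfg$fs), truth = list(beat_times = bt))
  })
}

#' Three-level stress class model for cohort simulation
#'
#' Per-level Gaussian models for the physiological latents from which a
#' feature record derives: the mean inter-beat interval `MR` (ms), the
#' interval variability `SDNN` (ms) and the body temperature `TO` (deg C).
#' The remaining four features are deterministic functions of the latents,
#' exactly as they are for a record computed from a detected interval
#' series with white interval jitter: `HR = 60000/MR`,
#' `RMSSD = sqrt(2) * SDNN`, `pNN50 = 200 * (1 - pnorm(50/(sqrt(2)*SDNN)))`
#' and `CV = SDNN/MR`.
#'
#' The defaults encode the expected physiology: the comfort level (1) has a
#' low heart rate (75 beats/min, MR 800 ms) and temperature with high
#' beat-to-beat variability; the overt stress level (2) an elevated heart
#' rate (110 beats/min) and temperature with depressed variability; the
#' intermediate level (3) sits midway with doubled spreads, making it the
#' hardest level to grade.  Default counts are 65 animals per level
#' (195 total) with a held-out test composition of 18/11/30.
#'
#' @param means,sds Named list with elements `"1"`, `"2"`, `"3"`, each a
#'   named numeric vector with entries `MR`, `SDNN`, `TO` (additional named
#'   entries are ignored by the generator).
#' @param class_counts Integer vector of records per level.
#' @param test_counts Integer vector of held-out records per level (must be
#'   elementwise smaller than `class_counts`).
#' @return Object of class `stress_class_model`.
#' @export
stress_class_model <- function(means = NULL, sds = NULL,
                               class_counts = c(65L, 65L, 65L),
                               test_counts = c(18L, 11L, 30L)) {
  if (is.null(means))
    means <- list(
      "1" = c(MR = 800,   SDNN = 60,   TO = 38.5),
      "2" = c(MR = 545.5, SDNN = 25,   TO = 39.8),
      "3" = c(MR = 672.7, SDNN = 42.5, TO = 39.15))
  if (is.null(sds))
    sds <- list(
      "1" = c(MR = 53, SDNN = 10, TO = 0.3),
      "2" = c(MR = 40, SDNN = 8,  TO = 0.4),
      "3" = c(MR = 93, SDNN = 18, TO = 0.7))
  need <- c("MR", "SDNN", "TO")
  for (lv in c("1", "2", "3")) {
    if (!all(need %in% names(means[[lv]])) || !all(need %in% names(sds[[lv]])))
      stop("means and sds must have named entries MR, SDNN, TO per level")
    if (any(sds[[lv]][need] <= 0)) stop("all SDs must be positive")
  }
  class_counts <- as.integer(class_counts)
  test_counts <- as.integer(test_counts)
  if (length(class_counts) != 3L || any(class_counts < 1L))
    stop("`class_counts` must be three counts >= 1")
  if (length(test_counts) != 3L || any(test_counts < 1L) ||
      any(test_counts >= class_counts))
    stop("`test_counts` must leave at least one training record per level")
  structure(list(means = means, sds = sds, class_counts = class_counts,
                 test_counts = test_counts),
            class = "stress_class_model")
}

feature_names <- function()
  c("HR", "MR", "SDNN", "RMSSD", "pNN50", "CV", "TO")

#' Simulate a body-temperature trace for a stress level
#'
#' Draws a temperature series (deg C, 1 Hz by default) around the level's
#' configured TO mean.
#'
#' @param level Stress level 1, 2 or 3.
#' @param n Number of samples (>= 0).
#' @param seed RNG seed.
#' @param model A [stress_class_model()] supplying the level's TO mean/SD.
#' @param fs Sampling rate in Hz.
#' @param sd Optional override of the level's TO standard deviation.
#' @return A [signal_trace()] in deg C.
#' @export
simulate_temperature <- function(level, n, seed = 1L,
                                 model = stress_class_model(), fs = 1,
                                 sd = NULL) {
  if (!level %in% 1:3) stop("unknown stress level; must be 1, 2 or 3")
  n <- as.integer(n)
  if (is.na(n) || n < 0L) stop("`n` must be a non-negative integer")
  lv <- as.character(level)
  mu <- model$means[[lv]][["TO"]]
  s <- if (is.null(sd)) model$sds[[lv]][["TO"]] else sd
  x <- if (n == 0L) numeric(0) else
    with_local_seed(seed, if (s == 0) rep(mu, n) else stats::rnorm(n, mu, s))
  signal_trace(x, fs)
}

#' Simulate a labeled feature cohort
#'
#' Draws, per animal, the physiological latents (MR, SDNN, TO) from the
#' per-level Gaussian class model (MR floored at 250 ms, SDNN at 1 ms),
#' derives the remaining four features through the identities a
#' signal-derived record obeys (see [stress_class_model()]), and attaches a
#' stratified train/test split.  With the default model this yields 195
#' records split 136/59 with a test composition of 18/11/30 across the
#' three levels.
#'
#' @param model A [stress_class_model()].
#' @param seed RNG seed.
#' @return Object of class `labeled_cohort`: list with `features`
#'   (n x 7 matrix), `labels` (integer vector in 1..3), `train_idx`,
#'   `test_idx`.
#' @export
simulate_cohort <- function(model = stress_class_model(), seed = 1L) {
  stopifnot(inherits(model, "stress_class_model"))
  with_local_seed(seed, {
    feats <- list(); labels <- integer(0)
    for (lv in 1:3) {
      k <- model$class_counts[lv]
      mu <- model$means[[as.character(lv)]]
      s <- model$sds[[as.character(lv)]]
      mr <- pmax(stats::rnorm(k, mu[["MR"]], s[["MR"]]), 250)
      sdnn <- pmax(stats::rnorm(k, mu[["SDNN"]], s[["SDNN"]]), 1)
      to <- stats::rnorm(k, mu[["TO"]], s[["TO"]])
      m <- cbind(HR = 60000 / mr, MR = mr, SDNN = sdnn,
                 RMSSD = sqrt(2) * sdnn,
                 pNN50 = 200 * (1 - stats::pnorm(50 / (sqrt(2) * sdnn))),
                 CV = sdnn / mr, TO = to)
      feats[[lv]] <- m
      labels <- c(labels, rep(lv, k))
    }
    features <- do.call(rbind, feats)
    test_idx <- integer(0)
    for (lv in 1:3) {
      rows <- which(labels == lv)
      test_idx <- c(test_idx, sample(rows, model$test_counts[lv]))
    }
    test_idx <- sort(test_idx)
    train_idx <- setdiff(seq_along(labels), test_idx)
    labeled_cohort(features, labels, train_idx, test_idx)
  })
}

#' Labeled cohort container
#'
#' @param features n x 7 numeric matrix (columns HR, MR, SDNN, RMSSD, pNN50,
#'   CV, TO).
#' @param labels Integer labels in 1..3, one per row.
#' @param train_idx,test_idx Disjoint, exhaustive row index sets.
#' @return Object of class `labeled_cohort`.
#' @export
labeled_cohort <- function(features, labels, train_idx, test_idx) {
  features <- as.matrix(features)
  labels <- as.integer(labels)
  if (nrow(features) != length(labels))
    stop("rows(features) must equal length(labels)")
  if (!all(labels %in% 1:3)) stop("labels must be in {1, 2, 3}")
  train_idx <- sort(as.integer(train_idx)); test_idx <- sort(as.integer(test_idx))
  if (length(intersect(train_idx, test_idx)) ||
      !setequal(c(train_idx, test_idx), seq_along(labels)))
    stop("split must be disjoint and exhaustive")
  for (ix in list(train_idx, test_idx))
    if (any(tabulate(labels[ix], 3L) == 0L))
      stop("degenerate split: a stress level is absent from train or test")
  structure(list(features = features, labels = labels,
                 train_idx = train_idx, test_idx = test_idx),
            class = "labeled_cohort")
}

#' @export
print.labeled_cohort <- function(x, ...) {
  cat(sprintf("<labeled_cohort> %d records (train %d / test %d), levels: %s\n",
              nrow(x$features), length(x$train_idx), length(x$test_idx),
              paste(tabulate(x$labels, 3L), collapse = "/")))
  invisible(x)
}
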