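#' Sample mean estimator
#'
#' \eqn{\hat m = \frac{1}{N}\sum_i x_i}.
#'
#' @param x Non-empty numeric vector.
#' @return The mean.
#' @export
estimate_mean <- function(x) {
  if (!is.numeric(x) || length(x) < 1L) stop("`x` must be a non-empty numeric vector")
  sum(x) / length(x)
}

#' Biased (1/N) variance estimator
#'
#' \eqn{\hat\sigma^2 = \frac{1}{N}\sum_i (x_i - \bar x)^2}; equals
#' `(n-1)/n * var(x)`.  Kept deliberately in the 1/N form; the HRV feature
#' SDNN uses the conventional `n-1` denominator instead (see
#' [hrv_features()]).
#'
#' @inheritParams estimate_mean
#' @return The biased variance.
#' @export
estimate_variance <- function(x) {
  if (!is.numeric(x) || length(x) < 1L) stop("`x` must be a non-empty numeric vector")
  m <- sum(x) / length(x)
  sum((x - m)^2) / length(x)
}

#' Time-domain heart-rate-variability features
#'
#' Computes the six HRV features from an inter-beat-interval series (ms):
#' `MR` mean interval, `HR = 60000/MR` beats/min, `SDNN` the sample SD
#' (`n-1` denominator), `RMSSD` the root mean square of successive
#' differences, `pNN50` the percentage of successive differences strictly
#' exceeding 50 ms, and `CV = SDNN/MR`.
#'
#' @param ibi Numeric vector of at least 2 inter-beat intervals in ms, all
#'   positive.
#' @return Named numeric vector with elements HR, MR, SDNN, RMSSD, pNN50, CV.
#' @export
#' @examples
#' hrv_features(c(800, 900, 800, 900))
hrv_features <- function(ibi) {
  if (!is.numeric(ibi) || length(ibi) < 2L)
    stop("`ibi` must contain at least 2 intervals")
  if (any(!is.finite(ibi)) || any(ibi <= 0)) stop("all intervals must be positive")
  mr <- mean(ibi)
  sdnn <- stats::sd(ibi)
  d <- diff(ibi)
  c(HR = 60000 / mr, MR = mr, SDNN = sdnn,
    RMSSD = sqrt(mean(d^2)), pNN50 = 100 * mean(abs(d) > 50),
    CV = sdnn / mr)
}

#' Invert the Stefan-Boltzmann law for infrared thermometry
#'
#' Recovers the absolute surface temperature from the net radiated power
#' seen by the sensor, \eqn{P = k\,\varepsilon\,\sigma\,(T^4 - T_s^4)}, as
#' \eqn{T = (P/(k\,\varepsilon\,\sigma) + T_s^4)^{1/4}}.
#'
#' @param P Net radiated power, W m^-2.
#' @param emissivity Surface emissivity in (0, 1].
#' @param k Proportionality (instrument) coefficient, > 0.
#' @param sensor_temp Sensor temperature in K.
#' @param sigma_SB Stefan-Boltzmann constant, W m^-2 K^-4.
#' @return Object temperature in K.
#' @export
object_temperature <- function(P, emissivity = 0.98, k = 1,
                               sensor_temp = 298.15,
                               sigma_SB = 5.670374419e-8) {
  if (emissivity <= 0 || emissivity > 1) stop("`emissivity` must be in (0, 1]")
  if (k <= 0 || sigma_SB <= 0) stop("`k` and `sigma_SB` must be positive")
  rad <- P / (k * emissivity * sigma_SB) + sensor_temp^4
  if (any(rad < 0)) stop("non-physical reading: negative fourth-power radicand")
  rad^0.25
}

#' Min-max normalization fitted on the training rows
#'
#' Scales each column by `(x - min)/(max - min)` with the minimum and
#' maximum taken over `fit_rows` only (no leakage from held-out rows);
#' values outside the fitted range are clipped to `[0, 1]`.  A column
#' constant over `fit_rows` is mapped to 0 with a warning.
#'
#' @param x Numeric matrix (or `labeled_cohort` features).
#' @param fit_rows Integer row indices used to fit the scaling (default all
#'   rows).
#' @param clip Clip out-of-range values to `[0, 1]` (default `TRUE`).
#' @return List with `features` (the normalized matrix), `min` and `range`
#'   (per-column scaling parameters).
#' @export
minmax_normalize <- function(x, fit_rows = seq_len(nrow(x)), clip = TRUE) {
  x <- as.matrix(x)
  if (!length(fit_rows)) stop("`fit_rows` must be non-empty")
  lo <- apply(x[fit_rows, , drop = FALSE], 2L, min)
  hi <- apply(x[fit_rows, , drop = FALSE], 2L, max)
  rng <- hi - lo
  if (any(rng == 0)) {
    warning("constant column(s) over the fitting rows normalized to 0: ",
            paste(colnames(x)[rng == 0], collapse = ", "))
  }
  out <- sweep(x, 2L, lo, "-")
  out <- sweep(out, 2L, ifelse(rng == 0, 1, rng), "/")
  out[, rng == 0] <- 0
  if (clip) out <- pmin(pmax(out, 0), 1)
  list(features = out, min = lo, range = rng)
}

#' Normalize a cohort on its training split
#'
#' Convenience wrapper: applies [minmax_normalize()] to a
#' `labeled_cohort`'s feature matrix with the scaling fitted on the
#' training rows.
#'
#' @param cohort A [labeled_cohort()].
#' @return The cohort with normalized features; scaling parameters attached
#'   as attribute `"scaling"`.
#' @export
normalize_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "labeled_cohort"))
  nm <- minmax_normalize(cohort$features, fit_rows = cohort$train_idx)
  out <- labeled_cohort(nm$features, cohort$labels,
                        cohort$train_idx, cohort$test_idx)
  attr(out, "scaling") <- nm[c("min", "range")]
  out
}

#' Seven-dimensional feature record from signals
#'
#' Builds the model input for one animal: the six HRV features from a
#' detected IBI series plus `TO`, the mean of the (optionally denoised)
#' body-temperature trace over the record window.
#'
#' @param ibi Inter-beat-interval series in ms.
#' @param temperature A [signal_trace()] in deg C (or numeric vector).
#' @return Named numeric vector HR, MR, SDNN, RMSSD, pNN50, CV, TO.
#' @export
feature_record <- function(ibi, temperature) {
  if (inherits(temperature, "signal_trace")) temperature <- temperature$samples
  if (!length(temperature)) stop("empty temperature trace")
  c(hrv_features(ibi), TO = estimate_mean(temperature))
}
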