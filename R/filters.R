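#' Recursive low-pass filter of the beat-detection chain
#'
#' Applies the integer-coefficient low-pass stage
#' \deqn{H(z) = \frac{1}{32}\frac{(1-z^{-6})^2}{(1-z^{-1})^2}}
#' via its difference equation
#' \eqn{y(n) = 2y(n-1) - y(n-2) + [x(n) - 2x(n-6) + x(n-12)]/32}
#' with zero initial conditions.  The filter is designed for a 200 Hz
#' sampling rate, where its -3 dB cutoff falls near 11 Hz; its DC gain is
#' 36/32 = 1.125 and its pure (linear-phase) delay is 5 samples.
#'
#' @param x Numeric vector, the signal to filter (finite values).
#' @return Numeric vector of the same length.
#' @seealso [highpass_filter()], [derivative_filter()], [window_integrate()],
#'   [pulse_chain()]
#' @export
#' @examples
#' y <- lowpass_filter(rep(1, 50))
#' tail(y, 1)  # steady state = DC gain 1.125
lowpass_filter <- function(x) {
  x <- check_samples(x)
  v <- (x - 2 * lag_pad(x, 6) + lag_pad(x, 12)) / 32
  as.numeric(stats::filter(v, c(2, -1), method = "recursive"))
}

#' Recursive high-pass filter of the beat-detection chain
#'
#' Applies the high-pass stage built as an all-pass delay minus a scaled
#' 32-point running sum,
#' \deqn{H(z) = z^{-16} - \frac{1}{32}\frac{1-z^{-32}}{1-z^{-1}},}
#' with zero initial conditions.  At 200 Hz its -3 dB cutoff is close to
#' 5 Hz, its DC gain is exactly 0 and its delay is 16 samples (80 ms at
#' 200 Hz).
#'
#' @inheritParams lowpass_filter
#' @return Numeric vector of the same length.
#' @export
highpass_filter <- function(x) {
  x <- check_samples(x)
  # running sum s(n) = s(n-1) + x(n) - x(n-32)
  v <- x - lag_pad(x, 32)
  s <- as.numeric(stats::filter(v, 1, method = "recursive"))
  lag_pad(x, 16) - s / 32
}

#' Five-point derivative filter
#'
#' \eqn{y(n) = [2x(n) + x(n-1) - x(n-3) - 2x(n-4)]/8}, zero initial
#' conditions.  Approximates the slope of the band-passed pulse wave with a
#' 2-sample delay; a unit-slope ramp gives a steady-state output of 1.25.
#'
#' @inheritParams lowpass_filter
#' @return Numeric vector of the same length.
#' @export
derivative_filter <- function(x) {
  x <- check_samples(x)
  (2 * x + lag_pad(x, 1) - lag_pad(x, 3) - 2 * lag_pad(x, 4)) / 8
}

#' Moving-window integration
#'
#' \eqn{y(n) = \frac{1}{N}\sum_{k=0}^{N-1} x(n-k)} with zero padding before
#' the start of the record.  `n_window = 30` is the designed width at a
#' 200 Hz sampling rate (150 ms), wide enough to merge the double-peaked
#' slope energy of a single pulse into one mound.
#'
#' @inheritParams lowpass_filter
#' @param n_window Integer window length `N` (>= 1).
#' @return Numeric vector of the same length.
#' @export
window_integrate <- function(x, n_window = 30L) {
  x <- check_samples(x)
  n_window <- as.integer(n_window)
  if (length(n_window) != 1L || is.na(n_window) || n_window < 1L)
    stop("`n_window` must be a single integer >= 1")
  cs <- cumsum(x)
  (cs - lag_pad(cs, n_window)) / n_window
}

#' Full beat-detection preprocessing chain
#'
#' Cascades the low-pass, high-pass and derivative stages, squares the
#' derivative output and applies the moving-window integral.  Squaring makes
#' the slope energy single-signed so that the integrator produces one mound
#' per beat whose centre sits at the analytic group delay of the chain (see
#' [chain_group_delay()]); it is the classical step between differentiation
#' and integration in this family of detectors.
#'
#' @inheritParams window_integrate
#' @return Numeric vector: the integrated slope-energy envelope, same length
#'   as `x`.
#' @export
pulse_chain <- function(x, n_window = 30L) {
  y <- derivative_filter(highpass_filter(lowpass_filter(x)))
  window_integrate(y * y, n_window = n_window)
}

#' Analytic group delay of the chain stages
#'
#' The low-pass stage delays by 5 samples, the high-pass by 16 (80 ms at
#' 200 Hz), the derivative by 2 and the `N`-point integrator by
#' `(N - 1)/2` samples.
#'
#' @param fs Sampling rate in Hz.
#' @param n_window Integration window length.
#' @return Named list with per-stage delays in ms (`lowpass`, `highpass`,
#'   `derivative`, `integration`) and their sum `total`.
#' @export
#' @examples
#' chain_group_delay(200)$highpass  # 80 ms
chain_group_delay <- function(fs, n_window = 30L) {
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("`fs` must be a single positive number")
  smp <- c(lowpass = 5, highpass = 16, derivative = 2,
           integration = (n_window - 1) / 2)
  out <- as.list(smp * 1000 / fs)
  out$total <- sum(smp) * 1000 / fs
  out
}

# finite impulse responses of the two recursive stages; both transfer
# functions are polynomials, so direct convolution with these kernels is an
# exact non-recursive route used by the oracle tests.
chain_fir_kernel <- function(stage = c("lowpass", "highpass")) {
  stage <- match.arg(stage)
  if (stage == "lowpass") {
    # (1-z^-6)^2/(1-z^-1)^2 = [1+z^-1+...+z^-5]^2 -> triangular, length 11
    stats::convolve(rep(1, 6), rev(rep(1, 6)), type = "open") / 32
  } else {
    # z^-16 - (1/32) [1+z^-1+...+z^-31]
    h <- rep(-1 / 32, 32)
    h[17] <- h[17] + 1
    h
  }
}

#' -3 dB cutoff frequency of a chain stage
#'
#' Evaluates the stage's magnitude response on a dense frequency grid and
#' returns the edge of its -3 dB band: for the low-pass stage the first
#' frequency above DC where the response drops below `1/sqrt(2)` of the DC
#' gain, for the high-pass stage the first frequency where it rises to
#' `1/sqrt(2)` of the passband maximum.  At the 200 Hz design rate these are
#' approximately 11 Hz and 5 Hz, the band that suppresses baseline drift
#' and power-line interference.
#'
#' @param stage `"lowpass"` or `"highpass"`.
#' @param fs Sampling rate in Hz.
#' @return Cutoff frequency in Hz (not rounded).
#' @export
cutoff_frequency <- function(stage = c("lowpass", "highpass"), fs = 200) {
  stage <- match.arg(stage)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("`fs` must be a single positive number")
  h <- chain_fir_kernel(stage)
  mag <- function(f) {
    om <- 2 * pi * f / fs
    vapply(om, function(w)
      Mod(sum(h * exp(-1i * w * (seq_along(h) - 1)))), numeric(1))
  }
  f <- seq(fs / 1e5, fs / 2 - fs / 1e5, length.out = 20000L)
  m <- mag(f)
  if (stage == "lowpass") {
    ref <- mag(0) / sqrt(2)
    i <- which(m <= ref)[1L]
    g <- function(f) mag(f) - ref
  } else {
    ref <- max(m) / sqrt(2)
    i <- which(m >= ref)[1L]
    g <- function(f) mag(f) - ref
  }
  if (is.na(i)) stop("no -3 dB crossing found below Nyquist")
  lo <- if (i > 1L) f[i - 1L] else fs / 1e6
  stats::uniroot(g, c(lo, f[i]), tol = 1e-10)$root
}

# ---- shared small helpers ----

# x delayed by k samples with zero fill (zero initial conditions)
lag_pad <- function(x, k) {
  n <- length(x)
  if (k >= n) return(numeric(n))
  c(numeric(k), x[seq_len(n - k)])
}

check_samples <- function(x) {
  if (inherits(x, "signal_trace")) x <- x$samples
  if (!is.numeric(x) || length(x) < 1L)
    stop("input must be a non-empty numeric vector or signal_trace")
  if (!all(is.finite(x))) stop("input contains non-finite samples")
  as.numeric(x)
}
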