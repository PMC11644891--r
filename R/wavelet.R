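#' Wavelet denoising plan
#'
#' Parameters of the wavelet threshold denoiser: a 9-level biorthogonal
#' bior6.8 decomposition with soft minimax-rule thresholding, in which the
#' three finest detail scales (the power-line / white-noise band) are zeroed
#' outright and the coarse level-9 approximation (the baseline-drift band)
#' is dropped from the reconstruction.
#'
#' @param basis Wavelet family; only `"bior6.8"` is supported.
#' @param levels Decomposition depth (default 9).
#' @param kill_detail_levels Integer set of detail scales set to zero
#'   outright (default `1:3`, the finest scales).
#' @param drop_approximation Drop the coarse approximation from the
#'   reconstruction (default `TRUE`).
#' @param threshold_rule Threshold selection rule; only `"minimax"`.
#' @param threshold_mode Shrinkage mode; only `"soft"`.
#' @param boundary Signal extension convention; only `"symmetric"`
#'   (half-point reflection).
#' @return An object of class `wavelet_plan`.
#' @export
wavelet_plan <- function(basis = "bior6.8", levels = 9L,
                         kill_detail_levels = 1:3,
                         drop_approximation = TRUE,
                         threshold_rule = "minimax",
                         threshold_mode = "soft",
                         boundary = "symmetric") {
  basis <- match.arg(basis, "bior6.8")
  threshold_rule <- match.arg(threshold_rule, "minimax")
  threshold_mode <- match.arg(threshold_mode, "soft")
  boundary <- match.arg(boundary, "symmetric")
  levels <- as.integer(levels)
  if (length(levels) != 1L || is.na(levels) || levels < 1L)
    stop("`levels` must be a single integer >= 1")
  kill_detail_levels <- sort(unique(as.integer(kill_detail_levels)))
  if (length(kill_detail_levels) &&
      (min(kill_detail_levels) < 1L || max(kill_detail_levels) > levels))
    stop("`kill_detail_levels` must be a subset of 1..levels")
  structure(list(basis = basis, levels = levels,
                 kill_detail_levels = kill_detail_levels,
                 drop_approximation = isTRUE(drop_approximation),
                 threshold_rule = threshold_rule,
                 threshold_mode = threshold_mode,
                 boundary = boundary),
            class = "wavelet_plan")
}

# bior6.8 analysis/synthesis filter bank (standard published coefficients,
# decomposition low/high and reconstruction low/high, length 18)
bior68_filters <- function() {
  dec_lo <- c(0, 0.00190883173648129, -0.00191428612908877,
              -0.01699063986760234, 0.01193456527972926, 0.04973290349094079,
              -0.07726317316720414, -0.09405920349573646, 0.4207962846098268,
              0.8259229974584023, 0.4207962846098268, -0.09405920349573646,
              -0.07726317316720414, 0.04973290349094079, 0.01193456527972926,
              -0.01699063986760234, -0.00191428612908877, 0.00190883173648129)
  dec_hi <- c(0, 0, 0, 0.01442628250562444, -0.01446750489679015,
              -0.07872200106262882, 0.04036797903033992, 0.41784910915027457,
              -0.7589077294536541, 0.41784910915027457, 0.04036797903033992,
              -0.07872200106262882, -0.01446750489679015, 0.01442628250562444,
              0, 0, 0, 0)
  rec_lo <- c(0, 0, 0, 0.01442628250562444, 0.01446750489679015,
              -0.07872200106262882, -0.04036797903033992, 0.41784910915027457,
              0.7589077294536541, 0.41784910915027457, -0.04036797903033992,
              -0.07872200106262882, 0.01446750489679015, 0.01442628250562444,
              0, 0, 0, 0)
  rec_hi <- c(0, -0.00190883173648129, -0.00191428612908877,
              0.01699063986760234, 0.01193456527972926, -0.04973290349094079,
              -0.07726317316720414, 0.09405920349573646, 0.4207962846098268,
              -0.8259229974584023, 0.4207962846098268, 0.09405920349573646,
              -0.07726317316720414, -0.04973290349094079, 0.01193456527972926,
              0.01699063986760234, -0.00191428612908877, -0.00190883173648129)
  list(dec_lo = dec_lo, dec_hi = dec_hi, rec_lo = rec_lo, rec_hi = rec_hi,
       length = 18L)
}

# one analysis step with half-point symmetric extension; returns the
# approximation and detail bands at half (rounded-up) resolution
dwt_step <- function(x, fb) {
  n <- length(x)
  p <- fb$length - 1L
  ext <- c(x[pmin(p:1, n)], x, x[pmax(n:(n - p + 1L), 1L)])
  outlen <- (n + fb$length - 1L) %/% 2L
  idx <- fb$length + 1L + 2L * (seq_len(outlen) - 1L)
  ca <- stats::convolve(ext, rev(fb$dec_lo), type = "open")[idx]
  cd <- stats::convolve(ext, rev(fb$dec_hi), type = "open")[idx]
  list(a = ca, d = cd)
}

# inverse of dwt_step; n_parent is the length of the signal that was analysed
idwt_step <- function(ca, cd, n_parent, fb) {
  up <- function(cc) {
    u <- numeric(2L * length(cc))
    u[seq(1L, by = 2L, length.out = length(cc))] <- cc
    u
  }
  s <- stats::convolve(up(ca), rev(fb$rec_lo), type = "open") +
       stats::convolve(up(cd), rev(fb$rec_hi), type = "open")
  s[(fb$length - 2L) + seq_len(n_parent)]
}

#' Multilevel biorthogonal wavelet decomposition
#'
#' Decomposes a signal into detail coefficient bands `d1..dL` (finest to
#' coarsest) and a coarse approximation using the bior6.8 filter bank with
#' half-point symmetric boundary extension.  Perfect reconstruction holds
#' before any thresholding (see [wt_reconstruct()]).
#'
#' @param x Numeric vector or [signal_trace()].
#' @param plan A [wavelet_plan()].
#' @return Object of class `wavelet_pyramid`: list with `d` (list of detail
#'   vectors, finest first), `a` (approximation), `parent_lengths`, `n`.
#' @export
wt_decompose <- function(x, plan = wavelet_plan()) {
  x <- check_samples(x)
  fb <- bior68_filters()
  if (length(x) < fb$length)
    stop("signal shorter than the bior6.8 filter length (18 samples)")
  d <- vector("list", plan$levels)
  parent_lengths <- integer(plan$levels)
  a <- x
  for (lev in seq_len(plan$levels)) {
    if (length(a) < fb$length)
      stop(sprintf(
        "signal too short for a %d-level decomposition; maximum feasible depth is %d",
        plan$levels, lev - 1L))
    parent_lengths[lev] <- length(a)
    st <- dwt_step(a, fb)
    d[[lev]] <- st$d
    a <- st$a
  }
  structure(list(d = d, a = a, parent_lengths = parent_lengths,
                 n = length(x), plan = plan),
            class = "wavelet_pyramid")
}

#' Reconstruct a signal from a wavelet pyramid
#'
#' @param pyr A `wavelet_pyramid` from [wt_decompose()] (coefficients may
#'   have been modified).
#' @return Numeric vector of the original signal length.
#' @export
wt_reconstruct <- function(pyr) {
  stopifnot(inherits(pyr, "wavelet_pyramid"))
  fb <- bior68_filters()
  a <- pyr$a
  for (lev in rev(seq_along(pyr$d)))
    a <- idwt_step(a, pyr$d[[lev]], pyr$parent_lengths[lev], fb)
  a
}

#' Minimax shrinkage threshold
#'
#' The minimax rule: zero for short coefficient vectors (`n <= 32`), else
#' \eqn{t = \sigma\,(0.3936 + 0.1829\,\log_2 n)}.
#'
#' @param d Coefficient vector (only its length is used).
#' @param sigma Noise scale (>= 0).
#' @return Threshold value.
#' @export
minimax_threshold <- function(d, sigma) {
  if (length(d) < 1L) stop("empty coefficient vector")
  if (!is.numeric(sigma) || length(sigma) != 1L || is.na(sigma) || sigma < 0)
    stop("`sigma` must be a single non-negative number")
  n <- length(d)
  if (n <= 32L) return(0)
  sigma * (0.3936 + 0.1829 * log2(n))
}

#' Soft thresholding (shrinkage)
#'
#' \eqn{\mathrm{sign}(d)\,\max(|d| - t, 0)} elementwise.
#'
#' @param d Coefficient vector.
#' @param t Threshold (>= 0).
#' @return Shrunk coefficient vector.
#' @export
soft_threshold <- function(d, t) {
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0)
    stop("`t` must be a single non-negative number")
  sign(d) * pmax(abs(d) - t, 0)
}

#' Wavelet threshold denoising
#'
#' Decomposes the signal per the plan, zeroes the detail scales in
#' `kill_detail_levels` outright, soft-thresholds the remaining detail
#' scales with a per-scale minimax threshold (noise scale estimated per
#' scale as `median(|d|)/0.6745`), drops the coarse approximation if
#' requested, and reconstructs.  With the defaults this removes power-line
#' interference and wide-band noise (finest scales) together with baseline
#' drift (the approximation band) from a 200 Hz pulse-wave record.
#'
#' @inheritParams wt_decompose
#' @return Numeric vector, same length as the input.
#' @export
wt_denoise <- function(x, plan = wavelet_plan()) {
  pyr <- wt_decompose(x, plan)
  for (lev in seq_along(pyr$d)) {
    if (lev %in% plan$kill_detail_levels) {
      pyr$d[[lev]] <- numeric(length(pyr$d[[lev]]))
    } else {
      d <- pyr$d[[lev]]
      sigma <- stats::median(abs(d)) / 0.6745
      pyr$d[[lev]] <- soft_threshold(d, minimax_threshold(d, sigma))
    }
  }
  if (plan$drop_approximation) pyr$a <- numeric(length(pyr$a))
  wt_reconstruct(pyr)
}
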