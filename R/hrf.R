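#' Canonical haemodynamic response function
#'
#' Double-gamma impulse response used for both simulation and design-matrix
#' construction: a positive gamma lobe peaking at 5 s minus a later
#' undershoot lobe peaking at 15 s (one sixth the amplitude), with finite
#' support on `[0, 32]` s. The 5 s peak matches the fixed 5 s forward shift
#' applied to percept reports when labelling volumes.
#'
#' @param t Time in seconds (vector); values outside `[0, 32)` return 0.
#' @return Response amplitude (dimensionless, unnormalised).
#' @examples
#' canonical_hrf(c(0, 5, 15))
#' @export
canonical_hrf <- function(t) {
  out <- stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  out[t < 0 | t >= 32] <- 0
  out
}

#' Sampled, unit-integral HRF kernel
#'
#' Samples [canonical_hrf()] on a `dt` grid over its 32 s support and scales
#' the samples so that `sum(kernel) * dt == 1`. Convolving a state boxcar
#' with this kernel then yields a response whose sustained plateau equals 1,
#' so effect sizes expressed in percent signal change map directly onto
#' plateau amplitudes.
#'
#' @param dt Sampling step in seconds.
#' @return Numeric vector of kernel samples at `t = 0, dt, 2 dt, ...`.
#' @export
hrf_kernel <- function(dt) {
  stopifnot(dt > 0)
  tt <- seq(0, 32, by = dt)
  h <- canonical_hrf(tt)
  h / (sum(h) * dt)
}
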