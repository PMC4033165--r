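#' Temporal band-pass filter configuration
#'
#' Butterworth band-pass used to remove scanner drift (high-pass) and
#' high-frequency noise (low-pass). `order` is the overall filter order of
#' the band-pass (an order-4 band-pass uses an order-2 low/high prototype).
#' `zero_phase` mode applies the filter forward-backward (no phase shift;
#' offline analysis); `causal` mode applies it forward only, as a real-time
#' loop must.
#'
#' @param highpass_cut,lowpass_cut Cutoff frequencies in Hz,
#'   `0 < highpass_cut < lowpass_cut < Nyquist`.
#' @param order Overall band-pass order (even, >= 2); default 4.
#' @param mode `"zero_phase"` or `"causal"`.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(highpass_cut = 1 / 128, lowpass_cut = 1 / 16,
                          order = 4, mode = c("zero_phase", "causal")) {
  mode <- match.arg(mode)
  stopifnot(highpass_cut > 0, lowpass_cut > highpass_cut,
            order >= 2, order %% 2 == 0)
  structure(list(highpass_cut = highpass_cut, lowpass_cut = lowpass_cut,
                 order = as.integer(order), mode = mode),
            class = "filter_config")
}

butter_coefs <- function(cfg, tr) {
  nyq <- 0.5 / tr
  if (cfg$lowpass_cut >= nyq)
    stop("lowpass cutoff must be below the Nyquist frequency (",
         signif(nyq, 3), " Hz at TR ", tr, " s)", call. = FALSE)
  bf <- signal::butter(cfg$order / 2,
                       c(cfg$highpass_cut, cfg$lowpass_cut) / nyq,
                       type = "pass")
  list(b = as.numeric(bf$b), a = as.numeric(bf$a))
}

#' Band-pass filter voxel time series
#'
#' @param x Numeric matrix, volumes in rows, voxels in columns (a vector is
#'   treated as one voxel).
#' @param tr Repetition time in seconds.
#' @param cfg A [filter_config()].
#' @return Filtered matrix of the same shape.
#' @export
bandpass <- function(x, tr, cfg = filter_config()) {
  stopifnot(inherits(cfg, "filter_config"), tr > 0)
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, ncol = 1L)
  if (nrow(x) <= 3 * cfg$order)
    stop("series too short for the requested filter order", call. = FALSE)
  co <- butter_coefs(cfg, tr)
  out <- if (cfg$mode == "zero_phase") {
    # forward-backward pass: squared magnitude response, zero phase
    fwd <- iir_filter_matrix(co$b, co$a, x)
    rev_rows(iir_filter_matrix(co$b, co$a, rev_rows(fwd)))
  } else {
    iir_filter_matrix(co$b, co$a, x)
  }
  if (vec) drop(out) else out
}

rev_rows <- function(x) x[rev(seq_len(nrow(x))), , drop = FALSE]

# Causal IIR filtering of a whole matrix, column-wise, via the same
# direct-form II transposed recursion used by the streaming filter so batch
# and streaming paths agree exactly.
iir_filter_matrix <- function(b, a, x) {
  st <- iir_state_init(b, a, ncol(x))
  out <- x
  for (t in seq_len(nrow(x))) {
    step <- iir_step(st, x[t, ])
    out[t, ] <- step$y
    st <- step$state
  }
  out
}

# Per-channel streaming IIR state (direct-form II transposed).
iir_state_init <- function(b, a, n_channels) {
  n <- max(length(a), length(b))
  list(b = c(b, rep(0, n - length(b))), a = c(a, rep(0, n - length(a))),
       z = matrix(0, n - 1L, n_channels))
}

# Advance the filter by one sample for every channel; returns the filtered
# sample vector and the updated state.
iir_step <- function(state, x) {
  b <- state$b; a <- state$a; z <- state$z
  y <- b[1L] * x + z[1L, ]
  nz <- nrow(z)
  if (nz > 1L)
    for (i in seq_len(nz - 1L))
      z[i, ] <- b[i + 1L] * x + z[i + 1L, ] - a[i + 1L] * y
  z[nz, ] <- b[nz + 1L] * x - a[nz + 1L] * y
  list(y = y, state = list(b = b, a = a, z = z))
}

filter_response <- function(cfg, tr, f) {
  co <- butter_coefs(cfg, tr)
  z <- exp(-1i * 2 * pi * f * tr)
  sum(co$b * z^(seq_along(co$b) - 1L)) / sum(co$a * z^(seq_along(co$a) - 1L))
}

#' Delays of the causal band-pass at a given frequency
#'
#' A causal filter delays the components it passes. `filter_phase_delay`
#' returns the phase delay `-arg H(f) / (2 pi f)` in seconds -- the lag of
#' a sinusoid at `f`, which is what misaligns a percept alternation cycle
#' against its labels; for a band-pass it is near zero at band centre.
#' `filter_group_delay` returns the group delay (phase slope), the lag of
#' the signal's envelope. The online decoder aligns labels using the phase
#' delay at the session's dominant alternation frequency.
#'
#' @param cfg A [filter_config()].
#' @param tr Repetition time in seconds.
#' @param f Frequency in Hz.
#' @return Delay in seconds.
#' @export
filter_phase_delay <- function(cfg, tr, f) {
  -Arg(filter_response(cfg, tr, f)) / (2 * pi * f)
}

#' @rdname filter_phase_delay
#' @export
filter_group_delay <- function(cfg, tr, f) {
  w0 <- 2 * pi * f * tr
  dw <- 1e-6
  co <- butter_coefs(cfg, tr)
  H <- function(w) {
    z <- exp(-1i * w)
    sum(co$b * z^(seq_along(co$b) - 1L)) / sum(co$a * z^(seq_along(co$a) - 1L))
  }
  -Arg(H(w0 + dw) / H(w0 - dw)) / (2 * dw) * tr
}

#' Zero-centre voxel time series
#'
#' Offline, the per-voxel temporal mean is removed and returned as the
#' baseline. Online, a previously stored training baseline is subtracted
#' from new volumes without recomputation.
#'
#' @param x Matrix (volumes x voxels) or a single volume vector.
#' @param baseline Optional stored per-voxel baseline (online mode).
#' @return List with `x` (centred data) and `baseline`.
#' @export
zero_center <- function(x, baseline = NULL) {
  if (is.null(dim(x))) {
    if (is.null(baseline))
      stop("online zero-centring of a single volume needs a stored baseline",
           call. = FALSE)
    return(list(x = x - baseline, baseline = baseline))
  }
  if (is.null(baseline)) baseline <- colMeans(x)
  list(x = sweep(x, 2L, baseline), baseline = baseline)
}

#' Exclude high signal-change (vessel-like) voxels
#'
#' At 3 T, voxels whose signal deviates by more than 10% from baseline are
#' likely dominated by large vessels. A voxel is excluded iff
#' `max_t |s(t) - baseline| / baseline > threshold` (strict), with the
#' per-voxel temporal mean as baseline. Voxels with non-positive baseline
#' are excluded with a warning.
#'
#' @param x Matrix, volumes x voxels (raw, unfiltered signal).
#' @param threshold Fractional signal-change threshold (default 0.10).
#' @return List with `retained` and `excluded` voxel indices and
#'   `signal_change`, the per-voxel maximal fractional deviation.
#' @export
exclude_high_signal_change <- function(x, threshold = 0.10) {
  stopifnot(is.matrix(x), threshold > 0)
  baseline <- colMeans(x)
  dev <- sweep(abs(sweep(x, 2L, baseline)), 2L, abs(baseline), "/")
  psc <- apply(dev, 2L, max)
  bad_base <- baseline <= 0
  if (any(bad_base)) {
    warning(sum(bad_base), " voxel(s) with non-positive baseline excluded")
    psc[bad_base] <- Inf
  }
  excluded <- which(psc > threshold)
  list(retained = setdiff(seq_len(ncol(x)), excluded),
       excluded = excluded, signal_change = psc)
}

#' Per-volume percept labels from a timeline
#'
#' Percept reports are shifted forward by the haemodynamic delay before
#' being attached to volumes: the volume acquired over `[kT, (k+1)T)` gets
#' the state occupying the majority of the shifted window
#' `[kT - d, (k+1)T - d)`. Windows that begin before the run start yield
#' `NA` (undefined; such volumes are dropped from training and accuracy
#' denominators). Majority ties go to the state occupying the earlier part
#' of the window.
#'
#' @param timeline A [percept_timeline()].
#' @param n_volumes Number of volumes in the run.
#' @param tr Repetition time in seconds (> 0).
#' @param hrf_delay Forward shift `d` in seconds (default 5).
#' @return Character vector of length `n_volumes` with values `"LINE"`,
#'   `"OBJECT"` or `NA`.
#' @export
labels_per_volume <- function(timeline, n_volumes, tr, hrf_delay = 5) {
  stopifnot(tr > 0, hrf_delay >= 0)
  ends <- timeline$onset + timeline$duration
  vapply(seq_len(n_volumes) - 1L, function(k) {
    a <- k * tr - hrf_delay
    b <- (k + 1) * tr - hrf_delay
    if (a < 0) return(NA_character_)
    ov <- pmax(0, pmin(b, ends) - pmax(a, timeline$onset))
    occ <- tapply(ov, timeline$state, sum)
    occ[is.na(occ)] <- 0
    if (length(occ) == 1L) return(names(occ))
    if (abs(diff(range(occ))) < 1e-12) {
      # tie: the state occupying the earlier part of the window
      timeline_state_at(timeline, min(a, total_duration(timeline) - 1e-9))
    } else names(occ)[which.max(occ)]
  }, character(1L))
}

#' Spatial Gaussian smoothing
#'
#' Isotropic Gaussian smoothing of a 3D volume (or of every volume of a 4D
#' array), with `sigma = fwhm / (2 sqrt(2 log 2))` converted to voxel units
#' and nearest-neighbour edge replication. `fwhm = 0` is the identity.
#'
#' @param volume 3D or 4D numeric array.
#' @param fwhm_mm Full width at half maximum in mm (>= 0).
#' @param voxel_size_mm Isotropic voxel size in mm.
#' @return Smoothed array of the same shape.
#' @export
smooth_spatial <- function(volume, fwhm_mm, voxel_size_mm = 3) {
  stopifnot(fwhm_mm >= 0, voxel_size_mm > 0)
  if (fwhm_mm == 0) return(volume)
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size_mm
  radius <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-radius, radius), sd = sigma)
  k <- k / sum(k)
  nd <- length(dim(volume))
  if (nd == 4L) {
    out <- volume
    for (t in seq_len(dim(volume)[4]))
      out[, , , t] <- smooth_spatial(volume[, , , t], fwhm_mm, voxel_size_mm)
    return(out)
  }
  stopifnot(nd == 3L)
  out <- volume
  for (d in 1:3) out <- convolve_axis(out, k, d)
  out
}

# Separable 1D convolution along axis `d` with nearest-edge replication.
convolve_axis <- function(arr, k, d) {
  radius <- (length(k) - 1L) / 2L
  n <- dim(arr)[d]
  idx <- function(i) pmin(pmax(i, 1L), n)
  out <- array(0, dim(arr))
  for (j in seq_along(k)) {
    off <- j - radius - 1L
    src <- idx(seq_len(n) + off)
    slice <- switch(d,
                    arr[src, , , drop = FALSE],
                    arr[, src, , drop = FALSE],
                    arr[, , src, drop = FALSE])
    out <- out + k[j] * slice
  }
  out
}
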