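#' Voxel population specification for simulated runs
#'
#' Describes which voxels of the grid respond to the percept and how. The
#' simulated brain contains an antagonistic network: `object_positive`
#' voxels show *higher* BOLD signal during object percepts (ventral-stream
#' like), `object_negative` voxels show *lower* signal during object
#' percepts (early-visual like), and `vessel` voxels oscillate with an
#' amplitude large enough (> 10% signal change) to trip the vascular
#' exclusion rule downstream.
#'
#' @param grid_shape Integer vector `c(X, Y, Z)` of voxel counts.
#' @param object_positive,object_negative,vessel Disjoint integer index sets
#'   into the flattened grid.
#' @param effect Percent-signal-change amplitude of the percept response
#'   (plateau deviation from baseline, in baseline units since
#'   `baseline = 100` by default).
#' @param vessel_amplitude Sinusoid amplitude of vessel voxels in percent
#'   signal change (> 10 so the exclusion rule fires).
#' @param baseline Baseline signal level; 100 makes percent signal change
#'   equal absolute deviation.
#' @return A list of class `voxel_spec`.
#' @export
voxel_spec <- function(grid_shape, object_positive = integer(),
                       object_negative = integer(), vessel = integer(),
                       effect = 1.0, vessel_amplitude = 12, baseline = 100) {
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 1))
  n <- prod(grid_shape)
  if (n < 1) stop("voxel grid must be non-empty", call. = FALSE)
  idx <- c(object_positive, object_negative, vessel)
  stopifnot(all(idx >= 1), all(idx <= n), !anyDuplicated(idx),
            is.finite(effect), is.finite(vessel_amplitude))
  structure(
    list(grid_shape = as.integer(grid_shape),
         object_positive = as.integer(object_positive),
         object_negative = as.integer(object_negative),
         vessel = as.integer(vessel),
         effect = effect, vessel_amplitude = vessel_amplitude,
         baseline = baseline),
    class = "voxel_spec"
  )
}

#' @rdname voxel_spec
#' @param n_positive,n_negative,n_vessel Numbers of voxels of each kind to
#'   place at random (disjoint) grid locations.
#' @param seed Optional seed for the placement.
#' @export
sample_voxel_spec <- function(grid_shape, n_positive = 100, n_negative = 100,
                              n_vessel = 5, effect = 1.0,
                              vessel_amplitude = 12, baseline = 100,
                              seed = NULL) {
  draw <- function() {
    idx <- sample.int(prod(grid_shape), n_positive + n_negative + n_vessel)
    voxel_spec(grid_shape,
               object_positive = idx[seq_len(n_positive)],
               object_negative = idx[n_positive + seq_len(n_negative)],
               vessel = idx[n_positive + n_negative + seq_len(n_vessel)],
               effect = effect, vessel_amplitude = vessel_amplitude,
               baseline = baseline)
  }
  if (!is.null(seed)) with_preserved_seed(seed, draw()) else draw()
}

#' Noise model for simulated runs
#'
#' Additive noise is a first-order autoregressive process with stationary
#' standard deviation `sigma` (percent signal change) plus a slow sinusoidal
#' drift of amplitude `drift_amplitude` and period `drift_period`, each voxel
#' receiving a random drift phase.
#'
#' @param sigma Stationary noise SD in percent signal change (>= 0).
#' @param ar1 Lag-one autocorrelation in `[0, 1)`.
#' @param drift_amplitude Drift amplitude in percent signal change.
#' @param drift_period Drift period in seconds.
#' @param seed Optional seed.
#' @return A list of class `noise_config`.
#' @export
noise_config <- function(sigma = 0.5, ar1 = 0.3, drift_amplitude = 1.0,
                         drift_period = 128, seed = NULL) {
  stopifnot(sigma >= 0, ar1 >= 0, ar1 < 1, drift_amplitude >= 0,
            drift_period > 0)
  structure(list(sigma = sigma, ar1 = ar1,
                 drift_amplitude = drift_amplitude,
                 drift_period = drift_period, seed = seed),
            class = "noise_config")
}

# Noise-free percept response sampled at volume midpoints: the state boxcar
# on a fine grid convolved with the unit-integral HRF kernel, so a sustained
# state yields a plateau of exactly 1.
state_response <- function(timeline, tr, n_volumes, state = "OBJECT",
                           dt = 0.1) {
  t_fine <- seq(0, n_volumes * tr - dt, by = dt)
  box <- as.numeric(timeline_state_at(timeline, t_fine) == state)
  h <- hrf_kernel(dt)
  resp <- stats::convolve(box, rev(h), type = "open")[seq_along(t_fine)] * dt
  t_mid <- (seq_len(n_volumes) - 0.5) * tr
  resp[pmin(length(t_fine), pmax(1L, round(t_mid / dt) + 1L))]
}

#' Simulate one BOLD run
#'
#' Each voxel's series is `baseline + effect * (state boxcar convolved with
#' the HRF) + drift + AR(1) noise`. Object-positive voxels respond with
#' `+effect` to the OBJECT boxcar, object-negative voxels with `-effect`;
#' vessel voxels receive a sinusoid of the configured amplitude instead of a
#' percept response. The ground-truth timeline travels with the run.
#'
#' @param timeline A [percept_timeline()].
#' @param voxels A [voxel_spec()].
#' @param noise A [noise_config()].
#' @param tr Repetition time in seconds.
#' @param run_id Integer run index stored with the run.
#' @return A list of class `bold_run` with elements `data` (X x Y x Z x T
#'   array), `tr`, `run_id`, `timeline`.
#' @export
simulate_run <- function(timeline, voxels, noise = noise_config(), tr = 2.0,
                         run_id = 1L) {
  stopifnot(inherits(timeline, "percept_timeline"),
            inherits(voxels, "voxel_spec"), inherits(noise, "noise_config"),
            tr > 0)
  if (!is.null(noise$seed))
    return(with_preserved_seed(noise$seed, {
      ns <- noise; ns$seed <- NULL
      simulate_run(timeline, voxels, ns, tr, run_id)
    }))
  n_vol <- floor(total_duration(timeline) / tr)
  nv <- prod(voxels$grid_shape)
  resp <- state_response(timeline, tr, n_vol)
  x <- matrix(voxels$baseline, nrow = n_vol, ncol = nv)
  if (length(voxels$object_positive))
    x[, voxels$object_positive] <- x[, voxels$object_positive] +
      voxels$effect * resp
  if (length(voxels$object_negative))
    x[, voxels$object_negative] <- x[, voxels$object_negative] -
      voxels$effect * resp
  t_mid <- (seq_len(n_vol) - 0.5) * tr
  if (length(voxels$vessel)) {
    phase <- stats::runif(length(voxels$vessel), 0, 2 * pi)
    vs <- voxels$vessel_amplitude *
      sin(outer(2 * pi * t_mid / 10, rep(1, length(voxels$vessel))) +
            matrix(phase, n_vol, length(voxels$vessel), byrow = TRUE))
    x[, voxels$vessel] <- voxels$baseline + vs
  }
  if (noise$drift_amplitude > 0) {
    ph <- stats::runif(nv, 0, 2 * pi)
    x <- x + noise$drift_amplitude *
      sin(outer(2 * pi * t_mid / noise$drift_period, rep(1, nv)) +
            matrix(ph, n_vol, nv, byrow = TRUE))
  }
  if (noise$sigma > 0) {
    eps <- matrix(stats::rnorm(n_vol * nv), n_vol, nv)
    if (noise$ar1 > 0) {
      innov_sd <- sqrt(1 - noise$ar1^2)
      for (t in 2:n_vol) eps[t, ] <- noise$ar1 * eps[t - 1, ] +
          innov_sd * eps[t, ]
    }
    x <- x + noise$sigma * eps
  }
  structure(
    list(data = array(t(x), dim = c(voxels$grid_shape, n_vol)),
         tr = tr, run_id = as.integer(run_id), timeline = timeline),
    class = "bold_run"
  )
}

#' @export
print.bold_run <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bold_run %d> grid %dx%dx%d, %d volumes, TR %.1f s, %d percept intervals\n",
              x$run_id, d[1], d[2], d[3], d[4], x$tr, nrow(x$timeline)))
  invisible(x)
}

# T x V matrix view of a run (volumes in rows, voxels flattened column-major).
run_matrix <- function(run) {
  d <- dim(run$data)
  t(matrix(run$data, nrow = prod(d[1:3]), ncol = d[4]))
}

#' @export
n_volumes <- function(run) dim(run$data)[4]

#' Simulate a multi-run scanning session
#'
#' Convenience wrapper drawing one timeline and one run per acquisition run,
#' with per-run seeds derived from `seed` so the whole session is
#' reproducible.
#'
#' @param n_runs Number of runs.
#' @param duration Run length in seconds (420 by default).
#' @param tr Repetition time in seconds.
#' @param dwell A [dwell_config()] (its `seed` field is ignored here).
#' @param voxels A [voxel_spec()].
#' @param noise A [noise_config()] (its `seed` field is ignored here).
#' @param seed Session seed.
#' @return A list of class `percept_session`: `runs`, `grid_shape`, `tr`,
#'   `seed`, `voxels`.
#' @export
simulate_session <- function(n_runs = 8, duration = 420, tr = 2.0,
                             dwell = dwell_preset("online"),
                             voxels = sample_voxel_spec(c(20, 20, 10), seed = 1),
                             noise = noise_config(), seed = 1) {
  stopifnot(n_runs >= 1)
  runs <- purrr::map(seq_len(n_runs), function(r) {
    dw <- dwell; dw$seed <- seed * 1000L + r
    ns <- noise; ns$seed <- seed * 1000L + 500L + r
    tl <- simulate_percept_timeline(duration, dw)
    simulate_run(tl, voxels, ns, tr, run_id = r)
  })
  structure(
    list(runs = runs, grid_shape = voxels$grid_shape, tr = tr,
         seed = seed, voxels = voxels),
    class = "percept_session"
  )
}

#' @export
print.percept_session <- function(x, ...) {
  cat(sprintf("<percept_session> %d runs, grid %s, TR %.1f s, seed %s\n",
              length(x$runs), paste(x$grid_shape, collapse = "x"),
              x$tr, format(x$seed)))
  invisible(x)
}
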