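#' Percept dwell-time configuration
#'
#' Dwell times of a bistable percept (how long one perceptual state lasts
#' before it flips) are well approximated by a gamma distribution. A
#' `dwell_config` bundles the gamma shape and scale together with a minimum
#' admissible duration and an optional seed, and is consumed by
#' [simulate_percept_timeline()] and [simulate_dwell_times()].
#'
#' Two presets mirror the two experimental regimes the package emulates:
#' `"offline"` (shape 2.00, scale 7.51 s, TR 2.5 s) and `"online"`
#' (shape 5.29, scale 4.26 s, TR 2.0 s). `min_duration` defaults to two
#' repetition times so that every interval spans at least two volumes and
#' per-volume labels remain well defined after the hemodynamic shift.
#'
#' @param shape Gamma shape parameter (dimensionless, > 0).
#' @param scale Gamma scale parameter in seconds (> 0).
#' @param min_duration Minimum dwell time in seconds; shorter draws are
#'   rejected and redrawn.
#' @param seed Optional integer seed making draws reproducible.
#' @return A list of class `dwell_config`.
#' @examples
#' dwell_preset("online")
#' dwell_config(shape = 3, scale = 5)
#' @export
dwell_config <- function(shape, scale, min_duration = 0, seed = NULL) {
  stopifnot(is.numeric(shape), length(shape) == 1L, shape > 0,
            is.numeric(scale), length(scale) == 1L, scale > 0,
            is.numeric(min_duration), min_duration >= 0)
  structure(
    list(shape = shape, scale = scale,
         min_duration = min_duration, seed = seed),
    class = "dwell_config"
  )
}

#' @rdname dwell_config
#' @param preset `"offline"` or `"online"`.
#' @export
dwell_preset <- function(preset = c("online", "offline"), seed = NULL) {
  preset <- match.arg(preset)
  switch(preset,
    online  = dwell_config(shape = 5.29, scale = 4.26, min_duration = 2 * 2.0,
                           seed = seed),
    offline = dwell_config(shape = 2.00, scale = 7.51, min_duration = 2 * 2.5,
                           seed = seed)
  )
}

#' Draw percept dwell times
#'
#' Draws i.i.d. gamma dwell times, rejecting (and redrawing) values below
#' `dwell$min_duration`.
#'
#' @param n Number of durations to draw.
#' @param dwell A [dwell_config()].
#' @return Numeric vector of `n` durations in seconds.
#' @export
simulate_dwell_times <- function(n, dwell) {
  stopifnot(inherits(dwell, "dwell_config"), n >= 1)
  if (!is.null(dwell$seed)) {
    return(with_preserved_seed(dwell$seed, simulate_dwell_times(n, strip_seed(dwell))))
  }
  out <- numeric(0)
  while (length(out) < n) {
    d <- stats::rgamma(n - length(out), shape = dwell$shape, scale = dwell$scale)
    out <- c(out, d[d >= dwell$min_duration])
  }
  out[seq_len(n)]
}

strip_seed <- function(dwell) {
  dwell$seed <- NULL
  dwell
}

# Evaluate `expr` under `seed` and restore the caller's RNG state afterwards.
with_preserved_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Construct a percept timeline
#'
#' A percept timeline is an ordered set of contiguous intervals, each labelled
#' with the perceptual state (`"LINE"` or `"OBJECT"`), covering
#' `[0, total_duration)`. Consecutive intervals carry different states.
#'
#' @param onset,duration,state Parallel vectors of interval onsets (s),
#'   durations (s) and states.
#' @param total_duration Run length in seconds.
#' @return A tibble of class `percept_timeline` with columns `onset`,
#'   `duration`, `state` and attribute `total_duration`.
#' @export
percept_timeline <- function(onset, duration, state, total_duration) {
  tl <- tibble::tibble(onset = as.numeric(onset),
                       duration = as.numeric(duration),
                       state = as.character(state))
  attr(tl, "total_duration") <- as.numeric(total_duration)
  class(tl) <- c("percept_timeline", class(tl))
  validate_percept_timeline(tl)
}

validate_percept_timeline <- function(tl) {
  td <- attr(tl, "total_duration")
  stopifnot(nrow(tl) >= 1, all(tl$duration > 0),
            all(tl$state %in% c("LINE", "OBJECT")))
  if (abs(tl$onset[1]) > 1e-9)
    stop("timeline must start at 0", call. = FALSE)
  if (nrow(tl) > 1) {
    gaps <- tl$onset[-1] - (tl$onset[-nrow(tl)] + tl$duration[-nrow(tl)])
    if (any(abs(gaps) > 1e-9))
      stop("timeline intervals must be contiguous", call. = FALSE)
    if (any(tl$state[-1] == tl$state[-nrow(tl)]))
      stop("consecutive intervals must alternate states", call. = FALSE)
  }
  if (abs(sum(tl$duration) - td) > 1e-9)
    stop("interval durations must sum to total_duration", call. = FALSE)
  tl
}

#' @export
total_duration <- function(x) attr(x, "total_duration")

#' Simulate a bistable percept timeline
#'
#' Generates alternating LINE/OBJECT intervals whose durations are i.i.d.
#' gamma draws (see [simulate_dwell_times()]); the initial state is chosen by
#' a fair coin and the last interval is truncated at `total_duration`.
#'
#' @param total_duration Run length in seconds (> 0).
#' @param dwell A [dwell_config()]; if its `seed` is set the timeline is
#'   reproducible and the caller's RNG state is untouched.
#' @return A [percept_timeline()].
#' @examples
#' tl <- simulate_percept_timeline(420, dwell_preset("online", seed = 1))
#' head(tl)
#' @export
simulate_percept_timeline <- function(total_duration, dwell) {
  if (!is.numeric(total_duration) || length(total_duration) != 1L ||
      total_duration <= 0)
    stop("`total_duration` must be a positive number", call. = FALSE)
  stopifnot(inherits(dwell, "dwell_config"))
  if (!is.null(dwell$seed)) {
    return(with_preserved_seed(
      dwell$seed,
      simulate_percept_timeline(total_duration, strip_seed(dwell))
    ))
  }
  states <- c("LINE", "OBJECT")
  first <- sample(states, 1L)
  durs <- numeric(0)
  while (sum(durs) < total_duration)
    durs <- c(durs, simulate_dwell_times(8L, dwell))
  keep <- which(cumsum(durs) >= total_duration)[1L]
  durs <- durs[seq_len(keep)]
  onsets <- cumsum(c(0, durs[-keep]))
  durs[keep] <- total_duration - onsets[keep]
  st <- rep(states[c(match(first, states), 3L - match(first, states))],
            length.out = keep)
  percept_timeline(onsets, durs, st, total_duration)
}

#' Jitter reported switch times
#'
#' Emulates imperfect report timing: each interior interval boundary is
#' shifted by independent Gaussian noise (SD `sd` seconds), keeping
#' boundaries ordered and inside the run. `sd = 0` returns the timeline
#' unchanged. The default generator applies no jitter; this models report
#' latency when wanted.
#'
#' @param tl A [percept_timeline()].
#' @param sd Jitter standard deviation in seconds (>= 0).
#' @param seed Optional seed.
#' @param min_gap Minimal interval duration preserved (seconds).
#' @return A [percept_timeline()] with the same states.
#' @export
jitter_reports <- function(tl, sd, seed = NULL, min_gap = 0.5) {
  stopifnot(inherits(tl, "percept_timeline"), sd >= 0)
  if (sd == 0 || nrow(tl) == 1L) return(tl)
  if (!is.null(seed))
    return(with_preserved_seed(seed, jitter_reports(tl, sd, min_gap = min_gap)))
  td <- total_duration(tl)
  b <- tl$onset[-1L] + stats::rnorm(nrow(tl) - 1L, sd = sd)
  b <- sort(pmin(pmax(b, min_gap), td - min_gap))
  # enforce a minimal gap between consecutive boundaries
  for (i in seq_along(b)[-1L]) b[i] <- max(b[i], b[i - 1L] + min_gap)
  b <- pmin(b, td - min_gap)
  edges <- unique(c(0, b, td))
  percept_timeline(edges[-length(edges)], diff(edges),
                   tl$state[seq_len(length(edges) - 1L)], td)
}

#' State occupying each time point
#'
#' @param tl A [percept_timeline()].
#' @param t Numeric vector of times in seconds within `[0, total_duration)`.
#' @return Character vector of states at `t`.
#' @export
timeline_state_at <- function(tl, t) {
  idx <- findInterval(t, tl$onset)
  idx[idx < 1L] <- NA_integer_
  tl$state[idx]
}
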