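#' Accuracy near and away from perceptual switches
#'
#' Decoding errors concentrate around switches, where the sluggish
#' haemodynamic response blends the two states. This splits the defined
#' volumes into a near-switch set (each switch-labelled volume plus one
#' neighbour on each side, for `window_volumes = 3`) and its complement,
#' and reports accuracy over each. A switch volume is the first defined
#' volume of a new true state within a run.
#'
#' @param result A `decoding_result` or `online_result` (tibble with
#'   `run`, `volume`, `truth`, `predicted`).
#' @param window_volumes Odd window size centred on the switch volume.
#' @return Tibble with one row: `overall`, `away_from_switch`,
#'   `near_switch`, `n_near`, `n_away`.
#' @export
switch_local_accuracy <- function(result, window_volumes = 3) {
  stopifnot(nrow(result) >= 1, window_volumes >= 1,
            window_volumes %% 2 == 1)
  half <- (window_volumes - 1) / 2
  res <- tibble::as_tibble(result) |>
    dplyr::filter(!is.na(.data$truth)) |>
    dplyr::arrange(.data$run, .data$volume)
  near <- logical(nrow(res))
  for (r in unique(res$run)) {
    i <- which(res$run == r)
    sw <- i[which(res$truth[i][-1] != res$truth[i][-length(i)]) + 1L]
    for (s in sw) {
      j <- intersect(seq(s - half, s + half), i)
      near[j] <- TRUE
    }
  }
  ok <- res$predicted == res$truth
  tibble::tibble(
    overall = mean(ok),
    away_from_switch = mean(ok[!near]),
    near_switch = if (any(near)) mean(ok[near]) else NA_real_,
    n_near = sum(near), n_away = sum(!near))
}

#' Fit a gamma distribution to percept dwell times
#'
#' `"mle"` fits shape and scale by maximum likelihood; `"histogram_ls"`
#' least-squares-fits the gamma pdf to the normalised dwell-time histogram
#' (default 3 s bins) and reports the fit's R squared.
#'
#' @param durations Numeric vector of dwell times in seconds (>= 10
#'   values, all > 0).
#' @param method `"mle"` or `"histogram_ls"`.
#' @param bin_width Histogram bin width in seconds (histogram method).
#' @return A `gamma_fit` list: `shape`, `scale`, `method`, `se` (named,
#'   MLE only), `r_squared` (histogram method only), `n`.
#' @export
fit_gamma <- function(durations, method = c("mle", "histogram_ls"),
                      bin_width = 3) {
  method <- match.arg(method)
  if (length(durations) < 10 || any(durations <= 0) ||
      any(!is.finite(durations)))
    stop("need >= 10 strictly positive finite durations", call. = FALSE)
  if (stats::var(durations) == 0)
    stop("degenerate input: all durations identical; a gamma fit is not ",
         "defined (shape would diverge)", call. = FALSE)
  if (method == "mle") {
    fit <- fitdistrplus::fitdist(durations, "gamma")
    shape <- unname(fit$estimate["shape"])
    rate <- unname(fit$estimate["rate"])
    se <- fit$sd
    # delta method for scale = 1/rate
    scale_se <- unname(se["rate"]) / rate^2
    out <- list(shape = shape, scale = 1 / rate, method = "mle",
                se = c(shape = unname(se["shape"]), scale = scale_se),
                r_squared = NA_real_, n = length(durations))
  } else {
    breaks <- seq(0, max(durations) + bin_width, by = bin_width)
    h <- graphics::hist(durations, breaks = breaks, plot = FALSE)
    mid <- h$mids; dens <- h$density
    start <- list(shape = mean(durations)^2 / stats::var(durations),
                  scale = stats::var(durations) / mean(durations))
    obj <- function(p) sum((dens - stats::dgamma(mid, shape = p[1],
                                                 scale = p[2]))^2)
    opt <- stats::optim(unlist(start), obj, method = "L-BFGS-B",
                        lower = c(1e-3, 1e-3))
    ss_res <- opt$value
    ss_tot <- sum((dens - mean(dens))^2)
    out <- list(shape = unname(opt$par[1]), scale = unname(opt$par[2]),
                method = "histogram_ls", se = NULL,
                r_squared = 1 - ss_res / ss_tot, n = length(durations))
  }
  structure(out, class = "gamma_fit")
}

#' @export
print.gamma_fit <- function(x, ...) {
  cat(sprintf("<gamma_fit %s> shape %.3f, scale %.3f s (mode %.1f s, n = %d)\n",
              x$method, x$shape, x$scale, gamma_mode(x), x$n))
  invisible(x)
}

#' Mode of a fitted gamma dwell-time distribution
#'
#' Closed form `(shape - 1) * scale` for `shape > 1`, else 0 (the
#' exponential-like limit piles mass at zero).
#'
#' @param fit A `gamma_fit`, or a shape value when `scale` is given.
#' @param scale Scale in seconds (when `fit` is a bare shape).
#' @return Mode in seconds.
#' @examples
#' gamma_mode(5.29, 4.26) # ~18.3 s
#' @export
gamma_mode <- function(fit, scale = NULL) {
  if (inherits(fit, "gamma_fit")) {
    shape <- fit$shape; scale <- fit$scale
  } else {
    shape <- fit
    stopifnot(!is.null(scale))
  }
  if (shape > 1) (shape - 1) * scale else 0
}

#' Summary statistics of percept durations
#'
#' @param timelines A [percept_timeline()] or list of them.
#' @param query_delay Optional delay in seconds; the output then includes
#'   the fraction of dwell times shorter than it (the percepts a delayed
#'   decoder cannot resolve).
#' @return Tibble with `median_s`, one `prop_<state>` column per state
#'   (fraction of total time), `n_intervals`, and `frac_below_delay` when
#'   `query_delay` is given.
#' @export
duration_stats <- function(timelines, query_delay = NULL) {
  if (inherits(timelines, "percept_timeline")) timelines <- list(timelines)
  stopifnot(length(timelines) >= 1)
  tab <- dplyr::bind_rows(purrr::map(timelines, tibble::as_tibble))
  props <- tapply(tab$duration, tab$state, sum) / sum(tab$duration)
  out <- tibble::tibble(median_s = stats::median(tab$duration),
                        n_intervals = nrow(tab))
  for (s in names(props)) out[[paste0("prop_", tolower(s))]] <- unname(props[s])
  if (!is.null(query_delay))
    out$frac_below_delay <- mean(tab$duration < query_delay)
  out
}

#' Signed per-voxel t map
#'
#' Pooled-variance two-sample t per voxel on labelled samples, signed as
#' object minus line: positive t means higher BOLD signal during object
#' percepts.
#'
#' @param x Matrix, samples x voxels (e.g. reduced interval-centre group
#'   data).
#' @param y Labels (`"LINE"`/`"OBJECT"`).
#' @param mask Optional logical voxel mask; unmasked voxels get `NA`.
#' @return List with `t` (per voxel) and `df`.
#' @export
signed_tmap <- function(x, y, mask = NULL) {
  y <- normalize_labels(y)
  stopifnot(is.matrix(x), length(y) == nrow(x),
            length(unique(y)) == 2L)
  io <- y == "OBJECT"
  n1 <- sum(io); n2 <- sum(!io)
  m1 <- colMeans(x[io, , drop = FALSE])
  m2 <- colMeans(x[!io, , drop = FALSE])
  v1 <- colSums(sweep(x[io, , drop = FALSE], 2L, m1)^2)
  v2 <- colSums(sweep(x[!io, , drop = FALSE], 2L, m2)^2)
  df <- n1 + n2 - 2L
  sp <- sqrt((v1 + v2) / df * (1 / n1 + 1 / n2))
  tv <- ifelse(sp > 0, (m1 - m2) / sp, 0)
  if (!is.null(mask)) {
    stopifnot(length(mask) == ncol(x))
    tv[!mask] <- NA_real_
  }
  list(t = tv, df = df)
}

#' Two-sided critical t value
#'
#' @param alpha_two_sided Two-sided significance level in (0, 1).
#' @param df Degrees of freedom (>= 1).
#' @return The threshold `t` with `P(|T| > t) = alpha`.
#' @examples
#' critical_t(0.001, 3936) # ~3.29
#' @export
critical_t <- function(alpha_two_sided, df) {
  stopifnot(alpha_two_sided > 0, alpha_two_sided < 1, df >= 1)
  stats::qt(1 - alpha_two_sided / 2, df)
}
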