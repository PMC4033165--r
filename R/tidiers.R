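#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
#' @method tidy linear_percept_model
tidy.linear_percept_model <- function(x, ...) {
  tibble::tibble(voxel = x$voxel_indices, weight = x$w)
}

#' @export
#' @method glance linear_percept_model
glance.linear_percept_model <- function(x, ...) {
  tibble::tibble(n_features = length(x$w), n_samples = x$n_samples,
                 C = x$C, bias = x$b, w_norm = sqrt(sum(x$w^2)))
}

#' @export
#' @method tidy decoding_result
tidy.decoding_result <- function(x, ...) {
  attr(x, "fold_accuracy")
}

#' @export
#' @method glance decoding_result
glance.decoding_result <- function(x, ...) {
  tibble::tibble(accuracy = accuracy(x), n_volumes = nrow(x),
                 n_runs = length(unique(x$run)))
}

#' @export
#' @method tidy online_result
tidy.online_result <- function(x, ...) {
  ev <- attr(x, "events")
  acc <- tibble::as_tibble(x) |>
    dplyr::filter(!is.na(.data$truth)) |>
    dplyr::group_by(.data$run) |>
    dplyr::summarise(accuracy = mean(.data$predicted == .data$truth),
                     .groups = "drop")
  acc$n_switch_events <- vapply(
    acc$run, function(r) if (nrow(ev)) sum(ev$run == r) else 0L, integer(1L))
  acc
}

#' @export
#' @method glance online_result
glance.online_result <- function(x, ...) {
  lat <- attr(x, "latency")
  tibble::tibble(accuracy = accuracy(x),
                 accuracy_hrf_aligned = attr(x, "accuracy_hrf_aligned"),
                 n_events = nrow(attr(x, "events")),
                 filter_delay_s = lat$filter_delay_s,
                 total_delay_s = lat$hrf_delay_s + lat$filter_delay_s)
}

#' @export
#' @method tidy gamma_fit
tidy.gamma_fit <- function(x, ...) {
  out <- tibble::tibble(term = c("shape", "scale"),
                        estimate = c(x$shape, x$scale))
  if (!is.null(x$se)) out$std.error <- unname(x$se[c("shape", "scale")])
  out
}

#' @export
#' @method glance gamma_fit
glance.gamma_fit <- function(x, ...) {
  tibble::tibble(method = x$method, mode_s = gamma_mode(x),
                 mean_s = x$shape * x$scale, r.squared = x$r_squared,
                 nobs = x$n)
}

#' @export
#' @method tidy permutation_null
tidy.permutation_null <- function(x, ...) {
  tibble::tibble(permutation = seq_along(x$null), accuracy = x$null)
}

#' @export
#' @method glance permutation_null
glance.permutation_null <- function(x, ...) {
  tibble::tibble(observed = x$statistic, null_mean = x$mean,
                 ci_lower = x$ci[1], ci_upper = x$ci[2],
                 exceeds_ci = x$exceeds_ci,
                 n_permutations = x$n_permutations)
}

#' @export
#' @method tidy weight_significance
tidy.weight_significance <- function(x, ...) {
  tibble::tibble(voxel = seq_along(x$p_w), weight = x$w_obs, p_w = x$p_w)
}

#' @export
#' @method tidy group_map
tidy.group_map <- function(x, ...) {
  tibble::tibble(voxel = seq_along(x$w_bar), weight = x$w_bar)
}

#' @export
#' @method glance group_map
glance.group_map <- function(x, ...) {
  tibble::tibble(n_subjects = x$n, mean_p_hat = mean(x$p_hat),
                 n_nonzero = sum(x$w_bar != 0))
}
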