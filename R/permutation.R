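#' Block-preserving label permutation
#'
#' Decomposes a label sequence into maximal blocks of consecutively equal
#' labels and uniformly shuffles the block order, preserving the dwell-time
#' structure that makes volume-wise shuffles anti-conservative for
#' autocorrelated time series. With a `runs` grouping, blocks never
#' straddle run boundaries (the decomposition splits there); shuffling is
#' across the concatenated session.
#'
#' @param labels Character vector (may contain `NA`, which form their own
#'   blocks and travel with the shuffle).
#' @param runs Optional integer vector of run indices, same length.
#' @return Permuted label vector with identical per-label counts.
#' @export
block_permute <- function(labels, runs = NULL) {
  stopifnot(length(labels) >= 1)
  key <- paste(if (is.null(runs)) "" else runs,
               ifelse(is.na(labels), "<NA>", labels))
  r <- rle(key)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ord <- sample.int(length(starts))
  unlist(purrr::map(ord, ~ labels[starts[.x]:ends[.x]]), use.names = FALSE)
}

#' Empirical guessing level of the decoder
#'
#' Re-runs the full cross-validated decoding pipeline (feature selection
#' inside every fold) on block-permuted labels, yielding the empirical
#' distribution of accuracies obtainable without label information. Only
#' observed accuracies exceeding the upper percentile bound of this null
#' should be considered reliable. Feature selection under permuted labels
#' uses the class-difference F (a shuffled label sequence defines no
#' timeline), and the observed accuracy is computed with the same scoring
#' so the comparison is like-for-like.
#'
#' @param session A `percept_session`.
#' @param cfg A [decode_config()]; its `score_method` is forced to
#'   `"anova"`.
#' @param n_perm Number of permutations (500 in the full protocol).
#' @param alpha Two-sided tail mass for the percentile interval.
#' @param optimize Optimise the low-pass cutoff inside each fold (slow;
#'   default `FALSE` uses the first candidate).
#' @param refit_features If `FALSE`, feature selection is done once on the
#'   observed labels and frozen across permutations (fast approximate
#'   mode).
#' @param seed Optional seed.
#' @return A `permutation_null` list: `statistic` (observed accuracy),
#'   `null` (vector of permuted accuracies), `mean`, `ci` (percentile
#'   bounds), `n_permutations`, `alpha`, `exceeds_ci`.
#' @export
guessing_level_ci <- function(session, cfg = decode_config(), n_perm = 500,
                              alpha = 0.05, optimize = FALSE,
                              refit_features = TRUE, seed = NULL) {
  if (!is.null(seed))
    return(with_preserved_seed(seed, guessing_level_ci(
      session, cfg, n_perm, alpha, optimize, refit_features)))
  stopifnot(n_perm >= 1)
  cfg$score_method <- "anova"
  prep <- prepare_decoding(session, cfg)
  observed <- accuracy(loro_cv_prepared(prep, cfg, optimize))
  runs_idx <- rep(seq_len(prep$n_runs),
                  purrr::map_int(prep$labels, length))
  flat <- unlist(prep$labels)
  if (!refit_features) {
    # approximate fast mode: freeze the feature set chosen on the observed
    # labels of the whole session and reuse it across permutations
    def <- !is.na(flat)
    xall <- do.call(rbind, prep$filtered[[1L]])
    cfg$frozen_features <- suppressWarnings(select_top_k(
      class_f_scores(xall[def, , drop = FALSE], flat[def]), cfg$k_select))
  }
  null <- purrr::map_dbl(seq_len(n_perm), function(i) {
    perm <- block_permute(flat, runs_idx)
    labs <- split(perm, runs_idx)
    accuracy(loro_cv_prepared(prep, cfg, optimize, labels = labs))
  })
  ci <- stats::quantile(null, c(alpha / 2, 1 - alpha / 2), names = FALSE)
  structure(list(statistic = observed, null = null, mean = mean(null),
                 ci = ci, n_permutations = n_perm, alpha = alpha,
                 exceeds_ci = observed > ci[2]),
            class = "permutation_null")
}

#' @export
print.permutation_null <- function(x, ...) {
  cat(sprintf(
    "<permutation_null> observed %.3f; guessing mean %.3f, %g%% CI [%.3f, %.3f] (%d permutations)\n",
    x$statistic, x$mean, 100 * (1 - x$alpha), x$ci[1], x$ci[2],
    x$n_permutations))
  invisible(x)
}

#' Per-voxel weight significance by permutation
#'
#' Trains one classifier per block-permuted label vector on a fixed feature
#' matrix and records every voxel's weight, giving each voxel a null
#' distribution of weights obtainable without label knowledge. The p-value
#' is `p_w(k) = #\{perm : |w_perm,k| >= |w_obs,k|\} / n_perm` (ties count
#' as exceeding; absolute weights, since the sign of an SVM weight is hard
#' to interpret). Weight vectors are normalised to unit length before the
#' comparison: a maximum-margin weight norm scales inversely with class
#' separability, so raw magnitudes of an informative fit and of permuted
#' fits are not on a common scale -- the normalised weight measures each
#' voxel's relative contribution to the separating direction.
#'
#' @param x Matrix, samples x voxels (e.g. pooled reduced group data).
#' @param y Labels.
#' @param n_perm Number of permutations (1000 in the full protocol).
#' @param C SVM cost.
#' @param runs Optional run/subject grouping passed to [block_permute()].
#' @param seed Optional seed.
#' @return A `weight_significance` list: `p_w` (per voxel), `w_obs`,
#'   `n_permutations`.
#' @export
weight_significance <- function(x, y, n_perm = 1000, C = 1, runs = NULL,
                                seed = NULL) {
  if (!is.null(seed))
    return(with_preserved_seed(seed,
      weight_significance(x, y, n_perm, C, runs)))
  y <- normalize_labels(y)
  unit <- function(w) w / max(sqrt(sum(w^2)), .Machine$double.eps)
  w_obs <- unit(train_linear_svm(x, y, C = C)$w)
  exceed <- numeric(length(w_obs))
  for (i in seq_len(n_perm)) {
    wp <- unit(train_linear_svm(x, block_permute(y, runs), C = C)$w)
    exceed <- exceed + (abs(wp) >= abs(w_obs))
  }
  structure(list(p_w = exceed / n_perm, w_obs = w_obs,
                 n_permutations = n_perm),
            class = "weight_significance")
}

#' Conjunction mask over two weight-significance maps
#'
#' A voxel enters the mask iff its weight p-value is strictly below
#' `threshold` in *both* inputs (e.g. the offline and the online
#' experiment).
#'
#' @param sig_a,sig_b `weight_significance` objects or bare p-value
#'   vectors on aligned voxel grids.
#' @param threshold Strict upper bound on `p_w` (default 0.1).
#' @return Logical mask vector.
#' @export
conjunction_mask <- function(sig_a, sig_b, threshold = 0.1) {
  pa <- if (inherits(sig_a, "weight_significance")) sig_a$p_w else sig_a
  pb <- if (inherits(sig_b, "weight_significance")) sig_b$p_w else sig_b
  if (length(pa) != length(pb))
    stop("voxel grids do not match", call. = FALSE)
  pa < threshold & pb < threshold
}
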