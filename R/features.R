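#' Build the two-percept GLM design matrix
#'
#' One boxcar per perceptual state (1 while that percept is reported, else
#' 0), convolved with the canonical HRF and sampled at volume midpoints,
#' plus an intercept column. Used to estimate per-voxel BOLD amplitudes for
#' the two percepts, whose difference the univariate F test scores.
#'
#' @param timeline A [percept_timeline()].
#' @param n_volumes Number of volumes.
#' @param tr Repetition time in seconds.
#' @return Numeric matrix with columns `line`, `object`, `intercept`.
#' @export
build_design <- function(timeline, n_volumes, tr) {
  if (length(unique(timeline$state)) < 2L)
    stop("degenerate design: timeline contains a single percept state",
         call. = FALSE)
  cbind(line = state_response(timeline, tr, n_volumes, state = "LINE"),
        object = state_response(timeline, tr, n_volumes, state = "OBJECT"),
        intercept = 1)
}

#' Univariate GLM-contrast F scores per voxel
#'
#' Ordinary least squares of each voxel's time series on the design, then
#' the F statistic for the single-degree contrast
#' `beta_object - beta_line = 0` with `(1, T - 3)` degrees of freedom
#' (equal to the squared contrast t; identical to a two-condition ANOVA).
#'
#' @param x Matrix, volumes x voxels (filtered/centred series).
#' @param design Design matrix from [build_design()] (rows must match `x`).
#' @return Tibble with columns `voxel`, `f`, `p`.
#' @export
univariate_scores <- function(x, design) {
  stopifnot(is.matrix(x), nrow(x) == nrow(design))
  if (nrow(x) <= ncol(design))
    stop("need more volumes than design columns", call. = FALSE)
  if (qr(design)$rank < ncol(design))
    stop("degenerate design: design matrix is rank deficient", call. = FALSE)
  xtx_inv <- solve(crossprod(design))
  beta <- xtx_inv %*% crossprod(design, x)
  res <- x - design %*% beta
  df2 <- nrow(x) - ncol(design)
  sigma2 <- colSums(res^2) / df2
  cvec <- c(-1, 1, 0)
  cb <- drop(crossprod(cvec, beta))
  cvar <- drop(crossprod(cvec, xtx_inv %*% cvec)) * sigma2
  f <- ifelse(cvar > 0, cb^2 / cvar, 0)
  tibble::tibble(voxel = seq_len(ncol(x)), f = f,
                 p = stats::pf(f, 1, df2, lower.tail = FALSE))
}

#' Class-difference F scores for labelled samples
#'
#' One-way two-group ANOVA F per voxel (squared pooled two-sample t,
#' df `(1, n - 2)`), for sample matrices that carry class labels rather
#' than a time-series design (e.g. interval-centre reduced data).
#'
#' @param x Matrix, samples x voxels.
#' @param y Character or factor labels with exactly two levels.
#' @return Tibble with columns `voxel`, `f`, `p`.
#' @export
class_f_scores <- function(x, y) {
  y <- as.character(y)
  lev <- unique(y)
  stopifnot(is.matrix(x), length(y) == nrow(x), length(lev) == 2L)
  i1 <- y == lev[1L]
  n1 <- sum(i1); n2 <- sum(!i1)
  m1 <- colMeans(x[i1, , drop = FALSE])
  m2 <- colMeans(x[!i1, , drop = FALSE])
  v1 <- colSums(sweep(x[i1, , drop = FALSE], 2L, m1)^2)
  v2 <- colSums(sweep(x[!i1, , drop = FALSE], 2L, m2)^2)
  df2 <- n1 + n2 - 2L
  sp2 <- (v1 + v2) / df2
  denom <- sp2 * (1 / n1 + 1 / n2)
  f <- ifelse(denom > 0, (m1 - m2)^2 / denom, 0)
  tibble::tibble(voxel = seq_len(ncol(x)), f = f,
                 p = stats::pf(f, 1, df2, lower.tail = FALSE))
}

#' Retain the k most discriminative voxels
#'
#' Keeps the `k` voxels with the smallest p-values; ties are broken by
#' larger F, then by lower voxel index. If fewer than `k` voxels are
#' available all are returned with a warning.
#'
#' @param scores Tibble from [univariate_scores()] or [class_f_scores()].
#' @param k Number of voxels to retain (offline default 5000; initial
#'   online selection 10000; cross-subject maps 30000).
#' @return Integer vector of selected voxel indices, best first.
#' @export
select_top_k <- function(scores, k) {
  stopifnot(k >= 1)
  ord <- order(scores$p, -scores$f, scores$voxel)
  if (k > nrow(scores)) {
    warning("only ", nrow(scores), " voxels available; requested ", k)
    k <- nrow(scores)
  }
  scores$voxel[ord[seq_len(k)]]
}

#' Multivariate refinement of a feature set
#'
#' After a first classifier pass, keep only voxels whose absolute weight
#' exceeds `threshold_factor * max |w|` (strict), i.e. the features that
#' carry appreciable discriminative load.
#'
#' @param model A fitted linear model (see [train_linear_svm()]).
#' @param threshold_factor Fraction of the maximum absolute weight
#'   (default 0.1).
#' @return Integer vector of retained voxel indices (a subset of
#'   `model$voxel_indices`).
#' @export
multivariate_refine <- function(model, threshold_factor = 0.1) {
  stopifnot(threshold_factor > 0, threshold_factor < 1)
  aw <- abs(model$w)
  if (max(aw) == 0)
    stop("empty selection: all classifier weights are zero", call. = FALSE)
  model$voxel_indices[aw > threshold_factor * max(aw)]
}
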