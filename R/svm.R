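#' Train the linear maximum-margin percept classifier
#'
#' Soft-margin linear SVM (via libsvm) mapping voxel patterns to percepts.
#' The decision function is `f(x) = w . x + b`; predicted percept is
#' `OBJECT` when `f(x) >= 0` and `LINE` otherwise (an exact 0 maps to
#' `OBJECT` by convention). Features enter as centred signal change without
#' further standardisation.
#'
#' @param x Matrix, samples x features.
#' @param y Labels, `"LINE"`/`"OBJECT"` (or -1/+1).
#' @param C Soft-margin cost (default 1).
#' @param voxel_indices Optional map from feature columns back to grid
#'   voxel indices.
#' @return A list of class `linear_percept_model` with `w`, `b`, `C`,
#'   `voxel_indices`, `n_samples`.
#' @export
train_linear_svm <- function(x, y, C = 1, voxel_indices = seq_len(ncol(x))) {
  stopifnot(is.matrix(x), nrow(x) >= 2, all(is.finite(x)), C > 0,
            length(voxel_indices) == ncol(x))
  y <- normalize_labels(y)
  if (length(unique(y)) < 2L)
    stop("invalid training set: both percept classes must be present",
         call. = FALSE)
  fit <- e1071::svm(x, factor(y, levels = c("LINE", "OBJECT")),
                    kernel = "linear", cost = C, scale = FALSE)
  w <- drop(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  # Orient the hyperplane so positive decision values mean OBJECT,
  # regardless of libsvm's internal class ordering.
  dec <- drop(x %*% w) + b
  pred <- as.character(stats::predict(fit, x))
  agree <- mean((dec >= 0) == (pred == "OBJECT"))
  if (agree < 0.5) { w <- -w; b <- -b }
  structure(
    list(w = unname(w), b = unname(b), C = C,
         voxel_indices = as.integer(voxel_indices), n_samples = nrow(x)),
    class = "linear_percept_model"
  )
}

normalize_labels <- function(y) {
  y <- as.character(y)
  y[y %in% c("1", "+1")] <- "OBJECT"
  y[y == "-1"] <- "LINE"
  if (!all(y %in% c("LINE", "OBJECT")))
    stop("labels must be LINE/OBJECT (or -1/+1)", call. = FALSE)
  y
}

#' Predict percepts from voxel patterns
#'
#' Applies the sign rule `y = sign(w . x + b)` and also returns the raw
#' decision value (the signed distance to the separating hyperplane, up to
#' the norm of `w`), useful for time-course diagnostics.
#'
#' @param model A `linear_percept_model`.
#' @param x Matrix (samples x features) or a single feature vector.
#' @return Tibble with columns `decision` and `label`.
#' @export
predict_percept <- function(model, x) {
  stopifnot(inherits(model, "linear_percept_model"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (ncol(x) != length(model$w))
    stop("feature dimension (", ncol(x), ") does not match model (",
         length(model$w), ")", call. = FALSE)
  dec <- drop(x %*% model$w) + model$b
  tibble::tibble(decision = dec,
                 label = ifelse(dec >= 0, "OBJECT", "LINE"))
}

#' @export
print.linear_percept_model <- function(x, ...) {
  cat(sprintf("<linear_percept_model> %d features, C = %g, |w| = %.4g, b = %.4g\n",
              length(x$w), x$C, sqrt(sum(x$w^2)), x$b))
  invisible(x)
}
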