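#' Offline decoding configuration
#'
#' Bundles every tunable of the offline leave-one-run-out pipeline:
#' the retention size of the univariate selection (5000 voxels by default),
#' the SVM cost, the candidate low-pass cutoffs optimised inside each
#' training fold (1/27, 1/18, 1/12, 1/8 Hz), the fixed 1/128 Hz high-pass,
#' the haemodynamic label shift (5 s), the vascular exclusion threshold
#' (10% signal change), and optional spatial smoothing.
#'
#' @param k_select Number of voxels retained by univariate selection.
#' @param C SVM soft-margin cost.
#' @param lowpass_candidates Candidate low-pass cutoffs in Hz; a single
#'   value disables in-fold optimisation.
#' @param highpass High-pass cutoff in Hz.
#' @param filter_order Overall Butterworth band-pass order.
#' @param hrf_delay Label shift in seconds.
#' @param signal_change_threshold Fractional exclusion threshold.
#' @param smooth_fwhm,voxel_size_mm Spatial smoothing FWHM and voxel size
#'   in mm (`smooth_fwhm = 0` disables smoothing).
#' @param score_method `"glm"` scores voxels by the HRF-regressor contrast
#'   F; `"anova"` scores defined-label samples by the class-difference F
#'   (used by the permutation null, where shuffled labels define no
#'   timeline).
#' @return A list of class `decode_config`.
#' @export
decode_config <- function(k_select = 5000, C = 1,
                          lowpass_candidates = c(1 / 27, 1 / 18, 1 / 12, 1 / 8),
                          highpass = 1 / 128, filter_order = 4,
                          hrf_delay = 5, signal_change_threshold = 0.10,
                          smooth_fwhm = 0, voxel_size_mm = 3,
                          score_method = c("glm", "anova")) {
  structure(list(
    k_select = k_select, C = C,
    lowpass_candidates = sort(lowpass_candidates), highpass = highpass,
    filter_order = filter_order, hrf_delay = hrf_delay,
    signal_change_threshold = signal_change_threshold,
    smooth_fwhm = smooth_fwhm, voxel_size_mm = voxel_size_mm,
    score_method = match.arg(score_method)
  ), class = "decode_config")
}

# Preprocess a session once for every candidate cutoff: smoothing,
# vascular exclusion (on raw data, intersected across runs), per-run
# zero-centring and zero-phase band-pass filtering, per-run labels and
# GLM designs. Folds then reuse these matrices; filtering and exclusion
# are label-free so no information leaks across folds.
prepare_decoding <- function(session, cfg) {
  runs <- session$runs
  mats_raw <- purrr::map(runs, function(r) {
    d <- if (cfg$smooth_fwhm > 0)
      smooth_spatial(r$data, cfg$smooth_fwhm, cfg$voxel_size_mm) else r$data
    t(matrix(d, nrow = prod(dim(d)[1:3]), ncol = dim(d)[4]))
  })
  retained <- Reduce(intersect, purrr::map(
    mats_raw, ~ exclude_high_signal_change(.x, cfg$signal_change_threshold)$retained))
  mats_raw <- purrr::map(mats_raw, ~ .x[, retained, drop = FALSE])
  filtered <- purrr::map(cfg$lowpass_candidates, function(lp) {
    fc <- filter_config(cfg$highpass, lp, cfg$filter_order, "zero_phase")
    purrr::map(mats_raw, ~ bandpass(zero_center(.x)$x, session$tr, fc))
  })
  names(filtered) <- format(cfg$lowpass_candidates)
  labels <- purrr::map(runs, ~ labels_per_volume(.x$timeline, n_volumes(.x),
                                                 session$tr, cfg$hrf_delay))
  designs <- purrr::map(runs, ~ build_design(.x$timeline, n_volumes(.x),
                                             session$tr))
  list(filtered = filtered, labels = labels, designs = designs,
       retained = retained, tr = session$tr, n_runs = length(runs))
}

# Feature selection + training on `train_runs`, prediction of the defined
# volumes of `test_run`, at a given cutoff index. `labels` may be a
# permuted override.
fold_predict <- function(prep, train_runs, test_run, cutoff_idx, cfg,
                         labels = prep$labels) {
  mats <- prep$filtered[[cutoff_idx]]
  xtr <- do.call(rbind, mats[train_runs])
  ytr_full <- unlist(labels[train_runs])
  def <- !is.na(ytr_full)
  sel <- if (!is.null(cfg$frozen_features)) {
    cfg$frozen_features
  } else {
    scores <- if (cfg$score_method == "glm" && identical(labels, prep$labels)) {
      univariate_scores(xtr, do.call(rbind, prep$designs[train_runs]))
    } else {
      class_f_scores(xtr[def, , drop = FALSE], ytr_full[def])
    }
    suppressWarnings(select_top_k(scores, cfg$k_select))
  }
  model <- train_linear_svm(xtr[def, sel, drop = FALSE], ytr_full[def],
                            C = cfg$C, voxel_indices = prep$retained[sel])
  yte <- labels[[test_run]]
  keep <- which(!is.na(yte))
  pred <- predict_percept(model, mats[[test_run]][keep, sel, drop = FALSE])
  tibble::tibble(run = test_run, volume = keep, truth = yte[keep],
                 predicted = pred$label, decision = pred$decision)
}

# Mean leave-one-run-out error over `runs` at one cutoff (inner CV and
# permutation machinery).
cv_error <- function(prep, runs, cutoff_idx, cfg, labels = prep$labels) {
  errs <- purrr::map_dbl(runs, function(r) {
    out <- fold_predict(prep, setdiff(runs, r), r, cutoff_idx, cfg, labels)
    mean(out$predicted != out$truth)
  })
  mean(errs)
}

#' Optimise the low-pass cutoff on training runs
#'
#' For each candidate cutoff, runs an inner leave-one-run-out
#' cross-validation restricted to the given training runs and returns the
#' cutoff with the smallest mean classification error; ties resolve to the
#' lowest cutoff (strongest smoothing).
#'
#' @param session A `percept_session`.
#' @param cfg A [decode_config()].
#' @param runs Indices of the training runs (>= 2).
#' @return Chosen cutoff in Hz (an element of `cfg$lowpass_candidates`).
#' @export
optimize_lowpass <- function(session, cfg = decode_config(), runs = NULL) {
  if (is.null(runs)) runs <- seq_along(session$runs)
  stopifnot(length(runs) >= 2)
  prep <- prepare_decoding(session, cfg)
  idx <- choose_cutoff(prep, runs, cfg)
  cfg$lowpass_candidates[idx]
}

choose_cutoff <- function(prep, runs, cfg, labels = prep$labels) {
  if (length(cfg$lowpass_candidates) == 1L || length(runs) < 2L) return(1L)
  errs <- purrr::map_dbl(seq_along(cfg$lowpass_candidates),
                         ~ cv_error(prep, runs, .x, cfg, labels))
  which(errs <= min(errs) + 1e-12)[1L] # candidates sorted ascending: tie -> lowest Hz
}

#' Leave-one-run-out decoding of a session
#'
#' For every fold, feature selection, low-pass-cutoff optimisation and
#' classifier training use only the training runs; every defined-label
#' volume of the held-out run is then predicted. Returns per-volume
#' predictions with decision values plus per-fold and pooled accuracy.
#'
#' @param session A `percept_session` with at least 3 runs.
#' @param cfg A [decode_config()].
#' @param optimize Logical; optimise the low-pass cutoff per fold (default
#'   `TRUE` when more than one candidate is configured).
#' @return A `decoding_result`: tibble of per-volume predictions (`run`,
#'   `volume`, `truth`, `predicted`, `decision`) with attributes
#'   `fold_accuracy` (tibble) and `accuracy` (pooled).
#' @export
loro_cv <- function(session, cfg = decode_config(), optimize = TRUE) {
  if (length(session$runs) < 3L)
    stop("invalid session: leave-one-run-out decoding needs >= 3 runs",
         call. = FALSE)
  prep <- prepare_decoding(session, cfg)
  loro_cv_prepared(prep, cfg, optimize)
}

loro_cv_prepared <- function(prep, cfg, optimize = TRUE,
                             labels = prep$labels) {
  runs <- seq_len(prep$n_runs)
  folds <- purrr::map(runs, function(r) {
    tr_runs <- setdiff(runs, r)
    ci <- if (optimize) choose_cutoff(prep, tr_runs, cfg, labels) else 1L
    out <- fold_predict(prep, tr_runs, r, ci, cfg, labels)
    out$cutoff_hz <- cfg$lowpass_candidates[ci]
    out
  })
  res <- dplyr::bind_rows(folds)
  fold_acc <- res |>
    dplyr::group_by(.data$run) |>
    dplyr::summarise(accuracy = mean(.data$predicted == .data$truth),
                     cutoff_hz = .data$cutoff_hz[1], .groups = "drop")
  structure(res,
            fold_accuracy = fold_acc,
            accuracy = mean(res$predicted == res$truth),
            class = c("decoding_result", class(res)))
}

#' @export
accuracy <- function(x) attr(x, "accuracy")
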