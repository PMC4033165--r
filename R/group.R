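#' Reduce a session to interval-centre samples
#'
#' For cross-subject analyses whole sessions are too large and
#' switch-adjacent volumes are unreliable, so each sustained-percept
#' interval contributes a single sample: the mean of the three volumes
#' centred on the interval's middle defined-label volume (even-length
#' intervals centre on the earlier middle; intervals spanning fewer than
#' three defined volumes contribute what they have).
#'
#' @param session A `percept_session`.
#' @param cfg A [decode_config()]; preprocessing uses its first (lowest)
#'   low-pass candidate.
#' @return A `reduced_data` list: `x` (samples x retained voxels), `y`,
#'   `run`, `interval_len` (defined volumes per interval), `retained`
#'   (grid indices of the columns of `x`), `grid_size`, `subject_id`.
#' @export
reduce_to_interval_centers <- function(session, cfg = decode_config()) {
  cfg$lowpass_candidates <- cfg$lowpass_candidates[1L]
  prep <- prepare_decoding(session, cfg)
  rows <- list(); y <- character(); runv <- integer(); ilen <- integer()
  for (r in seq_len(prep$n_runs)) {
    lab <- prep$labels[[r]]
    def <- which(!is.na(lab))
    blocks <- rle(lab[def])
    ends <- cumsum(blocks$lengths)
    starts <- ends - blocks$lengths + 1L
    for (b in seq_along(starts)) {
      len <- blocks$lengths[b]
      centre <- starts[b] + floor((len + 1) / 2) - 1L
      pick <- def[max(starts[b], centre - 1L):min(ends[b], centre + 1L)]
      rows[[length(rows) + 1L]] <-
        colMeans(prep$filtered[[1L]][[r]][pick, , drop = FALSE])
      y <- c(y, blocks$values[b])
      runv <- c(runv, r)
      ilen <- c(ilen, len)
    }
  }
  structure(list(x = do.call(rbind, rows), y = y, run = runv,
                 interval_len = ilen, retained = prep$retained,
                 grid_size = prod(session$grid_shape),
                 subject_id = session$seed),
            class = "reduced_data")
}

# Leave-one-run-out accuracy over reduced samples (the per-subject
# classification rate p_hat entering the group combination).
reduced_loro_accuracy <- function(reduced, k = 30000, C = 1) {
  runs <- unique(reduced$run)
  if (length(runs) < 2L) return(NA_real_)
  correct <- 0L; total <- 0L
  for (r in runs) {
    tr_i <- reduced$run != r
    if (length(unique(reduced$y[tr_i])) < 2L) next
    sel <- suppressWarnings(select_top_k(
      class_f_scores(reduced$x[tr_i, , drop = FALSE], reduced$y[tr_i]), k))
    m <- train_linear_svm(reduced$x[tr_i, sel, drop = FALSE],
                          reduced$y[tr_i], C = C)
    pred <- predict_percept(m, reduced$x[!tr_i, sel, drop = FALSE])
    correct <- correct + sum(pred$label == reduced$y[!tr_i])
    total <- total + sum(!tr_i)
  }
  correct / total
}

#' Per-subject weight map on the common grid
#'
#' Selects the `k` voxels with the lowest class-difference F p-values from
#' the subject's reduced samples, trains a linear classifier on them, and
#' embeds the weights into the common voxel grid (zero elsewhere). The
#' subject's own leave-one-run-out accuracy `p_hat` accompanies the map as
#' its reliability weight.
#'
#' @param reduced A `reduced_data` object.
#' @param k Univariate retention size (30000 in the full protocol).
#' @param C SVM cost.
#' @param p_hat Optional precomputed classification rate; computed by
#'   leave-one-run-out on the reduced samples when `NULL`.
#' @return A `subject_map` list: `w` (length `grid_size`), `p_hat`,
#'   `subject_id`.
#' @export
subject_weight_map <- function(reduced, k = 30000, C = 1, p_hat = NULL) {
  stopifnot(inherits(reduced, "reduced_data"))
  sel <- suppressWarnings(select_top_k(class_f_scores(reduced$x, reduced$y), k))
  model <- train_linear_svm(reduced$x[, sel, drop = FALSE], reduced$y, C = C)
  w <- numeric(reduced$grid_size)
  w[reduced$retained[sel]] <- model$w
  if (is.null(p_hat)) p_hat <- reduced_loro_accuracy(reduced, k, C)
  stopifnot(p_hat >= 0, p_hat <= 1)
  structure(list(w = w, p_hat = p_hat, subject_id = reduced$subject_id),
            class = "subject_map")
}

#' Combine subject weight maps into a group map
#'
#' Accuracy-weighted average: `w_bar_k = (1/n) sum_i 2 (p_hat_i - 1/2)
#' w_i_k`. A subject at chance (`p_hat = 0.5`) contributes nothing; a
#' below-chance subject contributes with flipped sign.
#'
#' @param maps List of `subject_map` objects on a common grid.
#' @return A `group_map` list: `w_bar`, `n`, `p_hat` (per subject).
#' @export
combine_weight_maps <- function(maps) {
  stopifnot(length(maps) >= 1,
            all(purrr::map_lgl(maps, inherits, "subject_map")))
  sizes <- purrr::map_int(maps, ~ length(.x$w))
  if (length(unique(sizes)) != 1L)
    stop("subject maps are not on a common voxel grid", call. = FALSE)
  w_bar <- Reduce(`+`, purrr::map(maps, ~ 2 * (.x$p_hat - 0.5) * .x$w)) /
    length(maps)
  structure(list(w_bar = w_bar, n = length(maps),
                 p_hat = purrr::map_dbl(maps, "p_hat")),
            class = "group_map")
}

#' Leave-one-subject-out transfer decoding
#'
#' Per fold: build the training subjects' weight maps, combine them by
#' accuracy weighting, select the `k_select` highest-|weight| voxels of the
#' combined map, train a fresh classifier on the pooled training subjects'
#' reduced samples restricted to those voxels, and score the held-out
#' subject's reduced samples. The held-out subject's data is never touched
#' during map building, combination or selection.
#'
#' @param subjects List (>= 3) of `reduced_data` objects on a common grid.
#' @param k_select Voxels retained from the combined map (30000 in the
#'   full protocol).
#' @param C SVM cost.
#' @return Tibble with one row per held-out subject: `subject`, `accuracy`
#'   (all reduced samples), `accuracy_away` (intervals spanning >= 3
#'   defined volumes only), `n_samples`. Attribute `predictions` holds the
#'   per-sample predictions.
#' @export
loso_cv <- function(subjects, k_select = 30000, C = 1) {
  if (length(subjects) < 3L)
    stop("leave-one-subject-out transfer needs >= 3 subjects", call. = FALSE)
  stopifnot(all(purrr::map_lgl(subjects, inherits, "reduced_data")))
  gsz <- unique(purrr::map_int(subjects, ~ as.integer(.x$grid_size)))
  if (length(gsz) != 1L)
    stop("subjects are not on a common voxel grid", call. = FALSE)
  embed <- function(red, cols) {
    # reduced samples expressed on grid columns `cols` (0 where a voxel
    # was excluded for that subject)
    out <- matrix(0, nrow(red$x), length(cols))
    hit <- match(cols, red$retained)
    ok <- !is.na(hit)
    out[, ok] <- red$x[, hit[ok], drop = FALSE]
    out
  }
  preds <- list()
  rows <- purrr::imap(subjects, function(test, i) {
    train_idx <- setdiff(seq_along(subjects), i)
    maps <- purrr::map(subjects[train_idx], subject_weight_map,
                       k = k_select, C = C)
    group <- combine_weight_maps(maps)
    nz <- which(group$w_bar != 0)
    sel <- nz[order(-abs(group$w_bar[nz]))]
    sel <- sel[seq_len(min(k_select, length(sel)))]
    xtr <- do.call(rbind, purrr::map(subjects[train_idx], embed, cols = sel))
    ytr <- unlist(purrr::map(subjects[train_idx], "y"))
    model <- train_linear_svm(xtr, ytr, C = C, voxel_indices = sel)
    pred <- predict_percept(model, embed(test, sel))
    away <- test$interval_len >= 3L
    preds[[i]] <<- tibble::tibble(subject = test$subject_id,
                                  truth = test$y, predicted = pred$label,
                                  decision = pred$decision, away = away)
    tibble::tibble(
      subject = test$subject_id,
      accuracy = mean(pred$label == test$y),
      accuracy_away = mean(pred$label[away] == test$y[away]),
      n_samples = nrow(test$x))
  })
  structure(dplyr::bind_rows(rows),
            predictions = dplyr::bind_rows(preds),
            class = c("loso_result", "tbl_df", "tbl", "data.frame"))
}
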