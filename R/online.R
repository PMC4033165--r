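#' Online decoding configuration
#'
#' Settings for the simulated real-time loop: initial univariate retention
#' (10000 voxels), multivariate refinement factor (0.1 of the maximum
#' absolute weight), the causal order-4 Butterworth band-pass
#' (1/128--1/16 Hz), the haemodynamic label shift, and the processing
#' latency recorded as metadata.
#'
#' A causal filter delays the signal it passes; `filter_delay` is the extra
#' lag (seconds) added to the haemodynamic shift when aligning labels with
#' causally filtered features, for both retraining and scoring. When `NULL`
#' it is computed as the filter's phase delay at the session's dominant
#' percept-alternation frequency, estimated from the training runs'
#' reports (see [filter_phase_delay()]).
#'
#' Because the real-time loop trains on only two runs in a feature space of
#' comparable dimension, the SVM cost is not fixed a priori: initial
#' training picks it from `C_candidates` by two-fold cross-validation
#' between the training runs (train on one, validate on the other, with
#' feature selection inside the fold), the same in-training-set
#' optimisation pattern the offline pipeline uses for its low-pass cutoff.
#' Set `C_candidates` to a single value to fix the cost.
#'
#' @param k_initial Voxels retained by the initial univariate selection.
#' @param refine_factor Threshold factor of [multivariate_refine()].
#' @param C_candidates SVM cost grid searched during initial training;
#'   ties resolve to the smaller (more regularised) cost.
#' @param highpass,lowpass,filter_order Causal band-pass parameters.
#' @param hrf_delay Haemodynamic label shift in seconds.
#' @param filter_delay Extra causal-filter delay in seconds, or `NULL`
#'   (auto).
#' @param signal_change_threshold Vascular exclusion threshold.
#' @param processing_delay_s Metadata-only processing latency in seconds
#'   (never measured from the host clock).
#' @return A list of class `online_config`.
#' @export
online_config <- function(k_initial = 10000, refine_factor = 0.1,
                          C_candidates = 10^seq(-4, 0),
                          highpass = 1 / 128, lowpass = 1 / 16,
                          filter_order = 4, hrf_delay = 5,
                          filter_delay = NULL,
                          signal_change_threshold = 0.10,
                          processing_delay_s = 4.3) {
  structure(list(
    k_initial = k_initial, refine_factor = refine_factor,
    C_candidates = sort(C_candidates),
    highpass = highpass, lowpass = lowpass, filter_order = filter_order,
    hrf_delay = hrf_delay, filter_delay = filter_delay,
    signal_change_threshold = signal_change_threshold,
    processing_delay_s = processing_delay_s
  ), class = "online_config")
}

online_filter_config <- function(cfg) {
  filter_config(cfg$highpass, cfg$lowpass, cfg$filter_order, "causal")
}

# Label delay used throughout the online pipeline: HRF shift plus the
# causal filter's phase delay at the percept alternation fundamental
# (one alternation cycle = two mean dwells). For the default band-pass the
# fundamental sits near band centre, where the phase delay is small.
online_label_delay <- function(cfg, tr, mean_dwell) {
  fd <- cfg$filter_delay
  if (is.null(fd)) {
    # clamp the fundamental into the passband: outside it the phase-delay
    # model does not describe what the filter passes
    f0 <- min(max(1 / (2 * mean_dwell), cfg$highpass), cfg$lowpass)
    fd <- filter_phase_delay(online_filter_config(cfg), tr, f0)
  }
  max(cfg$hrf_delay + fd, 0)
}

#' Initial training of the online decoder
#'
#' Uses the first two runs: the vascular exclusion rule is applied, voxel
#' baselines are stored for later subtraction, both runs are causally
#' band-pass filtered, the top `k_initial` voxels by class-difference F are
#' selected, a first classifier is trained, the feature set is refined to
#' voxels with `|w| > 0.1 max|w|`, and the classifier is retrained on the
#' refined set. The feature set is then frozen for the rest of the session.
#' No predictions are emitted for runs 1--2.
#'
#' @param session A `percept_session` with at least 2 runs.
#' @param cfg An [online_config()].
#' @return An `online_state` list: `model`, `baseline`, `feature_set`,
#'   `retained`, `filter`, `label_delay`, `completed_runs`, `last_label`,
#'   streaming filter state.
#' @export
initial_training <- function(session, cfg = online_config()) {
  stopifnot(length(session$runs) >= 2)
  tr <- session$tr
  raw <- purrr::map(session$runs[1:2], run_matrix)
  retained <- Reduce(intersect, purrr::map(
    raw, ~ exclude_high_signal_change(.x, cfg$signal_change_threshold)$retained))
  raw <- purrr::map(raw, ~ .x[, retained, drop = FALSE])
  baseline <- colMeans(do.call(rbind, raw))
  fc <- online_filter_config(cfg)
  filt <- purrr::map(raw, ~ bandpass(zero_center(.x, baseline)$x, tr, fc))
  mean_dwell <- mean(unlist(purrr::map(session$runs[1:2],
                                       ~ .x$timeline$duration)))
  label_delay <- online_label_delay(cfg, tr, mean_dwell)
  labels <- purrr::map(session$runs[1:2],
                       ~ labels_per_volume(.x$timeline, n_volumes(.x), tr,
                                           label_delay))
  x <- do.call(rbind, filt)
  y <- unlist(labels)
  def <- !is.na(y)
  if (length(unique(y[def])) < 2L)
    stop("invalid training set: first two runs contain a single percept class",
         call. = FALSE)
  C <- select_online_cost(filt, labels, cfg)
  scores <- class_f_scores(x[def, , drop = FALSE], y[def])
  sel <- suppressWarnings(select_top_k(scores, cfg$k_initial))
  first_pass <- train_linear_svm(x[def, sel, drop = FALSE], y[def],
                                 C = C, voxel_indices = sel)
  feature_set <- multivariate_refine(first_pass, cfg$refine_factor)
  model <- train_linear_svm(x[def, feature_set, drop = FALSE], y[def],
                            C = C,
                            voxel_indices = retained[feature_set])
  co <- butter_coefs(fc, tr)
  structure(list(
    model = model, baseline = baseline, feature_set = feature_set,
    retained = retained, coefs = co, tr = tr, cfg = cfg, C = C,
    label_delay = label_delay, completed_runs = 2L,
    last_label = NULL,
    filter_state = iir_state_init(co$b, co$a, length(feature_set))
  ), class = "online_state")
}

# Two-fold cross-run selection of the SVM cost: train on one training run,
# validate on the other (feature selection inside the fold); ties go to the
# smaller cost.
select_online_cost <- function(filt, labels, cfg) {
  cands <- cfg$C_candidates
  if (length(cands) == 1L) return(cands)
  val <- purrr::map_dbl(cands, function(C) {
    mean(purrr::map_dbl(1:2, function(i) {
      j <- 3L - i
      yi <- labels[[i]]; yj <- labels[[j]]
      di <- !is.na(yi); dj <- !is.na(yj)
      if (length(unique(yi[di])) < 2L) return(NA_real_)
      sel <- suppressWarnings(select_top_k(
        class_f_scores(filt[[i]][di, , drop = FALSE], yi[di]),
        cfg$k_initial))
      m <- train_linear_svm(filt[[i]][di, sel, drop = FALSE], yi[di], C = C)
      mean(predict_percept(m, filt[[j]][dj, sel, drop = FALSE])$label ==
             yj[dj])
    }), na.rm = TRUE)
  })
  cands[which(val >= max(val) - 1e-12)[1L]]
}

#' Reset the streaming filter at a run boundary
#'
#' @param state An `online_state`.
#' @return The state with a fresh causal-filter state.
#' @export
start_run <- function(state) {
  state$filter_state <- iir_state_init(state$coefs$b, state$coefs$a,
                                       length(state$feature_set))
  state
}

#' Process one incoming volume
#'
#' Subtracts the stored baseline, advances the causal band-pass by one
#' sample for the frozen feature set, applies the sign rule, and emits a
#' switch event iff the predicted percept differs from the previous
#' prediction (the first prediction after initial training emits none).
#'
#' @param state An `online_state`.
#' @param volume Numeric vector over the full voxel grid.
#' @return List with `state` (updated), `label`, `decision`, and `event`
#'   (`NULL` or a one-row tibble `volume`/`run` left to the caller,
#'   `new_label`, `decision`).
#' @export
process_volume <- function(state, volume) {
  stopifnot(inherits(state, "online_state"))
  if (length(volume) < max(state$retained))
    stop("volume shape does not match the training grid", call. = FALSE)
  v <- volume[state$retained][state$feature_set] -
    state$baseline[state$feature_set]
  step <- iir_step(state$filter_state, v)
  state$filter_state <- step$state
  pred <- predict_percept(state$model, step$y)
  ev <- NULL
  if (!is.null(state$last_label) && pred$label != state$last_label)
    ev <- tibble::tibble(new_label = pred$label, decision = pred$decision)
  state$last_label <- pred$label
  list(state = state, label = pred$label, decision = pred$decision,
       event = ev)
}

#' Retrain the online classifier after a completed run
#'
#' Retrains on all completed runs using the frozen refined feature set, the
#' stored baselines, causal filtering with state reset at run boundaries,
#' and delay-shifted reported labels. Deterministic: identical data yields
#' an identical model.
#'
#' @param state An `online_state`.
#' @param session The `percept_session` providing the completed runs.
#' @param completed Number of completed runs (defaults to
#'   `state$completed_runs`).
#' @return Updated `online_state`.
#' @export
retrain_after_run <- function(state, session, completed = state$completed_runs) {
  stopifnot(completed >= 2)
  tr <- state$tr
  fc <- online_filter_config(state$cfg)
  xs <- purrr::map(session$runs[seq_len(completed)], function(r) {
    m <- run_matrix(r)[, state$retained, drop = FALSE]
    bandpass(sweep(m, 2L, state$baseline), tr, fc)[, state$feature_set,
                                                   drop = FALSE]
  })
  ys <- purrr::map(session$runs[seq_len(completed)],
                   ~ labels_per_volume(.x$timeline, n_volumes(.x), tr,
                                       state$label_delay))
  x <- do.call(rbind, xs)
  y <- unlist(ys)
  def <- !is.na(y)
  state$model <- train_linear_svm(x[def, , drop = FALSE], y[def],
                                  C = state$C,
                                  voxel_indices = state$model$voxel_indices)
  state$completed_runs <- as.integer(completed)
  state
}

#' Simulate a full real-time decoding session
#'
#' Runs [initial_training()] on runs 1--2, then streams runs 3..N volume by
#' volume through [process_volume()], retraining after every completed run.
#' Accuracy is computed over defined-label volumes of runs 3..N against
#' reports shifted by the total delay (HRF + causal filter); the
#' HRF-only-aligned accuracy is also reported for reference.
#'
#' @param session A `percept_session` with at least 3 runs.
#' @param cfg An [online_config()].
#' @return An `online_result`: tibble of per-volume predictions (`run`,
#'   `volume`, `truth`, `predicted`, `decision`) with attributes `events`
#'   (tibble), `accuracy`, `accuracy_hrf_aligned`, `latency` (tibble of
#'   delay metadata) and `state` (final `online_state`).
#' @export
run_online_session <- function(session, cfg = online_config()) {
  if (length(session$runs) < 3L)
    stop("online decoding needs >= 3 runs", call. = FALSE)
  state <- initial_training(session, cfg)
  preds <- list()
  events <- list()
  for (r in seq(3L, length(session$runs))) {
    state <- start_run(state)
    run <- session$runs[[r]]
    m <- run_matrix(run)
    dec <- numeric(nrow(m)); lab <- character(nrow(m))
    for (t in seq_len(nrow(m))) {
      out <- process_volume(state, m[t, ])
      state <- out$state
      dec[t] <- out$decision; lab[t] <- out$label
      if (!is.null(out$event))
        events[[length(events) + 1L]] <-
          dplyr::mutate(out$event, run = r, volume = t, .before = 1L)
    }
    truth <- labels_per_volume(run$timeline, nrow(m), session$tr,
                               state$label_delay)
    preds[[length(preds) + 1L]] <- tibble::tibble(
      run = r, volume = seq_len(nrow(m)), truth = truth,
      predicted = lab, decision = dec)
    state <- retrain_after_run(state, session, completed = r)
  }
  res <- dplyr::bind_rows(preds)
  def <- !is.na(res$truth)
  hrf_truth <- unlist(purrr::map(seq(3L, length(session$runs)), function(r) {
    run <- session$runs[[r]]
    labels_per_volume(run$timeline, n_volumes(run), session$tr,
                      cfg$hrf_delay)
  }))
  structure(res,
            events = dplyr::bind_rows(events),
            accuracy = mean(res$predicted[def] == res$truth[def]),
            accuracy_hrf_aligned = mean(
              res$predicted[!is.na(hrf_truth)] ==
                hrf_truth[!is.na(hrf_truth)]),
            latency = tibble::tibble(
              tr_s = session$tr,
              hrf_delay_s = cfg$hrf_delay,
              filter_delay_s = state$label_delay - cfg$hrf_delay,
              processing_delay_s = cfg$processing_delay_s),
            state = state,
            class = c("online_result", class(res)))
}
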