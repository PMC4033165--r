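test_that("initial training freezes a refined feature set and emits nothing", {
  sess <- make_test_session(n_runs = 4, duration = 300, seed = 51)
  cfg <- online_config(k_initial = 60)
  st <- initial_training(sess, cfg)
  expect_s3_class(st, "online_state")
  expect_lte(length(st$feature_set), 60)
  expect_equal(st$completed_runs, 2L)
  expect_null(st$last_label)
  # most planted voxels survive into the refined set at high SNR
  planted <- c(sess$voxels$object_positive, sess$voxels$object_negative)
  grid_idx <- st$retained[st$feature_set]
  expect_gte(mean(planted %in% grid_idx), 0.8)
})

test_that("single-class training pairs are rejected", {
  sess <- make_test_session(n_runs = 2, duration = 120, seed = 52)
  for (i in 1:2) {
    tl <- percept_timeline(0, 120, "LINE", 120)
    sess$runs[[i]]$timeline <- tl
  }
  expect_error(initial_training(sess, online_config(k_initial = 30)),
               "single percept class")
})

test_that("switch events are exactly the sign changes of the prediction", {
  sess <- make_test_session(n_runs = 4, duration = 300, seed = 53)
  on <- run_online_session(sess, online_config(k_initial = 60))
  ev <- attr(on, "events")
  res <- tibble::as_tibble(on)
  flips <- 0L
  last <- NULL
  for (i in seq_len(nrow(res))) {
    if (!is.null(last) && res$predicted[i] != last) flips <- flips + 1L
    last <- res$predicted[i]
  }
  expect_equal(nrow(ev), flips)
  # consecutive events alternate labels within the stream
  expect_true(all(ev$new_label[-1] != ev$new_label[-nrow(ev)]))
})

test_that("the online loop is causal and deterministic", {
  sess <- make_test_session(n_runs = 3, duration = 200, seed = 54)
  cfg <- online_config(k_initial = 40)
  st <- initial_training(sess, cfg)
  m <- rtpercept:::run_matrix(sess$runs[[3]])
  # full pass
  s1 <- start_run(st)
  full <- numeric(nrow(m))
  for (t in seq_len(nrow(m))) {
    o <- process_volume(s1, m[t, ]); s1 <- o$state; full[t] <- o$decision
  }
  # prefix pass: outputs for the prefix are identical
  s2 <- start_run(st)
  half <- numeric(50)
  for (t in 1:50) {
    o <- process_volume(s2, m[t, ]); s2 <- o$state; half[t] <- o$decision
  }
  expect_equal(half, full[1:50], tolerance = 1e-12)
  # same seed, same session, same result
  on1 <- run_online_session(sess, cfg)
  on2 <- run_online_session(sess, cfg)
  expect_equal(tibble::as_tibble(on1), tibble::as_tibble(on2))
})

test_that("retraining is deterministic and keeps the feature space", {
  sess <- make_test_session(n_runs = 4, duration = 250, seed = 55)
  st <- initial_training(sess, online_config(k_initial = 40))
  r1 <- retrain_after_run(st, sess, completed = 3)
  r2 <- retrain_after_run(st, sess, completed = 3)
  expect_equal(r1$model$w, r2$model$w)
  expect_equal(length(r1$model$w), length(st$model$w))
  expect_equal(r1$completed_runs, 3L)
})

test_that("a constant volume stream settles to a single percept", {
  sess <- make_test_session(n_runs = 3, duration = 200, seed = 56)
  st <- start_run(initial_training(sess, online_config(k_initial = 40)))
  vol <- rep(100, prod(sess$grid_shape))
  labs <- character(60)
  for (t in 1:60) {
    o <- process_volume(st, vol); st <- o$state; labs[t] <- o$label
  }
  # after the filter settles the label never changes again
  expect_equal(length(unique(labs[30:60])), 1L)
})

test_that("online decoding tracks percepts from run 3 onward", {
  sess <- make_test_session(n_runs = 5, duration = 300, seed = 57)
  on <- run_online_session(sess, online_config(k_initial = 60))
  expect_setequal(unique(on$run), 3:5)
  expect_gt(accuracy(on), 0.65)
  sw <- switch_local_accuracy(on)
  expect_gt(sw$away_from_switch, sw$near_switch)
  # accuracy counts only defined-label volumes
  def <- !is.na(on$truth)
  expect_equal(accuracy(on), mean(on$predicted[def] == on$truth[def]))
  # latency ledger is metadata, not wall clock
  lat <- attr(on, "latency")
  expect_named(lat, c("tr_s", "hrf_delay_s", "filter_delay_s",
                      "processing_delay_s"))
  expect_equal(lat$processing_delay_s, 4.3)
})

test_that("per-run accuracy does not systematically degrade", {
  slopes <- purrr::map_dbl(1:5, function(s) {
    sess <- make_test_session(n_runs = 6, duration = 250, seed = 60 + s)
    on <- run_online_session(sess, online_config(k_initial = 60))
    acc <- tidy(on)
    unname(stats::coef(stats::lm(accuracy ~ run, data = acc))[2])
  })
  # mean slope across seeded sessions is not significantly negative
  expect_gt(mean(slopes), -0.02)
})
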