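# Brute-force oracle: minimise 0.5 |w|^2 + C * sum hinge over a grid of
# (w, b) for 2-feature toy sets.
hinge_objective <- function(w, b, x, y, C) {
  0.5 * sum(w^2) + C * sum(pmax(0, 1 - y * (drop(x %*% w) + b)))
}

grid_search_svm <- function(x, y, C, lim = 3, step = 0.05) {
  g <- seq(-lim, lim, by = step)
  best <- list(val = Inf)
  for (w1 in g) for (w2 in g) for (b in g) {
    v <- hinge_objective(c(w1, w2), b, x, y, C)
    if (v < best$val) best <- list(val = v, w = c(w1, w2), b = b)
  }
  best
}

test_that("training agrees with a hinge-loss grid-search oracle", {
  x <- rbind(c(0, 1), c(0.3, 1.2), c(-0.2, 0.8),
             c(0, -1), c(0.4, -0.9), c(-0.3, -1.3))
  y <- c(1, 1, 1, -1, -1, -1)
  for (C in c(1, 10)) {
    m <- train_linear_svm(x, y, C = C)
    oracle <- grid_search_svm(x, y, C)
    expect_lte(hinge_objective(m$w, m$b, x, y, C),
               oracle$val + 0.02 * abs(oracle$val) + 1e-6)
    # decision agreement on a probe grid
    probe <- as.matrix(expand.grid(seq(-2, 2, 0.5), seq(-2, 2, 0.5)))
    agree <- mean(sign(drop(probe %*% m$w) + m$b + 1e-12) ==
                    sign(drop(probe %*% oracle$w) + oracle$b + 1e-12))
    expect_gte(agree, 0.9)
  }
})

test_that("the separable symmetric toy set yields the horizontal axis", {
  x <- rbind(c(0, 1), c(0, -1))
  m <- train_linear_svm(x, c("OBJECT", "LINE"), C = 10)
  expect_equal(m$w[1], 0, tolerance = 1e-6)
  expect_gt(m$w[2], 0)
  expect_equal(m$b, 0, tolerance = 1e-6)
  expect_equal(predict_percept(m, c(0, 5))$label, "OBJECT")
  # duplicating the training set leaves the decision function unchanged
  m2 <- train_linear_svm(rbind(x, x), rep(c("OBJECT", "LINE"), 2), C = 10)
  expect_equal(m2$w, m$w, tolerance = 1e-4)
  expect_equal(m2$b, m$b, tolerance = 1e-4)
})

test_that("prediction applies the sign rule with ties to OBJECT", {
  m <- structure(list(w = c(1, -1), b = 0, C = 1, voxel_indices = 1:2),
                 class = "linear_percept_model")
  expect_equal(predict_percept(m, c(2, 1))$label, "OBJECT")
  m$b <- -5
  expect_equal(predict_percept(m, c(2, 1))$label, "LINE")
  m$b <- -1
  p <- predict_percept(m, c(2, 1)) # decision exactly 0
  expect_equal(p$decision, 0)
  expect_equal(p$label, "OBJECT")
  expect_error(predict_percept(m, c(1, 2, 3)), "dimension")
})

test_that("single-class training sets are rejected", {
  expect_error(train_linear_svm(matrix(rnorm(10), 5, 2), rep("LINE", 5)),
               "both percept classes")
})

test_that("swapping class names flips all predictions", {
  set.seed(31)
  x <- matrix(rnorm(60), 30, 2)
  y <- ifelse(x[, 1] + rnorm(30, sd = 0.3) > 0, "OBJECT", "LINE")
  if (length(unique(y)) < 2) y[1] <- setdiff(c("LINE", "OBJECT"), y[1])
  m1 <- train_linear_svm(x, y)
  m2 <- train_linear_svm(x, ifelse(y == "LINE", "OBJECT", "LINE"))
  p1 <- predict_percept(m1, x)$label
  p2 <- predict_percept(m2, x)$label
  # allow ties at decision 0 (none expected with continuous data)
  expect_true(all(p1 != p2))
})

test_that("cutoff optimisation picks from the candidate set with low ties", {
  sess <- make_test_session(n_runs = 3, duration = 200, seed = 41)
  cfg <- decode_config(k_select = 40,
                       lowpass_candidates = c(1 / 27, 1 / 16))
  chosen <- optimize_lowpass(sess, cfg, runs = 1:3)
  expect_true(chosen %in% cfg$lowpass_candidates)
})

test_that("leave-one-run-out decodes a high-SNR session", {
  sess <- make_test_session(n_runs = 4, duration = 300, seed = 43)
  res <- loro_cv(sess, small_cfg())
  expect_s3_class(res, "decoding_result")
  expect_gt(accuracy(res), 0.8)
  # per-volume table covers every defined volume of every run
  expect_setequal(unique(res$run), 1:4)
  expect_true(all(!is.na(res$truth)))
  fold <- tidy(res)
  expect_equal(nrow(fold), 4)
  expect_true(all(fold$cutoff_hz %in% small_cfg()$lowpass_candidates))
  # glance reports the pooled accuracy
  expect_equal(glance(res)$accuracy, accuracy(res))
})

test_that("sessions with fewer than 3 runs are rejected", {
  sess <- make_test_session(n_runs = 2, duration = 150, seed = 44)
  expect_error(loro_cv(sess, small_cfg()), "3 runs")
})

test_that("feature scaling invariance holds when C is rescaled", {
  set.seed(45)
  x <- matrix(rnorm(80), 40, 2)
  y <- ifelse(x[, 1] > 0, "OBJECT", "LINE")
  m1 <- train_linear_svm(x, y, C = 1)
  s <- 10
  m2 <- train_linear_svm(x * s, y, C = 1 / s^2)
  expect_equal(predict_percept(m1, x)$label,
               predict_percept(m2, x * s)$label)
  expect_equal(m2$w * s, m1$w, tolerance = 1e-2)
})
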