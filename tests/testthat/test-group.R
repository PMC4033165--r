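make_subject <- function(seed, vox, n_runs = 3, effect_session = TRUE) {
  sess <- simulate_session(n_runs = n_runs, duration = 250, tr = 2.0,
                           dwell = dwell_preset("online"), voxels = vox,
                           noise = noise_config(sigma = 0.3), seed = seed)
  reduce_to_interval_centers(sess, decode_config(k_select = 60,
                                                 lowpass_candidates = 1 / 16))
}

shared_vox <- function(effect = 1.5, seed = 81)
  sample_voxel_spec(c(8, 8, 3), n_positive = 15, n_negative = 15,
                    n_vessel = 1, effect = effect, seed = seed)

test_that("interval-centre reduction averages the right volumes", {
  # index-arithmetic oracle: interval of 7 volumes with values 1..7
  # reduces to mean(3,4,5) = 4; even length centres on the earlier middle
  sess <- make_test_session(n_runs = 1, duration = 120, grid = c(2, 2, 1),
                            n_inf = 1, n_vessel = 0, seed = 82)
  tl <- regular_timeline(interval = 30, total = 120)
  sess$runs[[1]]$timeline <- tl
  red <- reduce_to_interval_centers(sess, decode_config(
    k_select = 4, lowpass_candidates = 1 / 16, hrf_delay = 0))
  expect_equal(nrow(red$x), nrow(tl))
  expect_equal(red$y, tl$state)
  # direct check of the centring arithmetic on a constructed label run
  lab <- c(rep("LINE", 7), rep("OBJECT", 4))
  blocks <- rle(lab)
  ends <- cumsum(blocks$lengths)
  starts <- ends - blocks$lengths + 1L
  centre1 <- starts[1] + floor((blocks$lengths[1] + 1) / 2) - 1L
  expect_equal(centre1, 4L)          # volumes 3,4,5 of 1..7
  centre2 <- starts[2] + floor((blocks$lengths[2] + 1) / 2) - 1L
  expect_equal(centre2, 9L)          # earlier middle of 8..11
})

test_that("one sample per interval, with interval lengths attached", {
  sess <- make_test_session(n_runs = 2, duration = 250, seed = 83)
  red <- reduce_to_interval_centers(sess, decode_config(
    k_select = 50, lowpass_candidates = 1 / 16))
  n_int <- sum(purrr::map_int(1:2, function(r) {
    lab <- labels_per_volume(sess$runs[[r]]$timeline,
                             n_volumes(sess$runs[[r]]), 2.0, 5)
    length(rle(lab[!is.na(lab)])$lengths)
  }))
  expect_equal(nrow(red$x), n_int)
  expect_equal(length(red$interval_len), n_int)
  expect_true(all(red$y %in% c("LINE", "OBJECT")))
})

test_that("subject maps embed weights into the common grid", {
  red <- make_subject(84, shared_vox())
  sm <- subject_weight_map(red, k = 40)
  expect_length(sm$w, red$grid_size)
  expect_lte(sum(sm$w != 0), 40)
  expect_true(sm$p_hat >= 0 && sm$p_hat <= 1)
  # weights outside the selected voxels are exactly zero
  expect_true(all(sm$w[setdiff(seq_along(sm$w), red$retained)] == 0))
})

test_that("subject maps for a shared layout are positively correlated", {
  vox <- shared_vox()
  maps <- purrr::map(85:87, ~ subject_weight_map(make_subject(.x, vox),
                                                 k = 60))
  cors <- c()
  for (i in 1:2) for (j in (i + 1):3)
    cors <- c(cors, stats::cor(maps[[i]]$w, maps[[j]]$w))
  expect_gt(mean(cors), 0.3)
})

test_that("accuracy weighting follows the combination formula exactly", {
  m1 <- structure(list(w = c(2, 0), p_hat = 1.0, subject_id = 1),
                  class = "subject_map")
  m2 <- structure(list(w = c(0, 4), p_hat = 0.75, subject_id = 2),
                  class = "subject_map")
  gm <- combine_weight_maps(list(m1, m2))
  expect_equal(gm$w_bar, c(1.0, 1.0)) # hand evaluation
  # a chance-level subject contributes exactly zero
  m3 <- structure(list(w = c(100, -100), p_hat = 0.5, subject_id = 3),
                  class = "subject_map")
  gm3 <- combine_weight_maps(list(m1, m3))
  expect_equal(gm3$w_bar, c(1.0, 0))
  # n = 1 with perfect accuracy returns the map itself
  expect_equal(combine_weight_maps(list(m1))$w_bar, m1$w)
  # below-chance subjects flip sign
  m4 <- structure(list(w = c(2, 0), p_hat = 0.25, subject_id = 4),
                  class = "subject_map")
  expect_lt(combine_weight_maps(list(m4))$w_bar[1], 0)
  # linear in each subject's weights, invariant to subject order
  expect_equal(combine_weight_maps(list(m2, m1))$w_bar, gm$w_bar)
  m1b <- m1; m1b$w <- 2 * m1$w
  expect_equal(combine_weight_maps(list(m1b, m2))$w_bar,
               gm$w_bar + c(1, 0))
  expect_error(combine_weight_maps(list(m1, structure(
    list(w = c(1, 2, 3), p_hat = 0.9, subject_id = 9),
    class = "subject_map"))), "common voxel grid")
})

test_that("transfer succeeds for shared maps and fails for disjoint maps", {
  vox <- shared_vox()
  shared <- purrr::map(91:94, ~ make_subject(.x, vox))
  res <- loso_cv(shared, k_select = 60)
  expect_equal(nrow(res), 4)
  expect_true(all(res$accuracy > 0.8))
  # disjoint informative maps: each subject gets its own layout
  disjoint <- purrr::map(91:94, ~ make_subject(.x, shared_vox(seed = .x)))
  res_d <- loso_cv(disjoint, k_select = 60)
  expect_lt(mean(res_d$accuracy), mean(res$accuracy))
  expect_lt(mean(res_d$accuracy), 0.75)
  expect_error(loso_cv(shared[1:2]), "3 subjects")
})
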