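test_that("zero-centring removes per-voxel means and replays baselines", {
  x <- cbind(rep(100, 50), 100 + sin(1:50))
  zc <- zero_center(x)
  expect_equal(unname(colMeans(zc$x)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(zc$baseline[1]), 100)
  # online mode: stored baseline subtracted from a single volume
  one <- zero_center(c(103, 101), baseline = zc$baseline)
  expect_equal(unname(one$x[1]), 3, tolerance = 0.2)
  expect_error(zero_center(c(1, 2)), "baseline")
})

test_that("band-pass attenuation matches an FFT amplitude oracle", {
  tr <- 2.0
  n <- 512
  t <- (0:(n - 1)) * tr
  amp_at <- function(y, f) {
    sp <- Mod(stats::fft(y)) / n * 2
    sp[round(f * n * tr) + 1]
  }
  cfg <- filter_config(1 / 128, 1 / 16, 4, "zero_phase")
  # passband sinusoid (1/30 Hz) survives within 10%
  y1 <- bandpass(sin(2 * pi * t / 30), tr, cfg)
  expect_gt(amp_at(y1, 1 / 30), 0.9)
  # DC attenuated by > 95% away from the edge transients
  y2 <- bandpass(rep(5, n), tr, cfg)
  expect_lt(max(abs(y2[100:400])), 5 * 0.05)
  # stopband sinusoid (1/4 Hz) attenuated by > 90%
  y3 <- bandpass(sin(2 * pi * t / 4), tr, cfg)
  expect_lt(amp_at(y3, 1 / 4), 0.1)
})

test_that("filtering is linear", {
  set.seed(5)
  tr <- 2
  x <- rnorm(200); y <- rnorm(200)
  cfg <- filter_config(1 / 128, 1 / 16, 4, "causal")
  lhs <- bandpass(3 * x - 2 * y, tr, cfg)
  rhs <- 3 * bandpass(x, tr, cfg) - 2 * bandpass(y, tr, cfg)
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("causal filtering matches the reference implementation", {
  set.seed(6)
  x <- rnorm(300)
  bf <- signal::butter(2, c(1 / 128, 1 / 16) / 0.25, type = "pass")
  ref <- as.numeric(signal::filter(bf, x))
  mine <- bandpass(x, 2, filter_config(1 / 128, 1 / 16, 4, "causal"))
  expect_equal(mine, ref, tolerance = 1e-10)
})

test_that("streaming filter equals batch causal filtering", {
  set.seed(7)
  x <- matrix(rnorm(400), 100, 4)
  cfg <- filter_config(1 / 128, 1 / 16, 4, "causal")
  batch <- bandpass(x, 2, cfg)
  co <- rtpercept:::butter_coefs(cfg, 2)
  st <- rtpercept:::iir_state_init(co$b, co$a, 4)
  out <- x
  for (t in 1:100) {
    step <- rtpercept:::iir_step(st, x[t, ])
    out[t, ] <- step$y
    st <- step$state
  }
  expect_equal(out, batch, tolerance = 1e-12)
})

test_that("cutoffs beyond Nyquist are rejected", {
  expect_error(bandpass(matrix(rnorm(100)), 2,
                        filter_config(1 / 128, 0.3, 4)), "Nyquist")
})

test_that("the 10% exclusion rule is strict and idempotent", {
  base <- matrix(100, 40, 3)
  base[, 2] <- 100 + rep(c(10, -10), 20)  # max deviation exactly 10%: retained
  base[, 3] <- 100 + rep(c(11, -11), 20)  # 11% deviation: excluded
  excl <- exclude_high_signal_change(base, 0.10)
  expect_true(2L %in% excl$retained)
  expect_false(3L %in% excl$retained)
  # idempotent: re-applying on the retained set excludes nothing new
  again <- exclude_high_signal_change(base[, excl$retained, drop = FALSE],
                                      0.10)
  expect_equal(length(again$retained), length(excl$retained))
  # non-positive baseline excluded with a warning
  expect_warning(e2 <- exclude_high_signal_change(cbind(base[, 1], -1)),
                 "non-positive")
  expect_equal(e2$retained, 1L)
})

test_that("label shifting matches a brute-force window-overlap oracle", {
  tl <- simulate_percept_timeline(200, dwell_preset("online", seed = 9))
  oracle <- function(n, tr, d) {
    sapply(seq_len(n) - 1, function(k) {
      a <- k * tr - d; b <- (k + 1) * tr - d
      if (a < 0) return(NA_character_)
      grid <- seq(a + 1e-6, b - 1e-6, length.out = 2001)
      st <- timeline_state_at(tl, pmin(grid, 200 - 1e-9))
      occ <- table(st)
      if (length(occ) == 1) return(names(occ))
      if (abs(diff(range(occ))) <= 1) st[1] else names(occ)[which.max(occ)]
    })
  }
  for (par in list(c(2.5, 5), c(2.0, 5), c(2.0, 0), c(2.0, 7.3))) {
    n <- floor(200 / par[1])
    expect_equal(labels_per_volume(tl, n, par[1], par[2]),
                 oracle(n, par[1], par[2]),
                 info = paste("tr", par[1], "delay", par[2]))
  }
})

test_that("tr 2.5 with 5 s delay is an exact two-volume shift", {
  tl <- simulate_percept_timeline(300, dwell_preset("offline", seed = 2))
  lab0 <- labels_per_volume(tl, 120, 2.5, 0)
  lab5 <- labels_per_volume(tl, 120, 2.5, 5)
  expect_true(all(is.na(lab5[1:2])))
  expect_equal(lab5[3:120], lab0[1:118])
})

test_that("shifted labels are a re-indexing of timeline states", {
  tl <- simulate_percept_timeline(300, dwell_preset("online", seed = 12))
  lab <- labels_per_volume(tl, 150, 2.0, 5)
  def <- !is.na(lab)
  # multiset of defined labels equals the states at the shifted volume times
  expect_true(all(lab[def] %in% c("LINE", "OBJECT")))
  expect_equal(sum(is.na(lab)), ceiling(5 / 2.0))
})

test_that("spatial smoothing preserves mass and matches the target width", {
  vol <- array(0, c(21, 21, 9))
  vol[11, 11, 5] <- 1
  sm <- smooth_spatial(vol, fwhm_mm = 8, voxel_size_mm = 3)
  expect_equal(sum(sm), 1, tolerance = 0.01) # interior delta: mass kept
  prof <- sm[, 11, 5]
  half <- max(prof) / 2
  above <- which(prof >= half)
  fwhm_vox <- max(above) - min(above) + 1
  expect_lt(abs(fwhm_vox * 3 - 8), 3 * 0.5 + 1.6) # within half a voxel-ish
  expect_identical(smooth_spatial(vol, 0), vol)
})
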