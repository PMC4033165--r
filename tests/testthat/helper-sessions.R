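# Shared fixtures, all generated in code at test time.

# Small high-SNR session: 40 informative voxels in a 10x10x4 grid.
make_test_session <- function(n_runs = 4, duration = 300, tr = 2.0,
                              effect = 1.5, sigma = 0.3, seed = 7,
                              grid = c(10, 10, 4), n_inf = 20,
                              n_vessel = 2, dwell = dwell_preset("online")) {
  vox <- sample_voxel_spec(grid, n_positive = n_inf, n_negative = n_inf,
                           n_vessel = n_vessel, effect = effect, seed = seed)
  simulate_session(n_runs = n_runs, duration = duration, tr = tr,
                   dwell = dwell, voxels = vox,
                   noise = noise_config(sigma = sigma), seed = seed)
}

small_cfg <- function(...) {
  decode_config(k_select = 80, lowpass_candidates = 1 / 16, ...)
}

# Alternating two-state timeline with fixed interval length.
regular_timeline <- function(interval = 30, total = 300,
                             first = "LINE") {
  n <- total / interval
  states <- rep(c(first, setdiff(c("LINE", "OBJECT"), first)),
                length.out = n)
  percept_timeline(onset = seq(0, total - interval, by = interval),
                   duration = rep(interval, n), state = states,
                   total_duration = total)
}
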