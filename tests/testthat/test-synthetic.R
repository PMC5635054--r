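test_that("envelope generator: degenerate noise, determinism, AR structure", {
  # sd = 0 collapses to the constant mean
  e0 <- generate_envelope(5, 100, 0.9, mean = 15, sd = 0, seed = 1)
  expect_equal(as.numeric(e0), rep(15, 500))

  # identical seed, identical series (bitwise)
  e1 <- generate_envelope(20, 250, 0.95, seed = 42)
  e2 <- generate_envelope(20, 250, 0.95, seed = 42)
  expect_identical(as.numeric(e1), as.numeric(e2))
  expect_false(identical(as.numeric(e1),
                         as.numeric(generate_envelope(20, 250, 0.95, seed = 43))))

  # lag-1 autocorrelation of the pre-rectification process
  big <- generate_envelope(4000, 250, 0.95, seed = 7)   # 1e6 samples
  raw <- attr(big, "raw")
  expect_equal(cor(raw[-1], raw[-length(raw)]), 0.95, tolerance = 0.02 / 0.95)

  expect_error(generate_envelope(10, 0, 0.5), "fs_env")
  expect_error(generate_envelope(10, 100, 1.0), "ar_coeff")
  expect_error(generate_envelope(10, 100, 0.5, mean = -1), "mean")
})

test_that("simulated EEG carries the envelope on occipital channels", {
  cfg <- sim_config(fs_eeg = 500, duration = 60, n_volumes = 23,
                    gradient_amplitude = 0, bcg_amplitude = 0,
                    noise_sd_eeg = 0)
  env <- generate_envelope(60, 250, 0.999, seed = 3)
  sim <- simulate_eeg(env, cfg, seed = 5)
  o1 <- get_channel(sim$rec, "O1")
  # alpha is the only signal present: moving RMS * sqrt(2) over ~2.5
  # cycles recovers the instantaneous amplitude
  w <- round(0.25 * 500)
  amp <- sqrt(2 * as.numeric(stats::filter(o1^2, rep(1 / w, w), sides = 2)))
  t <- (seq_along(o1) - 1) / 500
  env_t <- approx((seq_along(env) - 1) / 250, as.numeric(env), xout = t,
                  rule = 2)$y
  core <- t > 3 & t < 57                           # skip filter edges
  expect_gt(cor(amp[core], env_t[core]), 0.99)
})

test_that("gradient artifact is TR-periodic and dominates the raw spectrum", {
  cfg <- sim_config(fs_eeg = 500, duration = 130, n_volumes = 50)
  env <- generate_envelope(130, 250, 0.999, seed = 3)
  sim <- simulate_eeg(env, cfg, seed = 5)
  # markers: one per volume acquired within duration
  expect_equal(nrow(sim$rec$markers), floor(130 / 2.6))
  expect_equal(sim$rec$markers$type, rep("Scanner", 50))
  # raw O-channel power is concentrated at k/TR harmonics
  frac <- harmonic_power_fraction(get_channel(sim$rec, "O1"), 500, 1 / 2.6)
  expect_gt(frac, 0.5)
  # noiseless artifact component is exactly epoch-periodic
  art <- reconstruct_artifacts(sim$ground_truth, 500,
                               n_samp = 500 * 130, which = "gradient")
  ep_len <- round(2.6 * 500)
  epochs <- sapply(sim$ground_truth$volume_onsets, function(on)
    art[1, (round(on * 500) + 1):(round(on * 500) + ep_len)])
  expect_equal(max(apply(epochs, 1, function(r) diff(range(r)))), 0)
  # marker count is bounded by n_volumes
  cfg2 <- sim_config(fs_eeg = 500, duration = 130, n_volumes = 10)
  sim2 <- simulate_eeg(env, cfg2, seed = 5)
  expect_equal(nrow(sim2$rec$markers), 10)
})

test_that("simulate_eeg validates montage and envelope coverage", {
  cfg <- sim_config(fs_eeg = 500, duration = 30, n_volumes = 10)
  short_env <- generate_envelope(10, 250, 0.9, seed = 1)
  expect_error(simulate_eeg(short_env, cfg), "shorter")
  expect_error(sim_config(channel_labels = c("Fz", "Cz", "Pz")), "occipital")
})

test_that("BOLD simulation embodies the configured coupling", {
  gs <- c(3, 3, 3)
  cfg <- sim_config(fs_eeg = 250, duration = 130, n_volumes = 50,
                    grid_shape = gs, noise_sd_bold = 0, drift_amplitude = 0)
  env <- generate_envelope(130, 250, 0.999, seed = 11)
  zero_map <- array(0, gs)

  # no coupling, no noise, no drift: constant baseline everywhere
  b0 <- simulate_bold(env, zero_map, cfg, seed = 1)
  expect_equal(max(abs(b0$data - cfg$baseline_bold)), 0)

  # a coupled voxel follows the baseline-scaled convolved envelope exactly
  cmap <- zero_map; cmap[2, 2, 2] <- 0.02
  b1 <- simulate_bold(env, cmap, cfg, seed = 1)
  v <- b1$data[2, 2, 2, ]
  z <- (v / cfg$baseline_bold - 1) / 0.02          # recover the regressor
  expect_equal(mean(z), 0, tolerance = 1e-10)
  expect_equal(sd(z), 1, tolerance = 1e-10)
  # uncoupled voxels remain at baseline
  expect_equal(max(abs(b1$data[1, 1, 1, ] - cfg$baseline_bold)), 0)

  expect_error(simulate_bold(env, array(0, c(2, 2, 2)), cfg), "grid_shape")
  expect_error(simulate_bold(env, zero_map,
                             sim_config(grid_shape = gs, n_volumes = 5)),
               "n_volumes")
})

test_that("coupled voxels out-correlate uncoupled ones at default noise", {
  gs <- c(3, 3, 3)
  cfg <- sim_config(fs_eeg = 250, duration = 130, n_volumes = 50,
                    grid_shape = gs)
  env <- generate_envelope(130, 250, 0.999, seed = 11)
  cmap <- array(0, gs); cmap[1, 1, 1] <- 0.02
  # oracle regressor: HRF-convolved envelope at the volume grid
  hrf <- canonical_hrf(dt = 0.1)
  tg <- seq(0, 130, by = 0.1)
  eg <- approx((seq_along(env) - 1) / 250, as.numeric(env), xout = tg,
               rule = 2)$y
  cv <- stats::convolve(eg, rev(hrf$values), type = "open")[seq_along(tg)]
  onsets <- seq(0, by = 2.6, length.out = 50)
  zref <- approx(tg, cv, xout = onsets)$y
  wins <- vapply(1:100, function(i) {
    b <- simulate_bold(env, cmap, cfg, seed = 1000 + i)
    cor(b$data[1, 1, 1, ], zref) > cor(b$data[3, 3, 3, ], zref)
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})

test_that("cohort simulation: sizes, covariate distributions, determinism", {
  gs <- c(4, 4, 4)
  cfg <- sim_config(fs_eeg = 250, duration = 30, n_volumes = 10,
                    grid_shape = gs)
  groups <- list(AD = list(n = 14, coupling_map = array(0, gs)),
                 HC = list(n = 14, coupling_map = array(0.02, gs)))
  co <- simulate_cohort(cfg, groups, seed = 9, materialize = FALSE)
  expect_length(co$subjects, 28)
  expect_equal(sum(co$covariates$group == "AD"), 14)
  expect_equal(sum(co$covariates$group == "HC"), 14)
  expect_false(anyDuplicated(co$covariates$subject_id) > 0)

  co2 <- simulate_cohort(cfg, groups, seed = 9, materialize = FALSE)
  expect_identical(co$covariates, co2$covariates)
  s1 <- simulate_subject(co, 1)
  s2 <- simulate_subject(co2, 1)
  expect_identical(s1$eeg$data, s2$eeg$data)
  expect_identical(s1$bold$data, s2$bold$data)

  # AD ages are drawn around 75.3 with sd 5.7
  big <- simulate_cohort(cfg, list(AD = list(n = 200, coupling_map = array(0, gs)),
                                   HC = list(n = 2, coupling_map = array(0, gs))),
                         seed = 4, materialize = FALSE)
  ad_age <- big$covariates$age[big$covariates$group == "AD"]
  expect_equal(mean(ad_age), 75.3, tolerance = 1.5 / 75.3)
  expect_equal(sd(ad_age), 5.7, tolerance = 0.25)

  expect_error(simulate_cohort(cfg, list(AD = list(n = 1, coupling_map = array(0, gs)),
                                         HC = list(n = 2, coupling_map = array(0, gs)))),
               "group size")
})

test_that("occipital band power concentrates where the envelope is high", {
  cfg <- sim_config(fs_eeg = 500, duration = 240, n_volumes = 80,
                    gradient_amplitude = 0, bcg_amplitude = 0)
  env <- generate_envelope(240, 250, 0.999, seed = 21)
  sim <- simulate_eeg(env, cfg, seed = 22)
  o1 <- get_channel(sim$rec, "O1")
  dp <- complex_demodulate(o1, 500, alpha_bands()$total_alpha)
  t <- (seq_along(o1) - 1) / 500
  env_t <- approx((seq_along(env) - 1) / 250, as.numeric(env), xout = t,
                  rule = 2)$y
  core <- t > 3 & t < 237
  upper <- env_t[core] > median(env_t[core])
  expect_gte(sum(dp$values[core][upper]) / sum(dp$values[core]), 0.8)
})
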