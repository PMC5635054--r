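tone_rec <- function(freqs, fs = 5000, dur = 10, labels = NULL) {
  t <- (0:(fs * dur - 1)) / fs
  ch <- lapply(freqs, function(f) sin(2 * pi * f * t))
  names(ch) <- if (is.null(labels)) paste0("C", seq_along(freqs)) else labels
  make_rec(ch, fs)
}

test_that("decimation preserves the pass band and rejects aliases", {
  rec <- tone_rec(c(10, 200), fs = 5000, dur = 10)
  dec <- decimate_eeg(rec, 250)
  expect_equal(dec$fs, 250)
  expect_equal(ncol(dec$data), 2500)
  # 10 Hz tone amplitude preserved within 1%
  core <- 500:2000
  amp10 <- sqrt(2 * mean(dec$data[1, core]^2))
  expect_equal(amp10, 1, tolerance = 0.01)
  # 200 Hz tone attenuated by >= 40 dB (it would alias to 50 Hz)
  p_before <- band_power_psd(rec$data[2, ], 5000, 195, 205) / ncol(rec$data)
  p_after <- band_power_psd(dec$data[2, core], 250, 40, 60) / length(core)
  expect_gte(10 * log10(p_before / p_after), 40)
  expect_error(decimate_eeg(rec, 300), "integer multiple")
  expect_error(decimate_eeg(dec, 250), "below")
})

test_that("marker-driven epoch onsets: spacing, boundaries, jitter warning", {
  mk <- tibble::tibble(time = seq(0, 26, by = 2.6), type = "Scanner",
                       label = "V")
  rec <- make_rec(list(C1 = numeric(30 * 250)), 250, mk)
  on <- epoch_onsets_from_markers(rec)
  expect_equal(diff(on), rep(2.6, 10), tolerance = 1e-12)

  rec1 <- make_rec(list(C1 = numeric(250 * 30)), 250,
                   tibble::tibble(time = 1, type = "Scanner", label = "V"))
  expect_error(epoch_onsets_from_markers(rec1), "at least 2")

  jit <- mk
  jit$time[3] <- jit$time[3] + 2 / 250           # two samples off
  rec2 <- make_rec(list(C1 = numeric(30 * 250)), 250, jit)
  expect_warning(on2 <- epoch_onsets_from_markers(rec2), "spacing")
  expect_length(on2, 11)
})

test_that("AAS removes an identical per-epoch artifact to numerical zero", {
  fs <- 250; tr <- 2; n_ep <- 20
  tpl <- 100 * sin(2 * pi * 13 * (0:(fs * tr - 1)) / fs) +
    50 * ((0:(fs * tr - 1)) %% 25) / 25
  x <- rep(tpl, n_ep)
  rec <- make_rec(list(C1 = x, C2 = 0.5 * x), fs)
  onsets <- (0:(n_ep - 1)) * tr
  out <- aas_subtract(rec, onsets, tr, n_avg = n_ep)
  expect_lt(sqrt(mean(out$data^2)), 1e-9 * sqrt(mean(x^2)))

  # n_avg = 1: each epoch is its own template, so epochs become exactly 0
  out1 <- aas_subtract(rec, onsets, tr, n_avg = 1)
  expect_equal(max(abs(out1$data)), 0)

  expect_error(aas_subtract(rec, onsets, tr + 0.1, n_avg = 5), "overlap")
  expect_error(aas_subtract(rec, c(0, 39), tr, n_avg = 5), "past the end")
})

test_that("AAS and BCG subtraction are linear in the data", {
  fs <- 250
  set.seed(1)
  a <- rnorm(fs * 20); b <- rnorm(fs * 20)
  onsets <- (0:8) * 2
  run <- function(x) {
    rec <- make_rec(list(C1 = x), fs)
    aas_subtract(rec, onsets, 2, n_avg = 5)$data[1, ]
  }
  expect_equal(run(a + b), run(a) + run(b), tolerance = 1e-12)
})

test_that("R-peak detection: clean, flat, and noisy ECG", {
  fs <- 500
  cfg <- sim_config(fs_eeg = fs, duration = 60, n_volumes = 23,
                    heart_rate = 60, rr_jitter = 0.03)
  env <- generate_envelope(60, 250, 0.99, seed = 1)
  sim <- simulate_eeg(env, cfg, seed = 2)
  truth <- sim$ground_truth$r_peak_times

  clean <- withr::with_seed(3, {
    t <- (0:(60 * fs - 1)) / fs
    x <- numeric(length(t))
    for (r in truth) x <- x + 800 * exp(-((t - r) / 0.012)^2)
    x
  })
  pk <- detect_r_peaks(clean, fs)
  expect_true(abs(length(pk) - length(truth)) <= 1)
  err <- vapply(pk, function(p) min(abs(truth - p)), numeric(1))
  expect_lt(max(err), 0.010)

  expect_warning(flat <- detect_r_peaks(rep(1, fs * 20), fs), "flat")
  expect_length(flat, 0)

  # 10 dB SNR: sensitivity >= 0.95
  noisy <- clean + withr::with_seed(4, rnorm(length(clean), 0, sd(clean) / sqrt(10)))
  pk2 <- detect_r_peaks(noisy, fs)
  hits <- vapply(truth, function(r) any(abs(pk2 - r) < 0.05), logical(1))
  expect_gte(mean(hits), 0.95)

  expect_error(detect_r_peaks(rnorm(fs), fs), "10 s")
})

test_that("BCG subtraction removes identical per-beat artifacts", {
  fs <- 250; dur <- 60
  # beat epochs fall exactly on the sampling grid: (r + 0.21) * fs integer
  r_peaks <- seq(0.502, dur - 1.5, by = 1)
  tpl <- 80 * exp(-(0:(0.5 * fs - 1)) / (0.12 * fs)) *
    sin(2 * pi * 7 * (0:(0.5 * fs - 1)) / fs)
  x <- numeric(dur * fs)
  for (r in r_peaks) {
    i0 <- round((r + 0.21) * fs) + 1
    x[i0:(i0 + length(tpl) - 1)] <- x[i0:(i0 + length(tpl) - 1)] + tpl
  }
  rec <- make_rec(list(C1 = x, ECG = numeric(length(x))), fs)
  out <- bcg_subtract(rec, r_peaks, n_avg = length(r_peaks))
  expect_lt(sqrt(mean(out$data[1, ]^2)), 1e-9 * sqrt(mean(x^2)))
  # ECG channel untouched
  expect_equal(out$data[2, ], rec$data[2, ])

  expect_error(bcg_subtract(rec, numeric(0)), "empty")
  expect_error(bcg_subtract(rec, r_peaks, template_len = 1.5), "median RR")
})

test_that("band and notch filtering meet their attenuation contracts", {
  fs <- 250; dur <- 20
  t <- (0:(fs * dur - 1)) / fs
  rec <- make_rec(list(A = sin(2 * pi * 50 * t), B = sin(2 * pi * 10 * t),
                       C = rep(100, length(t))), fs)
  out <- filter_eeg(rec)
  core <- (2 * fs):((dur - 2) * fs)
  # 50 Hz tone down >= 30 dB
  p50_in <- band_power_psd(rec$data[1, core], fs, 49, 51)
  p50_out <- band_power_psd(out$data[1, core], fs, 49, 51)
  expect_gte(10 * log10(p50_in / p50_out), 30)
  # 10 Hz tone within 5%
  amp10 <- sqrt(2 * mean(out$data[2, core]^2))
  expect_equal(amp10, 1, tolerance = 0.05)
  # DC offset removed
  expect_lt(max(abs(mean(out$data[3, core]))), 1)
  expect_error(filter_eeg(rec, hp = 80, lp = 70), "band edges")
})

test_that("ICA proxy removes injected cardiac components and nothing else", {
  fs <- 250; n <- fs * 60
  set.seed(10)
  S <- rbind(rnorm(n), rnorm(n), rnorm(n), rnorm(n))
  A <- matrix(rnorm(16), 4, 4)
  clean <- A %*% S
  ecg <- rnorm(n)
  rec <- make_rec(list(C1 = clean[1, ], C2 = clean[2, ], C3 = clean[3, ],
                       C4 = clean[4, ], ECG = ecg), fs)
  out <- ica_autoclean(rec, seed = 5)
  removed <- out$history[[length(out$history)]]$removed
  expect_length(removed, 0)
  rel_err <- max(abs(out$data[1:4, ] - clean)) / max(abs(clean))
  expect_lt(rel_err, 1e-6)

  # inject a source that is strongly ECG-correlated: it must be removed
  S2 <- S
  S2[2, ] <- 0.9 * ecg / sd(ecg) + sqrt(1 - 0.81) * rnorm(n)
  dirty <- A %*% S2
  rec2 <- make_rec(list(C1 = dirty[1, ], C2 = dirty[2, ], C3 = dirty[3, ],
                        C4 = dirty[4, ], ECG = ecg), fs)
  out2 <- ica_autoclean(rec2, seed = 5)
  removed2 <- out2$history[[length(out2$history)]]$removed
  expect_gte(length(removed2), 1)
  expect_lte(length(removed2), 2)
  # the cardiac source is gone from the reconstruction
  res_cor <- max(abs(apply(out2$data[1:4, ], 1, cor, y = ecg)))
  expect_lt(res_cor, 0.1)

  # thresholds at 1.0 disable removal entirely
  out3 <- ica_autoclean(rec2, corr_thresh = 1.0, lowfreq_frac_thresh = 1.0,
                        seed = 5)
  expect_length(out3$history[[length(out3$history)]]$removed, 0)
})

test_that("artifact interval marking follows the burst geometry", {
  fs <- 250; dur <- 60
  set.seed(2)
  x <- rnorm(fs * dur, 0, 10)
  expect_equal(nrow(mark_artifacts(x, fs)$intervals), 0)

  # 2 s, 500 uV burst: one flagged interval covering >= 90% of it
  x2 <- x
  x2[(20 * fs):(22 * fs)] <- x2[(20 * fs):(22 * fs)] + 500
  m2 <- mark_artifacts(x2, fs)
  fl <- m2$intervals[m2$intervals$flagged, ]
  expect_equal(nrow(fl), 1)
  covered <- min(fl$end, 22) - max(fl$start, 20)
  expect_gte(covered / 2, 0.9)

  # 0.4 s burst: recorded but not flagged as >= 1 s
  x3 <- x
  x3[(30 * fs):(30.4 * fs)] <- x3[(30 * fs):(30.4 * fs)] + 500
  m3 <- mark_artifacts(x3, fs)
  expect_gte(nrow(m3$intervals), 1)
  expect_equal(sum(m3$intervals$flagged), 0)
})

test_that("common-average re-reference zeroes the channel sum and is idempotent", {
  set.seed(3)
  rec <- make_rec(list(C1 = rnorm(100), C2 = rnorm(100), C3 = rnorm(100),
                       ECG = rnorm(100)), 100)
  out <- rereference_common_average(rec)
  expect_lt(max(abs(colSums(out$data[1:3, ]))), 1e-10 * max(abs(out$data)))
  out2 <- rereference_common_average(out)
  expect_equal(out2$data, out$data, tolerance = 1e-12)
  # ECG is excluded from the average and untouched
  expect_equal(out$data[4, ], rec$data[4, ])

  a <- rnorm(50)
  rec2 <- make_rec(list(C1 = a, C2 = -a), 50)
  expect_equal(rereference_common_average(rec2)$data, rec2$data,
               tolerance = 1e-12)
  expect_error(rereference_common_average(make_rec(list(C1 = a, ECG = a), 50)),
               "2 EEG channels")
})

test_that("occipital pooling is the arithmetic mean of O1, O2, Oz", {
  x <- c(1, 2, 3)
  rec <- make_rec(list(O1 = c(1, 1, 1), O2 = c(2, 1, 1), Oz = c(6, 1, 1)), 10)
  expect_equal(as.numeric(pool_occipital(rec))[1], 3)
  rec_same <- make_rec(list(O1 = x, O2 = x, Oz = x), 10)
  expect_equal(as.numeric(pool_occipital(rec_same)), x)
  rec_miss <- make_rec(list(O1 = x, O2 = x, Pz = x), 10)
  expect_error(pool_occipital(rec_miss), "Oz not found")
})

test_that("preprocessing preserves channel count, markers and history", {
  mk <- tibble::tibble(time = seq(0, 18, by = 2), type = "Scanner",
                       label = "V")
  set.seed(8)
  rec <- make_rec(list(O1 = rnorm(5000), O2 = rnorm(5000), Oz = rnorm(5000),
                       ECG = rnorm(5000)), 250, mk)
  out <- filter_eeg(aas_subtract(rec, mk$time, 2, 5))
  expect_equal(nrow(out$data), 4)
  expect_identical(out$markers, rec$markers)
  expect_equal(vapply(out$history, `[[`, "", "op"),
               c("aas_subtract", "filter"))
})
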