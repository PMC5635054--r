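#' @importFrom stats rnorm runif rbinom sd cor fft approx
NULL

# standard 32-channel 10-20 montage (Brain Products layout)
std_montage_32 <- c(
  "Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "FT9", "FC5", "FC1", "FC2",
  "FC6", "FT10", "T7", "C3", "Cz", "C4", "T8", "TP9", "CP5", "CP1", "CP2",
  "CP6", "TP10", "P7", "P3", "Pz", "P4", "P8", "O1", "Oz", "O2"
)

# fixed occipital-dominant projection of the alpha source onto the scalp
alpha_topography <- function(labels) {
  w <- rep(0.08, length(labels))
  names(w) <- labels
  w[labels %in% c("O1", "O2")] <- 1.0
  w[labels == "Oz"] <- 0.95
  w[grepl("^P[0-9z]", labels)] <- 0.4
  w[grepl("^(CP|TP)", labels)] <- 0.2
  w
}

#' Simulation configuration for a synthetic simultaneous EEG-fMRI session
#'
#' Defaults reproduce the acquisition protocol the pipeline targets:
#' 32-channel 5 kHz EEG with an additional ECG channel, 7.5 min (468 s)
#' eyes-closed rest, echo-planar imaging at TR = 2.6 s, 180 volumes, and a
#' small common-space voxel grid in place of whole-brain anatomy.
#'
#' @param n_channels number of EEG channels (ECG is added on top).
#' @param fs_eeg EEG sampling rate, Hz.
#' @param duration recording length, s.
#' @param tr fMRI repetition time, s.
#' @param n_volumes number of acquired volumes.
#' @param grid_shape integer length-3 vector of voxels per axis.
#' @param voxel_size isotropic voxel edge, mm.
#' @param alpha_center alpha carrier frequency, Hz.
#' @param fs_env sampling rate of the amplitude envelope, Hz.
#' @param envelope_ar_coeff AR(1) coefficient of the envelope process at
#'   `fs_env` (in `[0, 1)`); the default gives a multi-second fluctuation
#'   time scale.
#' @param envelope_mean,envelope_sd mean and sd of the alpha amplitude
#'   envelope, microvolts.
#' @param gradient_amplitude MR gradient artifact amplitude, microvolts.
#' @param gradient_jitter per-epoch multiplicative amplitude jitter sd
#'   (0 = strictly periodic artifact).
#' @param bcg_amplitude ballistocardiogram artifact amplitude, microvolts.
#' @param heart_rate mean heart rate, beats per minute.
#' @param rr_jitter relative sd of the RR interval (default 3%).
#' @param noise_sd_eeg background EEG noise sd (white + pink), microvolts.
#' @param noise_sd_bold BOLD noise sd as a fraction of baseline.
#' @param drift_amplitude slow scanner drift amplitude as a fraction of
#'   baseline.
#' @param baseline_bold BOLD baseline intensity (arbitrary units).
#' @param channel_labels EEG montage labels; must include O1, O2, Oz.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_channels = 32, fs_eeg = 5000, duration = 468,
                       tr = 2.6, n_volumes = 180,
                       grid_shape = c(20L, 20L, 20L), voxel_size = 3.5,
                       alpha_center = 10, fs_env = 250,
                       envelope_ar_coeff = 0.999,
                       envelope_mean = 20, envelope_sd = 12,
                       gradient_amplitude = 2000, gradient_jitter = 0,
                       bcg_amplitude = 100, heart_rate = 60,
                       rr_jitter = 0.03, noise_sd_eeg = 5,
                       noise_sd_bold = 0.01, drift_amplitude = 0.01,
                       baseline_bold = 1000,
                       channel_labels = std_montage_32[seq_len(n_channels)]) {
  amps <- c(gradient_amplitude, bcg_amplitude, noise_sd_eeg, noise_sd_bold,
            drift_amplitude, envelope_mean, envelope_sd)
  if (any(!is.finite(amps)) || any(amps < 0))
    stop("amplitudes and noise levels must be finite and >= 0", call. = FALSE)
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape <= 0L))
    stop("grid_shape must be three positive integers", call. = FALSE)
  if (envelope_ar_coeff < 0 || envelope_ar_coeff >= 1)
    stop("envelope_ar_coeff must lie in [0, 1)", call. = FALSE)
  if (!all(c("O1", "O2", "Oz") %in% channel_labels))
    stop("montage must include occipital channels O1, O2, Oz", call. = FALSE)
  structure(as.list(environment()), class = "sim_config")
}

#' Generate a stochastic alpha amplitude envelope
#'
#' A rectified AR(1) Gaussian process scaled to the requested mean and sd.
#' The pre-rectification series is kept as attribute `raw` so that recovery
#' tests can probe the generating process directly.
#'
#' @param duration length, s.
#' @param fs_env sampling rate of the envelope, Hz.
#' @param ar_coeff AR(1) coefficient in `[0, 1)`.
#' @param mean,sd target mean and sd of the (pre-rectification) envelope,
#'   microvolts; `mean` must be positive.
#' @param seed integer seed; identical seeds give identical output.
#' @return Numeric vector of class `alpha_envelope` with attributes `fs`
#'   and `raw`.
#' @export
generate_envelope <- function(duration, fs_env, ar_coeff, mean = 20, sd = 12,
                              seed = 1L) {
  if (!all(is.finite(c(duration, fs_env, ar_coeff, mean, sd))))
    stop("all parameters must be finite", call. = FALSE)
  if (fs_env <= 0) stop("fs_env must be positive", call. = FALSE)
  if (ar_coeff < 0 || ar_coeff >= 1)
    stop("ar_coeff must lie in [0, 1)", call. = FALSE)
  if (mean <= 0) stop("mean must be positive", call. = FALSE)
  n <- round(duration * fs_env)
  raw <- withr::with_seed(seed, {
    if (sd == 0) rep(mean, n)
    else {
      innov_sd <- sd * sqrt(1 - ar_coeff^2)
      x <- numeric(n)
      x[1] <- rnorm(1, 0, sd)
      e <- rnorm(n - 1, 0, innov_sd)
      for (i in seq_len(n - 1)) x[i + 1] <- ar_coeff * x[i] + e[i]
      mean + x
    }
  })
  env <- pmax(raw, 0)
  structure(env, fs = fs_env, raw = raw, class = "alpha_envelope")
}

# 1/f ("pink") background noise via spectral shaping, unit variance
pink_noise <- function(n) {
  w <- rnorm(n)
  W <- fft(w)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)            # symmetric frequency index
  x <- Re(fft(W / sqrt(f), inverse = TRUE)) / n
  x / sd(x)
}

# one TR-long gradient artifact epoch: sawtooth at the slice frequency
# plus two harmonics; strictly identical across epochs unless jittered
gradient_template <- function(fs, tr, amplitude) {
  n <- round(tr * fs)
  tau <- (seq_len(n) - 1) / fs
  f_slice <- 20 / tr
  saw <- 2 * (tau * f_slice - floor(tau * f_slice)) - 1
  amplitude * (saw + 0.4 * sin(2 * pi * 3 * f_slice * tau) +
                 0.2 * sin(2 * pi * 7 * f_slice * tau))
}

# damped-oscillation ballistocardiogram template, 0.5 s long
bcg_template <- function(fs, amplitude, len = 0.5) {
  tau <- seq(0, len, by = 1 / fs)
  tau <- tau[tau < len]
  amplitude * exp(-tau / 0.12) * sin(2 * pi * 7 * tau)
}

# synthetic ECG: sharp R spikes plus a small T wave on a noisy baseline
synth_ecg <- function(fs, duration, r_times, noise_sd = 10) {
  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs
  x <- rnorm(n, 0, noise_sd)
  for (r in r_times) {
    x <- x + 800 * exp(-((t - r) / 0.012)^2) +
      120 * exp(-((t - r - 0.3) / 0.06)^2)
  }
  x
}

# R-peak times with multiplicative RR jitter, starting 0.5 s in
draw_r_peaks <- function(duration, heart_rate, rr_jitter) {
  rr_mean <- 60 / heart_rate
  n_max <- ceiling(duration / rr_mean) + 10
  rr <- rr_mean * pmax(0.5, 1 + rnorm(n_max, 0, rr_jitter))
  r <- 0.5 + cumsum(c(0, rr))
  r[r < duration - 0.01]
}

#' Simulate a simultaneous EEG recording inside the scanner
#'
#' Builds an occipital-dominant alpha oscillation modulated by `envelope`,
#' adds white + pink background noise, a TR-locked gradient artifact with
#' per-volume `Scanner` markers, an R-peak-locked pulse artifact, and an
#' ECG channel.
#'
#' @param envelope an [generate_envelope()] result covering `duration`.
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return A list with elements `rec` (an [eeg_recording()]) and
#'   `ground_truth` (envelope, artifact templates and gains, R-peak times,
#'   volume onsets) sufficient to compute every recovery metric.
#' @export
simulate_eeg <- function(envelope, config, seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  fs <- config$fs_eeg
  dur <- config$duration
  fs_env <- attr(envelope, "fs")
  if (is.null(fs_env)) stop("envelope must come from generate_envelope()",
                            call. = FALSE)
  if (length(envelope) / fs_env < dur - 1e-9)
    stop("envelope shorter than configured duration", call. = FALSE)
  labels <- config$channel_labels
  if (!all(c("O1", "O2", "Oz") %in% labels))
    stop("montage must include occipital channels O1, O2, Oz", call. = FALSE)

  n <- round(dur * fs)
  t <- (seq_len(n) - 1) / fs
  env_t <- approx(x = (seq_along(envelope) - 1) / fs_env,
                  y = as.numeric(envelope), xout = t, rule = 2)$y
  w <- alpha_topography(labels)

  onsets <- seq(0, by = config$tr, length.out = config$n_volumes)
  onsets <- onsets[onsets + config$tr <= dur + 1e-9]
  g_tpl <- gradient_template(fs, config$tr, config$gradient_amplitude)
  b_tpl <- bcg_template(fs, config$bcg_amplitude)

  withr::with_seed(seed, {
    # narrowband alpha: carrier with diffusing phase (~1 Hz spectral
    # width), not a coherent sinusoid — spontaneous alpha is incoherent
    # across scanner epochs, which also keeps it out of the AAS template
    phase <- cumsum(rnorm(n, 0, sqrt(2 * pi * 1 / fs)))
    alpha_carrier <- env_t * sin(2 * pi * config$alpha_center * t + phase)
    r_peaks <- draw_r_peaks(dur, config$heart_rate, config$rr_jitter)
    g_gain <- seq(0.8, 1.2, length.out = length(labels))
    b_gain <- seq(1.2, 0.5, length.out = length(labels))
    epoch_jit <- if (config$gradient_jitter > 0)
      1 + rnorm(length(onsets), 0, config$gradient_jitter)
    else rep(1, length(onsets))

    grad_track <- numeric(n)            # unit-gain gradient component
    for (k in seq_along(onsets)) {
      i0 <- round(onsets[k] * fs) + 1L
      idx <- i0:(i0 + length(g_tpl) - 1L)
      idx <- idx[idx <= n]
      grad_track[idx] <- grad_track[idx] + epoch_jit[k] * g_tpl[seq_along(idx)]
    }
    bcg_track <- numeric(n)             # unit-gain pulse component
    for (r in r_peaks) {
      i0 <- round((r + 0.21) * fs) + 1L
      if (i0 > n) next
      idx <- i0:(i0 + length(b_tpl) - 1L)
      idx <- idx[idx <= n]
      bcg_track[idx] <- bcg_track[idx] + b_tpl[seq_along(idx)]
    }

    data <- matrix(0, nrow = length(labels) + 1L, ncol = n)
    for (ci in seq_along(labels)) {
      noise <- if (config$noise_sd_eeg > 0)
        config$noise_sd_eeg * (0.7 * rnorm(n) + 0.7 * pink_noise(n))
      else 0
      data[ci, ] <- w[ci] * alpha_carrier + noise +
        g_gain[ci] * grad_track + b_gain[ci] * bcg_track
    }
    ecg <- synth_ecg(fs, dur, r_peaks,
                     noise_sd = max(config$noise_sd_eeg, 1e-12)) +
      grad_track
    data[length(labels) + 1L, ] <- ecg

    markers <- tibble::tibble(
      time = onsets, type = "Scanner",
      label = sprintf("V%3.3d", seq_along(onsets))
    )
    rec <- eeg_recording(data, fs, c(labels, "ECG"), markers,
                         history = list(list(op = "simulate_eeg", seed = seed)))
    gt <- list(
      envelope = as.numeric(envelope), envelope_fs = fs_env,
      topography = w,
      gradient_template = g_tpl, gradient_gain = g_gain,
      gradient_epoch_jitter = epoch_jit,
      bcg_template = b_tpl, bcg_gain = b_gain,
      r_peak_times = r_peaks, volume_onsets = onsets,
      alpha_center = config$alpha_center
    )
    list(rec = rec, ground_truth = gt)
  })
}

#' Reconstruct the artifact-only component from simulation ground truth
#'
#' @param gt `ground_truth` element returned by [simulate_eeg()].
#' @param fs target sampling rate, Hz (templates are resampled if needed).
#' @param n_samp number of samples to reconstruct.
#' @param which `"gradient"`, `"bcg"`, or `"both"`.
#' @return channels x samples matrix of the noiseless artifact component
#'   (EEG channels only, no ECG row).
#' @export
reconstruct_artifacts <- function(gt, fs, n_samp, which = "both") {
  resamp <- function(tpl, fs_from, fs_to, len_s) {
    if (fs_from == fs_to) return(tpl)
    x_old <- (seq_along(tpl) - 1) / fs_from
    x_new <- seq(0, len_s, by = 1 / fs_to)
    x_new <- x_new[x_new < len_s - 1e-12]
    approx(x_old, tpl, xout = x_new, rule = 2)$y
  }
  fs_native <- length(gt$gradient_template) /
    (gt$volume_onsets[2] - gt$volume_onsets[1])
  n_ch <- length(gt$gradient_gain)
  out <- matrix(0, n_ch, n_samp)
  if (which %in% c("gradient", "both")) {
    tr <- gt$volume_onsets[2] - gt$volume_onsets[1]
    tpl <- resamp(gt$gradient_template, fs_native, fs, tr)
    track <- numeric(n_samp)
    for (k in seq_along(gt$volume_onsets)) {
      i0 <- round(gt$volume_onsets[k] * fs) + 1L
      idx <- i0:(i0 + length(tpl) - 1L)
      idx <- idx[idx <= n_samp]
      track[idx] <- track[idx] + gt$gradient_epoch_jitter[k] * tpl[seq_along(idx)]
    }
    out <- out + outer(gt$gradient_gain, rep(1, n_samp)) *
      matrix(track, n_ch, n_samp, byrow = TRUE)
  }
  if (which %in% c("bcg", "both")) {
    tpl <- resamp(gt$bcg_template, fs_native, fs, 0.5)
    track <- numeric(n_samp)
    for (r in gt$r_peak_times) {
      i0 <- round((r + 0.21) * fs) + 1L
      if (i0 > n_samp) next
      idx <- i0:(i0 + length(tpl) - 1L)
      idx <- idx[idx <= n_samp]
      track[idx] <- track[idx] + tpl[seq_along(idx)]
    }
    out <- out + outer(gt$bcg_gain, rep(1, n_samp)) *
      matrix(track, n_ch, n_samp, byrow = TRUE)
  }
  out
}

#' Simulate a BOLD series coupled to the alpha envelope
#'
#' Voxel time course: `baseline * (1 + coupling * z)` where `z` is the
#' HRF-convolved envelope standardized over the acquired volumes, plus a
#' slow drift and Gaussian noise. Negative couplings yield anti-correlated
#' voxels.
#'
#' @param envelope an [generate_envelope()] result.
#' @param coupling_map 3D array matching `grid_shape`; signed fraction of
#'   baseline per unit (sd) of convolved envelope.
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return A [bold_series()].
#' @export
simulate_bold <- function(envelope, coupling_map, config, seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  if (!all(dim(coupling_map) == config$grid_shape))
    stop("coupling_map must match grid_shape", call. = FALSE)
  if (any(!is.finite(coupling_map)))
    stop("coupling_map must be finite", call. = FALSE)
  if (config$n_volumes <= 6)
    stop("n_volumes must exceed 6 (initial volumes are dropped downstream)",
         call. = FALSE)
  fs_env <- attr(envelope, "fs")
  onsets <- seq(0, by = config$tr, length.out = config$n_volumes)

  # convolve the envelope with the canonical HRF on a 0.1 s grid
  dt <- 0.1
  t_env <- (seq_along(envelope) - 1) / fs_env
  t_grid <- seq(0, max(onsets) + config$tr, by = dt)
  env_g <- approx(t_env, as.numeric(envelope), xout = t_grid, rule = 2)$y
  hrf <- canonical_hrf(dt = dt)
  conv_full <- stats::convolve(env_g, rev(hrf$values), type = "open") * dt
  conv_g <- conv_full[seq_along(t_grid)]
  z <- approx(t_grid, conv_g, xout = onsets, rule = 2)$y
  z <- (z - mean(z)) / sd(z)

  nv <- config$n_volumes
  nvox <- prod(config$grid_shape)
  b0 <- config$baseline_bold
  withr::with_seed(seed, {
    drift <- b0 * config$drift_amplitude *
      (seq_len(nv) / nv + 0.5 * cos(2 * pi * onsets / 300))
    noise <- if (config$noise_sd_bold > 0)
      matrix(rnorm(nvox * nv, 0, b0 * config$noise_sd_bold), nvox, nv)
    else matrix(0, nvox, nv)
    sig <- b0 * (1 + as.numeric(coupling_map) %o% z)
    mat <- sig + noise + matrix(drift, nvox, nv, byrow = TRUE)
    bold_series(array(mat, c(config$grid_shape, nv)),
                voxel_size = config$voxel_size, tr = config$tr)
  })
}

subject_seed <- function(master_seed, i) {
  as.integer((as.numeric(master_seed) * 1009 + 7919 * i) %% 2147483629)
}

# Table-1-style covariate distributions; hippocampal means/sds chosen to
# give a modest, non-significant AD reduction (see methods vignette)
covariate_params <- list(
  AD = list(age = c(75.3, 5.7), edu = c(14.4, 2.7), mmse = c(24.6, 3.1),
            hippo = c(0.0040, 0.0007), p_female = 4 / 14),
  HC = list(age = c(73.4, 3.1), edu = c(13.6, 2.8), mmse = c(28.7, 0.8),
            hippo = c(0.0044, 0.0005), p_female = 4 / 14)
)

draw_covariates <- function(group, subject_id) {
  p <- covariate_params[[group]]
  tibble::tibble(
    subject_id = subject_id, group = group,
    age = rnorm(1, p$age[1], p$age[2]),
    gender = rbinom(1, 1, p$p_female),
    education = rnorm(1, p$edu[1], p$edu[2]),
    mmse = rnorm(1, p$mmse[1], p$mmse[2]),
    hippo_norm = rnorm(1, p$hippo[1], p$hippo[2])
  )
}

#' Simulate a two-group simultaneous EEG-fMRI cohort
#'
#' @param config a [sim_config()].
#' @param groups named list with entries `AD` and `HC`, each a list with
#'   `n` (group size, >= 2) and `coupling_map` (3D array matching
#'   `grid_shape`).
#' @param seed master seed; per-subject seeds are derived from it.
#' @param materialize if `TRUE` (default) simulate EEG and BOLD for every
#'   subject up front; if `FALSE` return lightweight subject specs and use
#'   [simulate_subject()] to materialize one subject at a time (the
#'   pipeline does this to bound memory).
#' @return A list of class `cohort_dataset` with elements `subjects`,
#'   `covariates` (tibble), `config`, `groups`, `seed`.
#' @export
simulate_cohort <- function(config, groups, seed = 1L, materialize = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  if (!all(c("AD", "HC") %in% names(groups)))
    stop("groups must be named AD and HC", call. = FALSE)
  for (g in names(groups)) {
    if (groups[[g]]$n < 2) stop("group size must be >= 2", call. = FALSE)
    if (!all(dim(groups[[g]]$coupling_map) == config$grid_shape))
      stop("coupling maps must share grid_shape", call. = FALSE)
  }
  specs <- list()
  i <- 0L
  for (g in c("AD", "HC")) {
    for (k in seq_len(groups[[g]]$n)) {
      i <- i + 1L
      specs[[i]] <- list(subject_id = sprintf("sub-%s%02d", g, k), group = g,
                         seed = subject_seed(seed, i))
    }
  }
  covariates <- withr::with_seed(seed, {
    do.call(rbind, lapply(specs, function(s)
      draw_covariates(s$group, s$subject_id)))
  })
  cohort <- structure(
    list(subjects = specs, covariates = covariates, config = config,
         groups = groups, seed = seed),
    class = "cohort_dataset"
  )
  if (materialize) {
    cohort$subjects <- lapply(seq_along(specs), function(j)
      simulate_subject(cohort, j))
  }
  cohort
}

#' Materialize one subject of a simulated cohort
#'
#' @param cohort a [simulate_cohort()] result (materialized or not).
#' @param i subject index.
#' @return The subject spec extended with `eeg` ([eeg_recording()]),
#'   `bold` ([bold_series()]) and `ground_truth`.
#' @export
simulate_subject <- function(cohort, i) {
  s <- cohort$subjects[[i]]
  if (!is.null(s$eeg)) return(s)
  cfg <- cohort$config
  env <- generate_envelope(cfg$duration, cfg$fs_env, cfg$envelope_ar_coeff,
                           cfg$envelope_mean, cfg$envelope_sd, seed = s$seed)
  sim <- simulate_eeg(env, cfg, seed = s$seed + 1L)
  bold <- simulate_bold(env, cohort$groups[[s$group]]$coupling_map, cfg,
                        seed = s$seed + 2L)
  c(s, list(eeg = sim$rec, bold = bold, ground_truth = sim$ground_truth))
}

#' @export
print.cohort_dataset <- function(x, ...) {
  tab <- table(vapply(x$subjects, `[[`, "", "group"))
  cat(sprintf("<cohort_dataset> %d subjects (%s) on a %s grid\n",
              length(x$subjects),
              paste(names(tab), tab, sep = "=", collapse = ", "),
              paste(x$config$grid_shape, collapse = "x")))
  invisible(x)
}

#' Synthetic gray-matter probability template
#'
#' A centered spherical probability field: 1 well inside the "brain",
#' falling smoothly to 0 at the edge of the grid. Stands in for a
#' population GM template on the simulated common-space grid.
#'
#' @param grid_shape integer length-3 vector.
#' @param radius_frac sphere radius as a fraction of the smallest half-axis.
#' @return 3D array of probabilities in `[0, 1]`.
#' @export
synthetic_gm_template <- function(grid_shape = c(20L, 20L, 20L),
                                  radius_frac = 0.85) {
  ctr <- (grid_shape + 1) / 2
  r0 <- radius_frac * min(grid_shape) / 2
  g <- expand.grid(x = seq_len(grid_shape[1]), y = seq_len(grid_shape[2]),
                   z = seq_len(grid_shape[3]))
  d <- sqrt((g$x - ctr[1])^2 + (g$y - ctr[2])^2 + (g$z - ctr[3])^2)
  p <- pmin(1, pmax(0, 1.25 - d / r0))
  array(p, grid_shape)
}

# rectangular block mask helper (1-based inclusive index ranges)
block_mask <- function(grid_shape, xr, yr, zr) {
  m <- array(FALSE, grid_shape)
  m[xr, yr, zr] <- TRUE
  m
}

#' Demonstration cohort configuration
#'
#' The bundled end-to-end demonstration: HC subjects carry positive
#' envelope/BOLD coupling in region A and negative coupling in region B;
#' AD subjects carry no coupling anywhere. EEG is simulated at 500 Hz
#' (decimated to 250 Hz by the pipeline) to keep the demonstration light;
#' all other acquisition parameters keep their protocol defaults.
#'
#' @param n_per_group subjects per group (default 8).
#' @param coupling signed coupling strength (fraction of baseline per sd
#'   of convolved envelope; default 0.02).
#' @param fs_eeg EEG sampling rate for the demonstration.
#' @param ... passed on to [sim_config()].
#' @return list with `config`, `groups`, `region_a`, `region_b`,
#'   `gm_template`, `roi_masks` (DMN-like = region A, thalamus-like block).
#' @export
demo_cohort_spec <- function(n_per_group = 8, coupling = 0.02,
                             fs_eeg = 500, ...) {
  config <- sim_config(fs_eeg = fs_eeg, ...)
  gs <- config$grid_shape
  region_a <- block_mask(gs, 5:9, 5:9, 8:12)      # 125 voxels, DMN-like
  region_b <- block_mask(gs, 13:17, 13:17, 8:12)  # 125 voxels, occipital-like
  thalamus <- block_mask(gs, 9:12, 9:12, 9:12)    # small central block
  cmap_hc <- array(0, gs)
  cmap_hc[region_a] <- coupling
  cmap_hc[region_b] <- -coupling
  cmap_ad <- array(0, gs)
  list(
    config = config,
    groups = list(AD = list(n = n_per_group, coupling_map = cmap_ad),
                  HC = list(n = n_per_group, coupling_map = cmap_hc)),
    region_a = region_a, region_b = region_b,
    gm_template = synthetic_gm_template(gs),
    roi_masks = list(DMN = region_a, thalamus = thalamus)
  )
}
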