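#' @importFrom signal butter filtfilt
NULL

filtfilt_rows <- function(mat, filt) {
  for (i in seq_len(nrow(mat))) mat[i, ] <- signal::filtfilt(filt, mat[i, ])
  mat
}

#' Downsample an EEG recording by an integer factor
#'
#' Applies a zero-phase 8th-order Butterworth anti-alias low-pass at 80% of
#' the new Nyquist frequency before keeping every k-th sample. Marker times
#' are in seconds and therefore unchanged.
#'
#' @param rec an [eeg_recording()].
#' @param target_fs new sampling rate, Hz; must divide `rec$fs` exactly.
#' @return The decimated [eeg_recording()].
#' @export
decimate_eeg <- function(rec, target_fs = 250) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (target_fs >= rec$fs)
    stop("target_fs must be below the current sampling rate", call. = FALSE)
  factor <- rec$fs / target_fs
  if (abs(factor - round(factor)) > 1e-9)
    stop("fs must be an integer multiple of target_fs", call. = FALSE)
  factor <- as.integer(round(factor))
  aa <- signal::butter(8, 0.8 * (target_fs / 2) / (rec$fs / 2), type = "low")
  data <- filtfilt_rows(rec$data, aa)
  data <- data[, seq(1, ncol(data), by = factor), drop = FALSE]
  out <- eeg_recording(data, target_fs, rec$channel_labels, rec$markers,
                       rec$history)
  record_step(out, "decimate", target_fs = target_fs, factor = factor)
}

#' Epoch onsets from recording markers
#'
#' @param rec an [eeg_recording()].
#' @param marker_type marker type to use (scanner volume triggers are
#'   written as `"Scanner"`).
#' @return strictly increasing onset times in seconds. Warns when the
#'   inter-onset spacing varies by more than one sample.
#' @export
epoch_onsets_from_markers <- function(rec, marker_type = "Scanner") {
  onsets <- sort(rec$markers$time[rec$markers$type == marker_type])
  if (length(onsets) < 2)
    stop(sprintf("need at least 2 markers of type '%s' (found %d)",
                 marker_type, length(onsets)), call. = FALSE)
  spacing <- diff(onsets)
  if (diff(range(spacing)) > 1 / rec$fs + 1e-12)
    warning("inter-onset spacing varies by more than one sample",
            call. = FALSE)
  onsets
}

# sliding-window mean over epoch index: for epoch k, the mean of the
# n_avg nearest epochs (window centered on k, truncated at the edges)
sliding_epoch_template <- function(E, n_avg) {
  K <- ncol(E)
  half <- floor(n_avg / 2)
  tpl <- matrix(0, nrow(E), K)
  for (k in seq_len(K)) {
    win <- max(1L, k - half):min(K, k + half)
    tpl[, k] <- rowMeans(E[, win, drop = FALSE])
  }
  tpl
}

#' Average-artifact subtraction (AAS)
#'
#' Removes a trigger-locked periodic artifact (MR gradient or pulse) by
#' subtracting, inside each epoch, the mean over the `n_avg` nearest
#' epochs (centered sliding window, truncated at the recording edges).
#' Samples outside epoch windows are untouched.
#'
#' @param rec an [eeg_recording()].
#' @param onsets epoch onset times, s (e.g. from
#'   [epoch_onsets_from_markers()]).
#' @param epoch_len epoch length, s.
#' @param n_avg sliding-window width in epochs (default 21).
#' @param channels channels to process (default all).
#' @return The corrected [eeg_recording()].
#' @export
aas_subtract <- function(rec, onsets, epoch_len, n_avg = 21,
                         channels = rec$channel_labels) {
  stopifnot(inherits(rec, "eeg_recording"), n_avg >= 1)
  fs <- rec$fs
  len <- round(epoch_len * fs)
  i0 <- round(onsets * fs) + 1L
  if (any(diff(i0) < len))
    stop("epochs overlap: reduce epoch_len or check onsets", call. = FALSE)
  if (max(i0) + len - 1L > n_samples(rec))
    stop("epoch extends past the end of the recording", call. = FALSE)
  idx <- match(channels, rec$channel_labels)
  for (ci in idx) {
    E <- vapply(i0, function(s) rec$data[ci, s:(s + len - 1L)], numeric(len))
    tpl <- sliding_epoch_template(E, n_avg)
    for (k in seq_along(i0)) {
      s <- i0[k]
      rec$data[ci, s:(s + len - 1L)] <-
        rec$data[ci, s:(s + len - 1L)] - tpl[, k]
    }
  }
  record_step(rec, "aas_subtract", epoch_len = epoch_len, n_avg = n_avg,
              n_epochs = length(i0))
}

#' Detect R peaks on an ECG channel
#'
#' Pan-Tompkins-style detector: 5-15 Hz band-pass, squaring, 0.12 s moving
#' average, adaptive threshold, 0.3 s refractory period, with peak times
#' refined on the band-passed signal.
#'
#' @param ecg numeric ECG samples.
#' @param fs sampling rate, Hz.
#' @return strictly increasing peak times in seconds; a flat or empty
#'   signal gives an empty result with a warning.
#' @export
detect_r_peaks <- function(ecg, fs) {
  if (length(ecg) < 10 * fs)
    stop("need at least 10 s of ECG", call. = FALSE)
  if (stats::sd(ecg) < 1e-12) {
    warning("ECG is flat; no R peaks detected", call. = FALSE)
    return(numeric())
  }
  bp <- signal::butter(3, c(5, 15) / (fs / 2), type = "pass")
  y <- signal::filtfilt(bp, ecg)
  e <- y^2
  w <- max(1L, round(0.12 * fs))
  ma <- as.numeric(stats::filter(e, rep(1 / w, w), sides = 2))
  ma[is.na(ma)] <- 0
  thr <- 0.25 * stats::quantile(ma, 0.99)
  above <- ma > thr
  # rising edges of suprathreshold runs, then greedy refractory scan
  starts <- which(diff(c(FALSE, above)) == 1)
  ends <- which(diff(c(above, FALSE)) == -1)
  cand <- mapply(function(s, e2) s - 1L + which.max(ma[s:e2]), starts, ends)
  cand <- sort(cand)
  keep <- numeric(0)
  last <- -Inf
  for (p in cand) {
    if ((p - last) / fs >= 0.3) { keep <- c(keep, p); last <- p }
  }
  # refine on the band-passed amplitude within +/- 50 ms
  half <- round(0.05 * fs)
  refined <- vapply(keep, function(p) {
    lo <- max(1L, p - half); hi <- min(length(y), p + half)
    lo - 1L + which.max(abs(y[lo:hi]))
  }, numeric(1))
  refined <- sort(unique(refined))
  # sub-sample refinement: cross-correlate each beat against the mean
  # beat waveform and interpolate the correlation peak parabolically
  # (pulse-artifact templates are sensitive to sample-level beat jitter)
  w <- round(0.1 * fs)
  ok <- refined - w >= 1 & refined + w <= length(ecg)
  if (sum(ok) >= 3) {
    beats <- vapply(refined[ok], function(p) ecg[(p - w):(p + w)],
                    numeric(2 * w + 1))
    mb <- rowMeans(beats)
    # search up to ~50 ms: the band-pass refinement occasionally locks
    # onto a neighboring oscillation lobe
    shifts <- -round(0.05 * fs):round(0.05 * fs)
    nb <- 2 * w + 1
    refined[ok] <- refined[ok] + vapply(seq_len(ncol(beats)), function(k) {
      cc <- vapply(shifts, function(s) {
        i <- seq_len(nb) - s
        good <- i >= 1 & i <= nb
        sum(beats[good, k] * mb[i[good]])
      }, numeric(1))
      ib <- which.max(cc)
      d <- shifts[ib]
      if (ib > 1 && ib < length(shifts)) {
        y1 <- cc[ib - 1]; y2 <- cc[ib]; y3 <- cc[ib + 1]
        den <- y1 - 2 * y2 + y3
        if (den < 0) d <- d + 0.5 * (y1 - y3) / den
      }
      d
    }, numeric(1))
  }
  (sort(refined) - 1) / fs
}

# per-epoch fractional alignment: locate the lag by cross-correlation
# with parabolic refinement, then keep whichever candidate (including the
# unshifted template) minimizes the residual energy — so an already
# perfectly aligned template is subtracted untouched
align_template <- function(d, tk, max_shift = 3) {
  shifts <- -max_shift:max_shift
  n <- length(tk)
  cc <- vapply(shifts, function(s) {
    i <- seq_len(n) - s
    ok <- i >= 1 & i <= n
    sum(d[ok] * tk[i[ok]])
  }, numeric(1))
  i_best <- which.max(cc)
  delta <- shifts[i_best]
  if (i_best > 1 && i_best < length(shifts)) {
    y1 <- cc[i_best - 1]; y2 <- cc[i_best]; y3 <- cc[i_best + 1]
    denom <- y1 - 2 * y2 + y3
    if (denom < 0) delta <- delta + 0.5 * (y1 - y3) / denom
  }
  best <- tk
  best_e <- sum((d - tk)^2)
  for (s in setdiff(unique(c(shifts[i_best], delta)), 0)) {
    tks <- approx(seq_len(n), tk, xout = seq_len(n) - s, rule = 2)$y
    e <- sum((d - tks)^2)
    if (e < best_e) { best_e <- e; best <- tks }
  }
  best
}

#' Ballistocardiogram template subtraction
#'
#' Removes the cardiac pulse artifact by sliding-window average-artifact
#' subtraction over heartbeat epochs `[peak + delay, peak + delay +
#' template_len)`. Before subtraction each beat's template is aligned to
#' the data at fractional-sample resolution by cross-correlation (pulse
#' timing is asynchronous with the sampling grid, and R-peak estimates
#' carry sample-level jitter). The ECG channel itself is left untouched.
#'
#' @param rec an [eeg_recording()].
#' @param r_peaks R-peak times, s (from [detect_r_peaks()]).
#' @param delay epoch start relative to the R peak, s (default 0.21).
#' @param template_len epoch length, s; must not exceed the median RR
#'   interval.
#' @param n_avg sliding-window width in heartbeats (default 21).
#' @param align per-beat fractional template alignment (default `TRUE`).
#' @return The corrected [eeg_recording()].
#' @export
bcg_subtract <- function(rec, r_peaks, delay = 0.21, template_len = 0.5,
                         n_avg = 21, align = TRUE) {
  stopifnot(inherits(rec, "eeg_recording"), delay >= 0)
  if (!length(r_peaks)) stop("r_peaks is empty", call. = FALSE)
  if (length(r_peaks) > 1 && template_len > stats::median(diff(r_peaks)))
    stop("template_len exceeds the median RR interval; use a shorter template",
         call. = FALSE)
  fs <- rec$fs
  len <- round(template_len * fs)
  pos <- (r_peaks + delay) * fs          # fractional start, 0-based samples
  i0 <- as.integer(floor(pos + 1e-9)) + 1L   # tolerate rounding at integers
  frac <- pmax(pos - (i0 - 1L), 0)       # sub-sample beat phase
  ok <- i0 + len <= n_samples(rec) & i0 >= 1L
  i0 <- i0[ok]; frac <- frac[ok]
  if (!length(i0)) stop("no heartbeat epoch fits within the recording",
                        call. = FALSE)
  grid <- seq_len(len)
  idx <- which(rec$channel_labels != "ECG")
  for (ci in idx) {
    # extract one extra sample so each epoch can be resampled onto the
    # common beat phase before averaging
    E_raw <- vapply(i0, function(s) rec$data[ci, s:(s + len)],
                    numeric(len + 1L))
    E <- vapply(seq_along(i0), function(k)
      approx(seq_len(len + 1L), E_raw[, k], xout = grid + frac[k])$y,
      numeric(len))
    tpl <- sliding_epoch_template(E, n_avg)
    for (k in seq_along(i0)) {
      tk <- if (align) align_template(E[, k], tpl[, k]) else tpl[, k]
      # back onto the sampling grid of this beat
      tk <- approx(grid, tk, xout = grid - frac[k], rule = 2)$y
      s <- i0[k]
      rec$data[ci, s:(s + len - 1L)] <-
        rec$data[ci, s:(s + len - 1L)] - tk
    }
  }
  record_step(rec, "bcg_subtract", delay = delay,
              template_len = template_len, n_avg = n_avg, align = align,
              n_beats = length(i0))
}

#' Band-pass and notch filtering
#'
#' Zero-phase (forward-backward) 4th-order Butterworth high- and low-pass
#' plus a 2 Hz-wide band-stop notch.
#'
#' @param rec an [eeg_recording()].
#' @param hp high-pass edge, Hz.
#' @param lp low-pass edge, Hz.
#' @param notch notch center, Hz (`NULL` disables).
#' @return The filtered [eeg_recording()].
#' @export
filter_eeg <- function(rec, hp = 0.5, lp = 70, notch = 50) {
  stopifnot(inherits(rec, "eeg_recording"))
  nyq <- rec$fs / 2
  if (!(hp > 0 && hp < lp && lp < nyq))
    stop("band edges must satisfy 0 < hp < lp < fs/2", call. = FALSE)
  rec$data <- filtfilt_rows(rec$data, signal::butter(4, hp / nyq, "high"))
  rec$data <- filtfilt_rows(rec$data, signal::butter(4, lp / nyq, "low"))
  if (!is.null(notch)) {
    if (notch + 1 >= nyq) stop("notch too close to Nyquist", call. = FALSE)
    bs <- signal::butter(2, c(notch - 1, notch + 1) / nyq, "stop")
    rec$data <- filtfilt_rows(rec$data, bs)
  }
  record_step(rec, "filter", hp = hp, lp = lp, notch = notch)
}

# --- compact symmetric fastICA (tanh contrast) -------------------------

whiten_rows <- function(X, tol = 1e-10) {
  mu <- rowMeans(X)
  Xc <- X - mu
  C <- Xc %*% t(Xc) / ncol(Xc)
  eg <- eigen(C, symmetric = TRUE)
  keep <- eg$values > tol * max(eg$values)
  K <- diag(1 / sqrt(eg$values[keep]), sum(keep)) %*% t(eg$vectors[, keep, drop = FALSE])
  list(Z = K %*% Xc, K = K, mu = mu)
}

fast_ica_rows <- function(Z, max_iter = 200, tol = 1e-6) {
  p <- nrow(Z); n <- ncol(Z)
  W <- matrix(rnorm(p * p), p, p)
  sym_decor <- function(W) {
    s <- svd(W)
    s$u %*% t(s$v)
  }
  W <- sym_decor(W)
  for (it in seq_len(max_iter)) {
    WZ <- W %*% Z
    G <- tanh(WZ)
    gp <- 1 - G^2
    W1 <- (G %*% t(Z)) / n - diag(rowMeans(gp)) %*% W
    W1 <- sym_decor(W1)
    delta <- max(abs(abs(rowSums(W1 * W)) - 1))
    W <- W1
    if (delta < tol) return(list(W = W, converged = TRUE))
  }
  list(W = W, converged = FALSE)
}

low_freq_fraction <- function(x, fs, f_cut = 2) {
  n <- length(x)
  P <- Mod(fft(x - mean(x))[seq_len(floor(n / 2))])^2
  f <- (seq_len(floor(n / 2)) - 1) * fs / n
  sum(P[f < f_cut]) / max(sum(P), .Machine$double.eps)
}

#' Automated ICA cleanup
#'
#' Decomposes the EEG channels (ECG excluded) with symmetric fastICA and
#' zeroes components that look cardiac (absolute correlation with the ECG
#' above `corr_thresh`) or ocular/drift-like (fraction of spectral power
#' below 2 Hz above `lowfreq_frac_thresh`), then reconstructs the data.
#' This is an automated proxy for manual component selection. If the
#' decomposition fails the stage is skipped with a warning.
#'
#' @param rec an [eeg_recording()]; must contain an `ECG` channel.
#' @param corr_thresh absolute ECG-correlation threshold (default 0.3).
#' @param lowfreq_frac_thresh low-frequency power-fraction threshold
#'   (default 0.6).
#' @param seed seed for the fastICA initialization.
#' @return The cleaned [eeg_recording()]; the indices of removed
#'   components are recorded in its history.
#' @export
ica_autoclean <- function(rec, corr_thresh = 0.3, lowfreq_frac_thresh = 0.6,
                          seed = 1L) {
  stopifnot(inherits(rec, "eeg_recording"))
  eeg_idx <- which(rec$channel_labels != "ECG")
  if (length(eeg_idx) < 2) stop("need at least 2 EEG channels", call. = FALSE)
  require_channels(rec, "ECG")
  ecg <- rec$data["ECG", ]
  res <- tryCatch({
    wh <- whiten_rows(rec$data[eeg_idx, , drop = FALSE])
    fit <- withr::with_seed(seed, fast_ica_rows(wh$Z))
    S <- fit$W %*% wh$Z
    unmix <- fit$W %*% wh$K                      # sources = unmix %*% centered X
    A <- pinv(unmix)                             # mixing (pseudo-inverse)
    remove <- which(
      abs(apply(S, 1, stats::cor, y = ecg)) > corr_thresh |
        apply(S, 1, low_freq_fraction, fs = rec$fs) > lowfreq_frac_thresh
    )
    list(S = S, A = A, mu = wh$mu, remove = remove)
  }, error = function(e) NULL)
  if (is.null(res)) {
    warning("ICA decomposition failed; stage skipped", call. = FALSE)
    return(record_step(rec, "ica_autoclean", skipped = TRUE))
  }
  if (length(res$remove)) {
    S_clean <- res$S
    S_clean[res$remove, ] <- 0
    rec$data[eeg_idx, ] <- res$A %*% S_clean + res$mu
  }
  record_step(rec, "ica_autoclean", removed = res$remove,
              corr_thresh = corr_thresh,
              lowfreq_frac_thresh = lowfreq_frac_thresh)
}

# Moore-Penrose pseudo-inverse via SVD (square, near-full-rank use)
pinv <- function(M, tol = 1e-10) {
  s <- svd(M)
  pos <- s$d > tol * max(s$d)
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' Artifact interval mask
#'
#' @param intervals tibble/data frame with columns `start`, `end` (s,
#'   half-open) and logical `flagged` (interval length at least the
#'   minimum duration fed to the nuisance regressor).
#' @param duration total recording duration, s.
#' @return object of class `artifact_mask`.
#' @export
artifact_mask <- function(intervals, duration) {
  intervals <- tibble::as_tibble(intervals)
  if (nrow(intervals)) {
    stopifnot(all(intervals$end > intervals$start),
              all(intervals$start >= 0), all(intervals$end <= duration))
    o <- order(intervals$start)
    intervals <- intervals[o, ]
    if (any(utils::head(intervals$end, -1) > utils::tail(intervals$start, -1)))
      stop("artifact intervals overlap", call. = FALSE)
  }
  structure(list(intervals = intervals, duration = duration),
            class = "artifact_mask")
}

#' @export
print.artifact_mask <- function(x, ...) {
  cat(sprintf("<artifact_mask> %d interval(s) over %.1f s (%d flagged >= min duration)\n",
              nrow(x$intervals), x$duration, sum(x$intervals$flagged)))
  invisible(x)
}

#' Mark high-amplitude artifact intervals
#'
#' Computes a moving RMS (0.2 s window) of the series, converts it to a
#' robust z-score (median/MAD), and marks intervals where it exceeds
#' `z_thresh`. Intervals separated by less than 0.5 s are merged; those at
#' least `min_dur` long are flagged for the artifact nuisance regressor.
#'
#' @param x numeric series (e.g. the pooled occipital channel).
#' @param fs sampling rate, Hz.
#' @param z_thresh robust z threshold (default 4).
#' @param min_dur flagging duration, s (default 1).
#' @return an [artifact_mask()].
#' @export
mark_artifacts <- function(x, fs, z_thresh = 4, min_dur = 1.0) {
  stopifnot(all(is.finite(x)))
  w <- max(1L, round(0.2 * fs))
  rms <- sqrt(as.numeric(stats::filter(x^2, rep(1 / w, w), sides = 2)))
  rms[is.na(rms)] <- stats::median(rms, na.rm = TRUE)
  med <- stats::median(rms)
  madv <- stats::mad(rms)
  z <- (rms - med) / max(madv, 1e-12)
  above <- z > z_thresh
  dur <- length(x) / fs
  if (!any(above))
    return(artifact_mask(tibble::tibble(start = numeric(), end = numeric(),
                                        flagged = logical()), dur))
  starts <- (which(diff(c(FALSE, above)) == 1) - 1) / fs
  ends <- which(diff(c(above, FALSE)) == -1) / fs
  # merge gaps shorter than 0.5 s
  ms <- starts[1]; me <- ends[1]
  out_s <- numeric(); out_e <- numeric()
  for (i in seq_along(starts)[-1]) {
    if (starts[i] - me < 0.5) me <- ends[i]
    else { out_s <- c(out_s, ms); out_e <- c(out_e, me)
           ms <- starts[i]; me <- ends[i] }
  }
  out_s <- c(out_s, ms); out_e <- c(out_e, me)
  artifact_mask(tibble::tibble(start = out_s, end = pmin(out_e, dur),
                               flagged = (out_e - out_s) >= min_dur), dur)
}

#' Re-reference to the common average
#'
#' Subtracts the instantaneous mean over all EEG channels (ECG excluded)
#' from every EEG channel; the re-referenced channels sum to zero at each
#' sample.
#'
#' @param rec an [eeg_recording()].
#' @return The re-referenced [eeg_recording()].
#' @export
rereference_common_average <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  idx <- which(rec$channel_labels != "ECG")
  if (length(idx) < 2) stop("need at least 2 EEG channels", call. = FALSE)
  avg <- colMeans(rec$data[idx, , drop = FALSE])
  rec$data[idx, ] <- sweep(rec$data[idx, , drop = FALSE], 2, avg)
  record_step(rec, "rereference_common_average")
}

#' Pool the occipital channels
#'
#' Sample-wise arithmetic mean of the occipital electrodes of interest.
#'
#' @param rec an [eeg_recording()].
#' @param channels channels to pool (default O1, O2, Oz).
#' @return numeric series with attribute `fs`.
#' @export
pool_occipital <- function(rec, channels = c("O1", "O2", "Oz")) {
  require_channels(rec, channels)
  out <- colMeans(rec$data[channels, , drop = FALSE])
  attr(out, "fs") <- rec$fs
  out
}
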