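#' Frequency band definition
#'
#' @param name band name.
#' @param f_lo,f_hi band edges in Hz, `f_lo < f_hi`.
#' @return object of class `band`.
#' @export
band <- function(name, f_lo, f_hi) {
  stopifnot(is.character(name), f_lo < f_hi, f_lo > 0)
  structure(list(name = name, f_lo = f_lo, f_hi = f_hi), class = "band")
}

#' The shipped alpha bands
#'
#' Total (8-12 Hz), lower (8-10 Hz) and upper (10-12 Hz) alpha.
#' @return named list of [band()] objects.
#' @export
alpha_bands <- function() {
  list(total_alpha = band("total_alpha", 8, 12),
       lower_alpha = band("lower_alpha", 8, 10),
       upper_alpha = band("upper_alpha", 10, 12))
}

#' @export
print.band <- function(x, ...) {
  cat(sprintf("<band> %s: %g-%g Hz\n", x$name, x$f_lo, x$f_hi))
  invisible(x)
}

#' Instantaneous band power by complex demodulation
#'
#' Multiplies the series by a complex exponential at the band center
#' frequency, zero-phase low-pass filters at half the bandwidth, and
#' returns twice the squared magnitude, so a pure in-band sinusoid of
#' amplitude A yields mean power A^2/2. The first and last 2 s are marked
#' edge-invalid (filter transients).
#'
#' @param x numeric series (microvolts).
#' @param fs sampling rate, Hz; must exceed twice the upper band edge.
#' @param band a [band()].
#' @param lp_order Butterworth order of the demodulation low-pass.
#' @return object of class `demod_power`: instantaneous power (uV^2) at
#'   `fs` with the band and edge-invalid margin attached.
#' @export
complex_demodulate <- function(x, fs, band, lp_order = 4) {
  stopifnot(inherits(band, "band"))
  if (fs <= 2 * band$f_hi)
    stop("band extends above the Nyquist frequency", call. = FALSE)
  fc <- (band$f_lo + band$f_hi) / 2
  bw <- (band$f_hi - band$f_lo) / 2
  t <- (seq_along(x) - 1) / fs
  rot <- exp(-2i * pi * fc * t)
  y <- as.numeric(x) * rot
  lp <- signal::butter(lp_order, bw / (fs / 2), type = "low")
  yr <- signal::filtfilt(lp, Re(y))
  yi <- signal::filtfilt(lp, Im(y))
  structure(list(values = 2 * (yr^2 + yi^2), fs = fs, band = band,
                 edge_sec = 2),
            class = "demod_power")
}

#' Band-power series in 1-second segments
#'
#' @param values numeric vector of power per segment (uV^2).
#' @param valid logical vector, one per segment.
#' @param band a [band()].
#' @return object of class `power_series` (rate 1 Hz).
#' @export
power_series <- function(values, valid = rep(TRUE, length(values)), band) {
  stopifnot(all(values >= 0 | !valid | is.na(values)),
            length(valid) == length(values), inherits(band, "band"))
  structure(list(values = as.numeric(values), rate = 1, valid = valid,
                 band = band),
            class = "power_series")
}

#' @export
print.power_series <- function(x, ...) {
  cat(sprintf("<power_series> %s: %d one-second segments (%d valid)\n",
              x$band$name, length(x$values), sum(x$valid)))
  invisible(x)
}

#' @export
plot.power_series <- function(x, ...) {
  tt <- seq_along(x$values) - 0.5
  plot(tt, x$values, type = "l", xlab = "time (s)",
       ylab = expression(power ~ (mu * V^2)),
       main = x$band$name, ...)
  if (any(!x$valid))
    graphics::points(tt[!x$valid], x$values[!x$valid], col = 2, pch = 4)
  invisible(x)
}

#' Average instantaneous power into 1-second segments
#'
#' Non-overlapping 1-s means of a [complex_demodulate()] output. Segments
#' intersecting artifact-mask intervals or the demodulation edge-invalid
#' margins are flagged invalid.
#'
#' @param dp a `demod_power` object.
#' @param seg segment length, s (1 s by design).
#' @param mask optional [artifact_mask()].
#' @return a [power_series()] with `floor(duration)` segments.
#' @export
segment_power <- function(dp, seg = 1, mask = NULL) {
  stopifnot(inherits(dp, "demod_power"))
  dur <- length(dp$values) / dp$fs
  if (dur < seg) stop("series shorter than one segment", call. = FALSE)
  n_seg <- floor(dur / seg)
  spp <- round(seg * dp$fs)
  vals <- vapply(seq_len(n_seg), function(k)
    mean(dp$values[((k - 1) * spp + 1):(k * spp)]), numeric(1))
  s0 <- (seq_len(n_seg) - 1) * seg
  s1 <- s0 + seg
  valid <- s0 >= dp$edge_sec & s1 <= dur - dp$edge_sec
  if (!is.null(mask) && nrow(mask$intervals)) {
    for (i in seq_len(nrow(mask$intervals))) {
      hit <- s1 > mask$intervals$start[i] & s0 < mask$intervals$end[i]
      valid <- valid & !hit
    }
  }
  power_series(vals, valid, dp$band)
}

#' Relative band power from short-segment periodograms
#'
#' Mean over non-overlapping 1-s rectangular-windowed periodograms of the
#' ratio of band power to power in a broad reference band.
#'
#' @param x numeric series.
#' @param fs sampling rate, Hz.
#' @param band a [band()].
#' @param total_band reference band `(lo, hi)` in Hz (default 1-40).
#' @param seg segment length, s.
#' @return scalar fraction in `[0, 1]`.
#' @export
fft_relative_power <- function(x, fs, band, total_band = c(1, 40), seg = 1) {
  stopifnot(inherits(band, "band"))
  if (band$f_lo < total_band[1] || band$f_hi > total_band[2])
    stop("band must lie inside total_band", call. = FALSE)
  dur <- length(x) / fs
  if (dur < 2 * seg) stop("need at least 2 s of data", call. = FALSE)
  spp <- round(seg * fs)
  n_seg <- floor(length(x) / spp)
  f <- (seq_len(spp) - 1) * fs / spp
  half <- f <= fs / 2
  in_band <- half & f >= band$f_lo & f <= band$f_hi
  in_total <- half & f >= total_band[1] & f <= total_band[2]
  ratios <- vapply(seq_len(n_seg), function(k) {
    seg_x <- x[((k - 1) * spp + 1):(k * spp)]
    P <- Mod(fft(seg_x - mean(seg_x)))^2
    tot <- sum(P[in_total])
    if (tot <= 0) return(NA_real_)
    sum(P[in_band]) / tot
  }, numeric(1))
  mean(ratios, na.rm = TRUE)
}
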