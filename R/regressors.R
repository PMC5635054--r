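#' Canonical double-gamma hemodynamic response function
#'
#' Difference of two gamma densities (peak at ~5 s, undershoot at ~15 s
#' for the defaults), evaluated on a regular grid and normalized so the
#' peak equals 1.
#'
#' @param dt sampling step, s.
#' @param a1,b1 shape and rate of the main-lobe gamma.
#' @param a2,b2 shape and rate of the undershoot gamma.
#' @param c undershoot amplitude ratio.
#' @param len kernel length, s.
#' @return object of class `hrf_kernel` with fields `values`, `t`, `dt`,
#'   `params`.
#' @export
canonical_hrf <- function(dt = 0.1, a1 = 6, a2 = 16, b1 = 1, b2 = 1,
                          c = 1 / 6, len = 32) {
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  if (any(c(a1, a2, b1, b2) <= 0))
    stop("gamma shape/rate parameters must be positive", call. = FALSE)
  t <- seq(0, len, by = dt)
  h <- stats::dgamma(t, shape = a1, rate = b1) -
    c * stats::dgamma(t, shape = a2, rate = b2)
  h <- h / max(h)
  structure(list(values = h, t = t, dt = dt,
                 params = list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c = c,
                               len = len)),
            class = "hrf_kernel")
}

#' @export
print.hrf_kernel <- function(x, ...) {
  cat(sprintf("<hrf_kernel> %g s at dt = %g s; peak at %.2f s\n",
              x$params$len, x$dt, x$t[which.max(x$values)]))
  invisible(x)
}

#' @export
plot.hrf_kernel <- function(x, ...) {
  plot(x$t, x$values, type = "l", xlab = "time (s)", ylab = "response", ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' Volume-grid regressor
#'
#' @param values one value per retained volume.
#' @param label predictor label.
#' @param volume_onsets onset times (s) of the retained volumes.
#' @return object of class `fmri_regressor`.
#' @export
fmri_regressor <- function(values, label, volume_onsets) {
  stopifnot(length(values) == length(volume_onsets), all(is.finite(values)))
  structure(list(values = as.numeric(values), label = label,
                 volume_onsets = as.numeric(volume_onsets)),
            class = "fmri_regressor")
}

#' @export
print.fmri_regressor <- function(x, ...) {
  cat(sprintf("<fmri_regressor> '%s': %d volumes (%.1f-%.1f s)\n", x$label,
              length(x$values), min(x$volume_onsets), max(x$volume_onsets)))
  invisible(x)
}

#' Build the HRF-convolved alpha-power regressor
#'
#' Invalid seconds of the power series are linearly interpolated from the
#' nearest valid neighbors, the series is mean-centered, convolved with
#' the canonical HRF at 1 Hz, and sampled at each retained volume onset by
#' linear interpolation. The first `drop_k` volumes are excluded to match
#' the dropped saturation volumes.
#'
#' @param ps a [power_series()].
#' @param hrf an [canonical_hrf()] kernel.
#' @param volume_onsets all acquired volume onsets, s.
#' @param drop_k number of initial volumes excluded (default 6).
#' @param center mean-center the power series before convolution
#'   (default `TRUE`).
#' @return an [fmri_regressor()] labeled `"alpha"`.
#' @export
build_alpha_regressor <- function(ps, hrf, volume_onsets, drop_k = 6,
                                  center = TRUE) {
  stopifnot(inherits(ps, "power_series"), inherits(hrf, "hrf_kernel"))
  x <- ps$values
  if (!any(ps$valid)) stop("all power segments are invalid", call. = FALSE)
  if (any(!ps$valid)) {
    good <- which(ps$valid)
    x <- approx(good, x[good], xout = seq_along(x), rule = 2)$y
  }
  if (center) x <- x - mean(x)
  t_sec <- seq_along(x) - 1                  # segment k covers [k-1, k)
  h <- approx(hrf$t, hrf$values, xout = seq(0, hrf$params$len, by = 1))$y
  conv <- stats::convolve(x, rev(h), type = "open")[seq_along(x)]
  keep <- volume_onsets[seq_along(volume_onsets) > drop_k]
  if (any(keep > max(t_sec) | keep < min(t_sec)))
    stop("volume onset outside the power series span", call. = FALSE)
  vals <- approx(t_sec, conv, xout = keep)$y
  fmri_regressor(vals, "alpha", keep)
}

#' Build the artifact nuisance regressor
#'
#' One value per retained volume: the fraction of the volume's
#' `[onset, onset + tr)` acquisition window overlapped by flagged
#' (>= 1 s) artifact intervals. Deliberately not HRF-convolved (a
#' regressor of no interest).
#'
#' @param mask an [artifact_mask()].
#' @param volume_onsets all acquired volume onsets, s.
#' @param tr repetition time, s.
#' @param drop_k number of initial volumes excluded (default 6).
#' @return an [fmri_regressor()] labeled `"artifact"`.
#' @export
build_artifact_regressor <- function(mask, volume_onsets, tr, drop_k = 6) {
  stopifnot(inherits(mask, "artifact_mask"))
  keep <- volume_onsets[seq_along(volume_onsets) > drop_k]
  iv <- mask$intervals[mask$intervals$flagged, , drop = FALSE]
  vals <- vapply(keep, function(on) {
    if (!nrow(iv)) return(0)
    ov <- pmin(iv$end, on + tr) - pmax(iv$start, on)
    sum(pmax(ov, 0)) / tr
  }, numeric(1))
  fmri_regressor(vals, "artifact", keep)
}
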