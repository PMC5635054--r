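#' Multichannel EEG recording
#'
#' Container for a multichannel EEG time series. Channels are rows of a
#' numeric matrix in microvolts; markers (e.g. per-volume scanner triggers)
#' live in a tibble keyed by time in seconds; `history` is an append-only
#' provenance list recording every operation applied to the data.
#'
#' @param data numeric matrix, channels x samples, in microvolts.
#' @param fs sampling rate in Hz.
#' @param channel_labels character vector, one per row of `data`. Occipital
#'   analyses require `O1`, `O2`, `Oz`; ballistocardiogram removal requires
#'   an `ECG` channel.
#' @param markers tibble or data frame with columns `time` (s), `type`,
#'   `label`. Scanner volume onsets carry type `"Scanner"`.
#' @param history list of prior processing steps (internal provenance).
#'
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, channel_labels = rownames(data),
                          markers = NULL, history = list()) {
  if (!is.matrix(data) || !is.numeric(data))
    stop("`data` must be a numeric channels x samples matrix", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("`fs` must be a positive finite scalar (Hz)", call. = FALSE)
  if (is.null(channel_labels))
    stop("channel labels are required", call. = FALSE)
  channel_labels <- as.character(channel_labels)
  if (length(channel_labels) != nrow(data))
    stop("one channel label per data row is required", call. = FALSE)
  rownames(data) <- channel_labels
  if (is.null(markers)) {
    markers <- tibble::tibble(time = numeric(), type = character(),
                              label = character())
  } else {
    markers <- tibble::as_tibble(markers)
    stopifnot(all(c("time", "type", "label") %in% names(markers)))
    dur <- ncol(data) / fs
    if (any(markers$time < 0 | markers$time > dur))
      stop("markers must lie within [0, duration]", call. = FALSE)
  }
  structure(
    list(data = data, fs = fs, channel_labels = channel_labels,
         markers = markers, history = history),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  cat("  channels:", paste(utils::head(x$channel_labels, 8), collapse = ", "),
      if (length(x$channel_labels) > 8) "..." else "", "\n")
  cat(sprintf("  markers: %d | history: %s\n", nrow(x$markers),
              if (length(x$history)) paste(vapply(x$history, `[[`, "", "op"),
                                           collapse = " > ") else "(raw)"))
  invisible(x)
}

n_samples <- function(rec) ncol(rec$data)

rec_duration <- function(rec) ncol(rec$data) / rec$fs

#' @export
plot.eeg_recording <- function(x, channels = x$channel_labels[1:min(4, nrow(x$data))],
                               tlim = NULL, ...) {
  idx <- match(channels, x$channel_labels)
  if (anyNA(idx)) stop("unknown channel(s): ",
                       paste(channels[is.na(idx)], collapse = ", "))
  t <- seq_len(ncol(x$data)) / x$fs
  keep <- if (is.null(tlim)) rep(TRUE, length(t)) else t >= tlim[1] & t <= tlim[2]
  off <- 3 * stats::median(apply(x$data[idx, keep, drop = FALSE], 1, stats::sd))
  plot(NA, xlim = range(t[keep]), ylim = c(0, (length(idx) + 1) * off),
       xlab = "time (s)", ylab = "", yaxt = "n", ...)
  for (i in seq_along(idx))
    graphics::lines(t[keep], x$data[idx[i], keep] + i * off)
  graphics::axis(2, at = seq_along(idx) * off, labels = channels, las = 1)
  invisible(x)
}

record_step <- function(rec, op, ...) {
  rec$history <- c(rec$history, list(c(list(op = op), list(...))))
  rec
}

require_channels <- function(rec, wanted) {
  missing <- setdiff(wanted, rec$channel_labels)
  if (length(missing))
    stop(sprintf("channel %s not found", paste(missing, collapse = ", ")),
         call. = FALSE)
  invisible(rec)
}

#' Extract a single channel as a numeric vector
#' @param rec an [eeg_recording()].
#' @param channel channel label.
#' @return numeric vector of samples (microvolts).
#' @export
get_channel <- function(rec, channel) {
  require_channels(rec, channel)
  rec$data[channel, ]
}
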