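#' Write an EEG recording as a BrainVision triplet
#'
#' Writes the `.vhdr` header, `.vmrk` marker file and multiplexed 32-bit
#' float `.eeg` binary next to each other. Scanner volume markers keep
#' their type so downstream average-artifact subtraction can find them.
#'
#' @param rec an [eeg_recording()].
#' @param path base path without extension (e.g. `"out/sub-01"`).
#' @return `path`, invisibly.
#' @export
write_brainvision <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  base <- basename(path)
  vhdr <- paste0(path, ".vhdr")
  vmrk <- paste0(path, ".vmrk")
  eeg  <- paste0(path, ".eeg")

  hdr <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "",
    "[Common Infos]",
    "Codepage=UTF-8",
    paste0("DataFile=", base, ".eeg"),
    paste0("MarkerFile=", base, ".vmrk"),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", nrow(rec$data)),
    # header stores the sampling interval in microseconds
    paste0("SamplingInterval=", format(1e6 / rec$fs, scientific = FALSE)),
    "",
    "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "",
    "[Channel Infos]",
    sprintf("Ch%d=%s,,1,µV", seq_len(nrow(rec$data)), rec$channel_labels)
  )
  writeLines(hdr, vhdr, useBytes = TRUE)

  mk <- rec$markers
  mrk <- c(
    "Brain Vision Data Exchange Marker File, Version 1.0",
    "",
    "[Common Infos]",
    "Codepage=UTF-8",
    paste0("DataFile=", base, ".eeg"),
    "",
    "[Marker Infos]",
    "Mk1=New Segment,,1,1,0,0"
  )
  if (nrow(mk)) {
    pos <- pmax(1L, as.integer(round(mk$time * rec$fs)) + 1L)
    mrk <- c(mrk, sprintf("Mk%d=%s,%s,%d,1,0",
                          seq_len(nrow(mk)) + 1L, mk$type, mk$label, pos))
  }
  writeLines(mrk, vmrk, useBytes = TRUE)

  con <- file(eeg, "wb")
  on.exit(close(con))
  # multiplexed: sample-major, channels interleaved
  writeBin(as.numeric(rec$data), con, size = 4L, endian = "little")
  invisible(path)
}

#' Read a BrainVision triplet
#'
#' Supports the subset written by [write_brainvision()]: binary multiplexed
#' IEEE float or 16-bit signed integer data with per-channel resolutions.
#'
#' @param vhdr path to the `.vhdr` header file.
#' @return An [eeg_recording()].
#' @export
read_brainvision <- function(vhdr) {
  lines <- readLines(vhdr, warn = FALSE)
  get_field <- function(key) {
    hit <- grep(paste0("^", key, "="), lines, value = TRUE)
    if (!length(hit)) stop("missing header field: ", key, call. = FALSE)
    sub(paste0("^", key, "="), "", hit[1])
  }
  n_ch <- as.integer(get_field("NumberOfChannels"))
  fs <- 1e6 / as.numeric(get_field("SamplingInterval"))
  fmt <- get_field("BinaryFormat")
  if (get_field("DataOrientation") != "MULTIPLEXED")
    stop("only MULTIPLEXED orientation is supported", call. = FALSE)

  ch_lines <- grep("^Ch[0-9]+=", lines, value = TRUE)
  ch_parts <- strsplit(sub("^Ch[0-9]+=", "", ch_lines), ",")
  labels <- vapply(ch_parts, `[[`, "", 1L)
  resol <- vapply(ch_parts, function(p)
    if (length(p) >= 3 && nzchar(p[[3]])) as.numeric(p[[3]]) else 1, 0)
  stopifnot(length(labels) == n_ch)

  dir <- dirname(vhdr)
  eeg <- file.path(dir, get_field("DataFile"))
  sz <- file.info(eeg)$size
  con <- file(eeg, "rb")
  on.exit(close(con))
  if (fmt == "IEEE_FLOAT_32") {
    raw <- readBin(con, "numeric", n = sz / 4, size = 4L, endian = "little")
  } else if (fmt == "INT_16") {
    raw <- readBin(con, "integer", n = sz / 2, size = 2L, signed = TRUE,
                   endian = "little")
  } else stop("unsupported BinaryFormat: ", fmt, call. = FALSE)
  n_s <- length(raw) %/% n_ch
  data <- matrix(raw[seq_len(n_s * n_ch)], nrow = n_ch) * resol

  markers <- tibble::tibble(time = numeric(), type = character(),
                            label = character())
  vmrk <- file.path(dir, get_field("MarkerFile"))
  if (file.exists(vmrk)) {
    ml <- grep("^Mk[0-9]+=", readLines(vmrk, warn = FALSE), value = TRUE)
    parts <- strsplit(sub("^Mk[0-9]+=", "", ml), ",")
    keep <- vapply(parts, function(p) p[[1]] != "New Segment", TRUE)
    parts <- parts[keep]
    if (length(parts)) {
      markers <- tibble::tibble(
        time = (vapply(parts, function(p) as.numeric(p[[3]]), 0) - 1) / fs,
        type = vapply(parts, `[[`, "", 1L),
        label = vapply(parts, `[[`, "", 2L)
      )
    }
  }
  eeg_recording(data, fs, labels, markers,
                history = list(list(op = "read_brainvision", file = vhdr)))
}
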