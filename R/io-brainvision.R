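# Minimal BrainVision writer/reader: text .vhdr and .vmrk headers plus an
# IEEE float32 multiplexed binary .eeg, the common interchange layout.
# Covers round-tripping recordings produced by the simulator; it is not a
# general-purpose reader for every header variant in the wild.

#' Write a recording in BrainVision format
#'
#' Writes `<base>.vhdr`, `<base>.vmrk` and `<base>.eeg` (multiplexed IEEE
#' float32, unit microvolt). Events become markers of type Stimulus.
#'
#' @param rec a `recording`
#' @param base output path without extension
#' @return invisible base path
#' @export
write_brainvision <- function(rec, base) {
  nch <- nrow(rec$data)
  vhdr <- file.path(paste0(base, ".vhdr"))
  vmrk <- file.path(paste0(base, ".vmrk"))
  eeg <- file.path(paste0(base, ".eeg"))
  stem <- basename(base)
  hdr <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "",
    "[Common Infos]",
    paste0("DataFile=", stem, ".eeg"),
    paste0("MarkerFile=", stem, ".vmrk"),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", nch),
    paste0("SamplingInterval=", format(1e6 / rec$rate_hz, scientific = FALSE)),
    "",
    "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "",
    "[Channel Infos]",
    sprintf("Ch%d=%s,,1,µV", seq_len(nch), rownames(rec$data))
  )
  writeLines(hdr, vhdr, useBytes = TRUE)
  ev <- rec$events
  mrk <- c(
    "Brain Vision Data Exchange Marker File, Version 1.0",
    "",
    "[Common Infos]",
    paste0("DataFile=", stem, ".eeg"),
    "",
    "[Marker Infos]",
    "Mk1=New Segment,,1,1,0,0"
  )
  if (nrow(ev)) {
    mrk <- c(mrk, sprintf("Mk%d=Stimulus,%s,%d,1,0",
                          seq_len(nrow(ev)) + 1L, ev$label, ev$sample))
  }
  writeLines(mrk, vmrk, useBytes = TRUE)
  con <- file(eeg, "wb")
  on.exit(close(con))
  writeBin(as.numeric(rec$data), con, size = 4, endian = "little")
  invisible(base)
}

#' Read a BrainVision recording
#'
#' Reads the subset of the format written by [write_brainvision()]
#' (multiplexed IEEE float32).
#'
#' @param base path without extension (or path to the .vhdr)
#' @param montage montage to attach (default [default_montage()])
#' @return a `recording`
#' @export
read_brainvision <- function(base, montage = default_montage()) {
  base <- sub("\\.vhdr$", "", base)
  hdr <- readLines(paste0(base, ".vhdr"), encoding = "UTF-8")
  get_field <- function(name) {
    ln <- grep(paste0("^", name, "="), hdr, value = TRUE)[1]
    sub(paste0("^", name, "="), "", ln)
  }
  nch <- as.integer(get_field("NumberOfChannels"))
  rate <- 1e6 / as.numeric(get_field("SamplingInterval"))
  fmt <- get_field("BinaryFormat")
  if (!identical(fmt, "IEEE_FLOAT_32")) {
    stop("unsupported BinaryFormat: ", fmt)
  }
  ch_lines <- grep("^Ch[0-9]+=", hdr, value = TRUE)
  labels <- vapply(strsplit(sub("^Ch[0-9]+=", "", ch_lines), ","),
                   `[`, character(1), 1)
  eeg <- paste0(base, ".eeg")
  n_total <- file.info(eeg)$size / 4
  con <- file(eeg, "rb")
  on.exit(close(con))
  raw <- readBin(con, numeric(), n = n_total, size = 4, endian = "little")
  data <- matrix(raw, nrow = nch, dimnames = list(labels, NULL))
  mrk <- readLines(paste0(base, ".vmrk"), encoding = "UTF-8")
  ev_lines <- grep("^Mk[0-9]+=Stimulus,", mrk, value = TRUE)
  events <- if (length(ev_lines)) {
    parts <- strsplit(sub("^Mk[0-9]+=", "", ev_lines), ",")
    data.frame(label = vapply(parts, `[`, character(1), 2),
               sample = as.integer(vapply(parts, `[`, character(1), 3)),
               stringsAsFactors = FALSE)
  } else NULL
  new_recording(data, rate, montage, events)
}
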