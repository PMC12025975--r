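# Minimal EDF (European Data Format) writer/reader for generated recordings.
# Layout: 256-byte fixed header + 256 bytes per signal, then one data record
# holding the whole recording as 16-bit little-endian integers scaled between
# per-signal physical min/max. Covers the subset of EDF this package emits;
# not a general-purpose EDF implementation.

edf_pad <- function(x, width) {
  s <- substr(format(x, scientific = FALSE, trim = TRUE), 1, width)
  sprintf(paste0("%-", width, "s"), s)
}

#' Write a recording to an EDF file
#'
#' 16-bit EDF with physical dimension microvolts and a single data record
#' spanning the whole recording.
#'
#' @param rec A `raw_recording`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stop_if_not(inherits(rec, "raw_recording"), "rec must be a raw_recording")
  ns <- nrow(rec$data)
  n <- ncol(rec$data)
  phys_min <- apply(rec$data, 1, min)
  phys_max <- apply(rec$data, 1, max)
  # guard flat channels so the scale is invertible
  flat <- phys_max - phys_min < 1e-9
  phys_max[flat] <- phys_min[flat] + 1
  dig_min <- -32768
  dig_max <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8),                                     # version
    edf_pad("synthetic", 80),                            # patient id
    edf_pad("synthetic recording", 80),                  # recording id
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),      # start date/time
    edf_pad(256 + ns * 256, 8),                          # header bytes
    edf_pad("", 44),                                     # reserved
    edf_pad(1, 8),                                       # n data records
    edf_pad(format(n / rec$fs, nsmall = 0), 8),          # record duration (s)
    edf_pad(ns, 4)
  )
  writeChar(hdr, con, eos = NULL)
  fields <- list(
    list(rec$channel_names, 16),
    list(rep("synthetic EEG", ns), 80),
    list(rep("uV", ns), 8),
    list(sprintf("%.6g", phys_min), 8),
    list(sprintf("%.6g", phys_max), 8),
    list(rep(dig_min, ns), 8),
    list(rep(dig_max, ns), 8),
    list(rep("", ns), 80),
    list(rep(n, ns), 8),
    list(rep("", ns), 32)
  )
  for (f in fields) {
    writeChar(paste0(vapply(f[[1]], edf_pad, "", width = f[[2]]), collapse = ""),
              con, eos = NULL)
  }
  for (ch in seq_len(ns)) {
    scale <- (dig_max - dig_min) / (phys_max[ch] - phys_min[ch])
    dig <- as.integer(round((rec$data[ch, ] - phys_min[ch]) * scale + dig_min))
    writeBin(dig, con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file written by [write_edf()]
#'
#' @param path EDF file path.
#' @return A `raw_recording`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                                 # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  rdv <- function(w) vapply(seq_len(ns), function(i) rd(w), "")
  labels <- rdv(16); rdv(80); rdv(8)
  phys_min <- as.numeric(rdv(8)); phys_max <- as.numeric(rdv(8))
  dig_min <- as.numeric(rdv(8)); dig_max <- as.numeric(rdv(8))
  rdv(80)
  nsamp <- as.integer(rdv(8)); rdv(32)
  stop_if_not(length(unique(nsamp)) == 1, "per-signal sample counts must agree")
  data <- matrix(0, ns, nsamp[1] * n_rec)
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      dig <- readBin(con, "integer", n = nsamp[ch], size = 2,
                     signed = TRUE, endian = "little")
      phys <- phys_min[ch] +
        (dig - dig_min[ch]) * (phys_max[ch] - phys_min[ch]) / (dig_max[ch] - dig_min[ch])
      data[ch, ((r - 1) * nsamp[ch] + 1):(r * nsamp[ch])] <- phys
    }
  }
  fs <- nsamp[1] / (dur / 1)
  new_raw_recording(data, fs, labels)
}

#' Write a recording as flat float64 binary plus a JSON header sidecar
#'
#' The binary holds the data matrix in channel-major (row-by-row) order; the
#' sidecar (`<path>.json`) records shape, sampling rate, channel names, and
#' units.
#'
#' @param rec A `raw_recording`.
#' @param path Output binary path.
#' @return `path`, invisibly.
#' @export
write_flat_binary <- function(rec, path) {
  stop_if_not(inherits(rec, "raw_recording"), "rec must be a raw_recording")
  con <- file(path, "wb")
  writeBin(as.numeric(t(rec$data)), con, size = 8, endian = "little")
  close(con)
  hdr <- list(n_channels = nrow(rec$data), n_samples = ncol(rec$data),
              fs = rec$fs, channel_names = rec$channel_names,
              dtype = "float64le", order = "channel-major", units = "uV")
  jsonlite::write_json(hdr, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a flat binary recording written by [write_flat_binary()]
#' @param path Binary file path (sidecar `<path>.json` must exist).
#' @return A `raw_recording`.
#' @export
read_flat_binary <- function(path) {
  hdr <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  con <- file(path, "rb")
  x <- readBin(con, "numeric", n = hdr$n_channels * hdr$n_samples, size = 8,
               endian = "little")
  close(con)
  new_raw_recording(matrix(x, hdr$n_channels, hdr$n_samples, byrow = TRUE),
                    hdr$fs, hdr$channel_names)
}
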