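#' Minimal European Data Format (EDF) writer
#'
#' Writes a multichannel recording as a plain EDF file (16-bit samples, one
#' data record per second). This is a deliberately small implementation
#' covering exactly what the synthetic cohort needs: identical sampling rate
#' across channels, microvolt physical units, and a symmetric physical range.
#' The recording is zero-padded to a whole number of one-second records.
#'
#' @param rec An [eeg_recording()] object.
#' @param path Output file path.
#' @param phys_max Physical range bound in microvolts; samples are quantized
#'   onto 16 bits over `[-phys_max, phys_max]` (resolution `2 * phys_max /
#'   65535`, about 0.012 uV at the default 400 uV). Values outside the range
#'   are clipped.
#' @param patient,recording_id Free-text EDF header fields.
#' @return `path`, invisibly.
#' @seealso [read_edf()]
#' @export
write_edf <- function(rec, path, phys_max = 400, patient = "X", recording_id = "synthetic") {
  stopifnot(inherits(rec, "eeg_recording"))
  data <- rec$data
  nchan <- nrow(data)
  fs <- rec$rate_hz
  stopifnot(fs == as.integer(fs))
  n_rec <- ceiling(ncol(data) / fs)
  pad <- n_rec * fs - ncol(data)
  if (pad > 0) data <- cbind(data, matrix(0, nchan, pad))

  dig_max <- 32767L
  dig_min <- -32768L
  scale <- (dig_max - dig_min) / (2 * phys_max)
  dig <- round((pmin(pmax(data, -phys_max), phys_max) + phys_max) * scale) + dig_min
  storage.mode(dig) <- "integer"

  pad_field <- function(x, width) {
    x <- substr(format(x, scientific = FALSE, trim = TRUE), 1, width)
    formatC(x, width = width, flag = "-")
  }
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c(
    pad_field("0", 8),
    pad_field(patient, 80),
    pad_field(recording_id, 80),
    pad_field("01.01.00", 8),
    pad_field("00.00.00", 8),
    pad_field(256 * (1 + nchan), 8),
    pad_field("", 44),
    pad_field(n_rec, 8),
    pad_field(1, 8),
    pad_field(nchan, 4)
  )
  writeChar(paste(hdr, collapse = ""), con, eos = NULL)
  sig <- c(
    pad_field(rec$channels, 16),
    pad_field(rep("dry electrode", nchan), 80),
    pad_field(rep("uV", nchan), 8),
    pad_field(rep(-phys_max, nchan), 8),
    pad_field(rep(phys_max, nchan), 8),
    pad_field(rep(dig_min, nchan), 8),
    pad_field(rep(dig_max, nchan), 8),
    pad_field(rep("", nchan), 80),
    pad_field(rep(fs, nchan), 8),
    pad_field(rep("", nchan), 32)
  )
  writeChar(paste(sig, collapse = ""), con, eos = NULL)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1) * fs + 1):(r * fs)
    writeBin(as.integer(t(dig[, cols, drop = FALSE])), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Minimal EDF reader
#'
#' Reads files produced by [write_edf()] (and plain EDF files with a common
#' sampling rate across all signals). Digital values are mapped back to
#' physical units with the per-signal calibration stored in the header.
#'
#' @param path EDF file path.
#' @return An [eeg_recording()] with an empty events table.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                          # header length (implied by n_signals)
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  nchan <- as.integer(rd(4))
  rdv <- function(width) vapply(seq_len(nchan), function(i) rd(width), "")
  labels <- trimws(rdv(16))
  rdv(80)
  rdv(8)                         # physical dimension
  pmin_ <- as.numeric(rdv(8))
  pmax_ <- as.numeric(rdv(8))
  dmin <- as.numeric(rdv(8))
  dmax <- as.numeric(rdv(8))
  rdv(80)
  spr <- as.integer(rdv(8))
  rdv(32)
  stopifnot(length(unique(spr)) == 1)
  fs <- spr[1] / rec_dur
  raw <- readBin(con, integer(), n = n_rec * sum(spr), size = 2,
                 endian = "little", signed = TRUE)
  data <- matrix(0, nchan, n_rec * spr[1])
  per_rec <- sum(spr)
  for (r in seq_len(n_rec)) {
    block <- raw[((r - 1) * per_rec + 1):(r * per_rec)]
    for (ch in seq_len(nchan)) {
      data[ch, ((r - 1) * spr[1] + 1):(r * spr[1])] <-
        block[((ch - 1) * spr[1] + 1):(ch * spr[1])]
    }
  }
  gain <- (pmax_ - pmin_) / (dmax - dmin)
  data <- sweep(sweep(data, 1, dmin), 1, gain, `*`) + pmin_
  eeg_recording(channels = labels, rate_hz = fs, data = data,
                events = empty_events())
}
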