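# Minimal European Data Format (EDF) reader/writer.
#
# Supports the subset the package needs: uninterrupted multichannel recordings
# with one common sampling rate, 1-s data records, 16-bit signed little-endian
# samples. Signals are quantized to the per-channel physical range, so a
# write/read round trip is exact only up to one quantization step
# (range / 65534); see read_edf() for the step size.

edf_pad <- function(x, width) {
  x <- as.character(x)
  x <- substr(x, 1L, width)
  formatC(x, width = width, flag = "-")
}

edf_num <- function(x, width) {
  s <- vapply(x, function(v) {
    for (d in 7:1) {
      out <- formatC(v, format = "g", digits = d, width = 1)
      if (nchar(out) <= width) return(out)
    }
    out
  }, character(1))
  edf_pad(s, width)
}

# magnitude string that still fits the 8-char field with a leading minus
edf_sym_range <- function(v, width = 8) {
  for (d in 7:1) {
    s <- formatC(v, format = "g", digits = d, width = 1)
    if (nchar(s) <= width - 1L) return(s)
  }
  s
}

#' Write a multichannel recording to an EDF file
#'
#' @param signals Numeric matrix `[n_samples x n_channels]` in microvolts.
#' @param fs Sampling rate in Hz (positive integer; one data record per second).
#' @param channels Character vector of channel labels (one per column).
#' @param path Output file path.
#' @param recording_id Free-text recording identification field.
#' @return `path`, invisibly.
#' @export
write_edf <- function(signals, fs, channels, path, recording_id = "ctleeg") {
  signals <- as.matrix(signals)
  nch <- ncol(signals)
  stopifnot(length(channels) == nch, fs == as.integer(fs), fs > 0)
  if (nrow(signals) %% fs != 0) {
    abort("signal length must be a whole number of seconds (1-s data records)")
  }
  n_rec <- nrow(signals) %/% fs

  # symmetric physical range per channel, padded 5% so extremes stay in range
  pmax_ <- apply(abs(signals), 2L, max)
  pmax_ <- ifelse(pmax_ <= 0, 1, pmax_ * 1.05)
  pm_str <- vapply(pmax_, edf_sym_range, character(1))
  dig_min <- -32767L; dig_max <- 32767L

  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  hdr_bytes <- 256L + 256L * nch
  writeChar(paste0(
    edf_pad("0", 8),
    edf_pad("X X X X", 80),
    edf_pad(recording_id, 80),
    edf_pad("01.01.26", 8),
    edf_pad("00.00.00", 8),
    edf_pad(hdr_bytes, 8),
    edf_pad("", 44),
    edf_pad(n_rec, 8),
    edf_pad(1, 8),
    edf_pad(nch, 4)
  ), con, eos = NULL)
  writeChar(paste0(
    paste(edf_pad(channels, 16), collapse = ""),
    paste(edf_pad(rep("AgAgCl electrode", nch), 80), collapse = ""),
    paste(edf_pad(rep("uV", nch), 8), collapse = ""),
    paste(edf_pad(paste0("-", pm_str), 8), collapse = ""),
    paste(edf_pad(pm_str, 8), collapse = ""),
    paste(edf_num(rep(dig_min, nch), 8), collapse = ""),
    paste(edf_num(rep(dig_max, nch), 8), collapse = ""),
    paste(edf_pad(rep("", nch), 80), collapse = ""),
    paste(edf_pad(rep(fs, nch), 8), collapse = ""),
    paste(edf_pad(rep("", nch), 32), collapse = "")
  ), con, eos = NULL)

  # header stores the rounded physical max; quantize against the same value
  pmax_hdr <- as.numeric(pm_str)
  scale <- (2 * pmax_hdr) / (dig_max - dig_min)
  for (r in seq_len(n_rec)) {
    rows <- ((r - 1L) * fs + 1L):(r * fs)
    dig <- round(sweep(signals[rows, , drop = FALSE], 2L, scale, "/"))
    dig <- pmin(pmax(dig, dig_min), dig_max)
    writeBin(as.integer(dig), con, size = 2L, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file written with a single common sampling rate
#'
#' @param path EDF file path.
#' @return A list with `signals` (numeric matrix `[n_samples x n_channels]`,
#'   microvolts), `fs` (Hz), `channels` (labels), and `quant_step` (the
#'   per-channel quantization step; round-trip error is at most half of it
#'   plus header rounding of the physical range).
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  hdr <- readChar(con, 256L, useBytes = TRUE)
  fld <- function(s, from, len) trimws(substr(s, from, from + len - 1L))
  n_rec <- as.integer(fld(hdr, 237, 8))
  rec_dur <- as.numeric(fld(hdr, 245, 8))
  nch <- as.integer(fld(hdr, 253, 4))
  sh <- readChar(con, 256L * nch, useBytes = TRUE)
  take <- function(offset, width) {
    vapply(seq_len(nch), function(i) {
      trimws(substr(sh, offset + (i - 1L) * width + 1L, offset + i * width))
    }, character(1))
  }
  channels <- take(0L, 16L)
  phys_min <- as.numeric(take(nch * (16L + 80L + 8L), 8L))
  phys_max <- as.numeric(take(nch * (16L + 80L + 8L + 8L), 8L))
  dig_min <- as.numeric(take(nch * (16L + 80L + 8L + 8L + 8L), 8L))
  dig_max <- as.numeric(take(nch * (16L + 80L + 8L + 8L + 8L + 8L), 8L))
  spr <- as.integer(take(nch * (16L + 80L + 8L * 5L + 80L), 8L))
  if (length(unique(spr)) != 1L) {
    abort("mixed per-channel sampling rates are not supported")
  }
  fs <- spr[1L] / rec_dur
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  signals <- matrix(0, nrow = n_rec * spr[1L], ncol = nch)
  for (r in seq_len(n_rec)) {
    dig <- readBin(con, "integer", n = spr[1L] * nch, size = 2L,
                   signed = TRUE, endian = "little")
    dig <- matrix(dig, nrow = spr[1L], ncol = nch)
    rows <- ((r - 1L) * spr[1L] + 1L):(r * spr[1L])
    signals[rows, ] <- sweep(sweep(dig, 2L, dig_min, "-"), 2L, gain, "*") +
      matrix(phys_min, nrow = spr[1L], ncol = nch, byrow = TRUE)
  }
  colnames(signals) <- channels
  list(signals = signals, fs = fs, channels = channels,
       quant_step = gain)
}
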