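# Minimal EDF (European Data Format) reader/writer.
#
# EDF stores 16-bit signed samples with per-signal physical/digital
# calibration, in fixed-duration data records. Round-tripping a signal
# through EDF therefore quantizes amplitudes: the error is at most half
# a digital step, i.e. (physical_max - physical_min) / 2 / 65535.
# Physical dimensions "uV" and "mV" are honored on read and converted to
# the package-internal microvolt unit.

edf_pad <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = width, flag = "-")
}

#' Write a channels-x-samples matrix to an EDF file
#'
#' One-second data records are used, so the sample count must be a
#' multiple of the sampling rate. Amplitudes are calibrated per channel
#' to a symmetric physical range covering the data and quantized to
#' 16 bits (quantization error at most `range/65535/2` microvolts).
#'
#' @param x Numeric matrix, channels x samples, in microvolts.
#' @param path Output file path.
#' @param sampling_rate Sampling rate in Hz (integer).
#' @param channel_names Character vector, one per row of `x`.
#' @return `path`, invisibly.
#' @export
write_edf <- function(x, path, sampling_rate, channel_names) {
  x <- as.matrix(x)
  ns <- nrow(x)
  n <- ncol(x)
  fs <- as.integer(sampling_rate)
  if (n %% fs != 0) {
    abort("Sample count must be a whole number of 1-s records.",
          class = "emoselect_edf_error")
  }
  n_rec <- n %/% fs
  phys_max <- pmax(apply(abs(x), 1, max), 1e-6)
  phys_max <- signif(phys_max * 1.0001, 6)
  dig_max <- 32767L
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8), edf_pad("synthetic", 80), edf_pad("emoselect", 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256 * (1 + ns), 8), edf_pad("", 44),
    edf_pad(n_rec, 8), edf_pad(1, 8), edf_pad(ns, 4)
  )
  sig_hdr <- paste0(
    paste(edf_pad(channel_names, 16), collapse = ""),
    paste(rep(edf_pad("", 80), ns), collapse = ""),
    paste(rep(edf_pad("uV", 8), ns), collapse = ""),
    paste(edf_pad(-phys_max, 8), collapse = ""),
    paste(edf_pad(phys_max, 8), collapse = ""),
    paste(rep(edf_pad(-32768L, 8), ns), collapse = ""),
    paste(rep(edf_pad(dig_max, 8), ns), collapse = ""),
    paste(rep(edf_pad("", 80), ns), collapse = ""),
    paste(rep(edf_pad(fs, 8), ns), collapse = ""),
    paste(rep(edf_pad("", 32), ns), collapse = "")
  )
  writeChar(paste0(hdr, sig_hdr), con, eos = NULL)
  scale <- (dig_max - (-32768)) / (2 * phys_max)
  for (r in seq_len(n_rec)) {
    span <- ((r - 1) * fs + 1):(r * fs)
    for (ch in seq_len(ns)) {
      dig <- round((x[ch, span] + phys_max[ch]) * scale[ch]) - 32768
      dig <- pmin(pmax(dig, -32768), 32767)
      writeBin(as.integer(dig), con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file
#'
#' @param path EDF file path.
#' @return List with `data` (channels x samples matrix, microvolts),
#'   `channel_names`, `sampling_rate`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  version <- rd(8)
  if (version != "0") {
    abort("Not an EDF file (bad version field).",
          class = "emoselect_edf_error")
  }
  rd(80); rd(80); rd(8); rd(8)
  n_hdr <- as.integer(rd(8))
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || is.na(n_rec) || n_hdr != 256 * (1 + ns)) {
    abort("Corrupt EDF header.", class = "emoselect_edf_error")
  }
  fld <- function(w) vapply(seq_len(ns), function(i) rd(w), "")
  labels <- fld(16); fld(80)
  dims <- fld(8)
  pmin_ <- as.numeric(fld(8)); pmax_ <- as.numeric(fld(8))
  dmin <- as.numeric(fld(8)); dmax <- as.numeric(fld(8))
  fld(80)
  spr <- as.integer(fld(8))
  fld(32)
  if (length(unique(spr)) != 1) {
    abort("Signals with differing sampling rates are not supported.",
          class = "emoselect_edf_error")
  }
  unit_scale <- ifelse(tolower(dims) == "mv", 1000,
                       ifelse(tolower(dims) %in% c("uv", "µv", ""),
                              1, NA))
  if (anyNA(unit_scale)) {
    abort(paste0("Unsupported physical dimension: ",
                 paste(unique(dims), collapse = ", ")),
          class = "emoselect_edf_error")
  }
  n <- n_rec * spr[1]
  x <- matrix(0, ns, n)
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      dig <- readBin(con, integer(), n = spr[1], size = 2,
                     endian = "little", signed = TRUE)
      phys <- pmin_[ch] + (dig - dmin[ch]) *
        (pmax_[ch] - pmin_[ch]) / (dmax[ch] - dmin[ch])
      x[ch, ((r - 1) * spr[1] + 1):(r * spr[1])] <- phys * unit_scale[ch]
    }
  }
  list(data = x, channel_names = labels,
       sampling_rate = spr[1] / rec_dur)
}
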