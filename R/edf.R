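# Minimal reader/writer for standard 16-bit EDF (European Data Format).
# One data record per second; amplitudes are linearly mapped between the
# physical and digital ranges declared in the header.

edf_pad <- function(x, width) formatC(as.character(x), width = width, flag = "-")

#' Write a recording as a 16-bit EDF file
#'
#' All channels share the recording's sampling rate; data are quantized to
#' the int16 digital range over each channel's physical min/max, so values
#' round-trip to within one quantization step.
#'
#' @param rec an [eeg_recording()].
#' @param path output path.
#' @export
write_edf <- function(rec, path) {
  ns <- length(rec$channels)
  record_dur <- 1                      # seconds per data record
  spr <- round(rec$fs * record_dur)    # samples per record per channel
  n_rec <- floor(nrow(rec$data) / spr)
  if (n_rec < 1) stop("recording shorter than one EDF data record (1 s)")
  phys_min <- apply(rec$data, 2, min)
  phys_max <- apply(rec$data, 2, max)
  flat <- phys_max - phys_min < 1e-12
  phys_max[flat] <- phys_min[flat] + 1   # avoid zero physical span
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8),
    edf_pad(ifelse(is.na(rec$subject_id), "X", rec$subject_id), 80),
    edf_pad("recording", 80),
    edf_pad("01.01.26", 8), edf_pad("00.00.00", 8),
    edf_pad(256 * (1 + ns), 8),
    edf_pad("", 44),
    edf_pad(n_rec, 8),
    edf_pad(format(record_dur), 8),
    edf_pad(ns, 4)
  )
  per_sig <- paste0(
    paste(vapply(rec$channels, edf_pad, "", width = 16), collapse = ""),
    paste(rep(edf_pad("EEG", 80), ns), collapse = ""),
    paste(rep(edf_pad("uV", 8), ns), collapse = ""),
    paste(vapply(sprintf("%.3f", phys_min), edf_pad, "", width = 8), collapse = ""),
    paste(vapply(sprintf("%.3f", phys_max), edf_pad, "", width = 8), collapse = ""),
    paste(rep(edf_pad(-32768, 8), ns), collapse = ""),
    paste(rep(edf_pad(32767, 8), ns), collapse = ""),
    paste(rep(edf_pad("", 80), ns), collapse = ""),
    paste(rep(edf_pad(spr, 8), ns), collapse = "")
  )
  writeChar(paste0(hdr, per_sig), con, eos = NULL)
  # re-read declared physical bounds at header precision so the scaling the
  # reader applies matches the one used to digitize
  pmin_d <- as.numeric(sprintf("%.3f", phys_min))
  pmax_d <- as.numeric(sprintf("%.3f", phys_max))
  scale <- (pmax_d - pmin_d) / (32767 - (-32768))
  for (r in seq_len(n_rec)) {
    rows <- ((r - 1) * spr + 1):(r * spr)
    for (ch in seq_len(ns)) {
      dig <- round((rec$data[rows, ch] - pmin_d[ch]) / scale[ch]) - 32768
      dig <- pmin(pmax(dig, -32768), 32767)
      writeBin(as.integer(dig), con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

#' Read a 16-bit EDF file
#'
#' @param path EDF path.
#' @return an [eeg_recording()]; requires all channels to share one
#'   sampling rate.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) trimws(readChar(con, n, useBytes = TRUE))
  rd(8)                       # version
  subject <- rd(80)
  rd(80); rd(8); rd(8); rd(8); rd(44)
  n_rec <- as.integer(rd(8))
  record_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)   # transducer
  for (i in seq_len(ns)) rd(8)    # physical dimension
  phys_min <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  phys_max <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dig_min <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dig_max <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(80)   # prefiltering
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  if (length(unique(spr)) != 1L)
    stop("mixed per-channel sampling rates are not supported")
  fs <- spr[1L] / record_dur
  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  out <- matrix(NA_real_, nrow = n_rec * spr[1L], ncol = ns,
                dimnames = list(NULL, labels))
  for (r in seq_len(n_rec)) {
    rows <- ((r - 1) * spr[1L] + 1):(r * spr[1L])
    for (ch in seq_len(ns)) {
      dig <- readBin(con, integer(), n = spr[ch], size = 2L,
                     endian = "little", signed = TRUE)
      out[rows, ch] <- phys_min[ch] + (dig - dig_min[ch]) * scale[ch]
    }
  }
  eeg_recording(out, fs = fs,
                subject_id = if (identical(subject, "X")) NA_character_ else subject)
}
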