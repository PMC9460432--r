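REQUIRED_CHANNELS <- c("FP1", "FP2", "FZ", "O2")

#' Multichannel EEG recording
#'
#' Constructs an `eeg_recording`: a set of equal-length amplitude series
#' (microvolts), one per channel, with a common sampling rate.
#'
#' @param data numeric matrix (samples x channels) or data frame; column
#'   names are the channel names.
#' @param fs sampling rate in Hz (the recordings this pipeline targets use
#'   500 Hz).
#' @param subject_id optional subject identifier.
#' @return an object of class `eeg_recording` with elements `data`
#'   (matrix), `fs`, `channels`, `subject_id`.
#' @examples
#' rec <- eeg_recording(matrix(rnorm(2000), ncol = 4,
#'                             dimnames = list(NULL, c("FP1","FP2","FZ","O2"))),
#'                      fs = 500)
#' @export
eeg_recording <- function(data, fs, subject_id = NA_character_) {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("recording data must be numeric")
  if (is.null(colnames(data))) stop("recording data must have channel names")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a single positive number")
  structure(
    list(data = data, fs = as.numeric(fs),
         channels = colnames(data), subject_id = subject_id),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> subject=%s  %d channels [%s]  %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, length(x$channels),
              paste(x$channels, collapse = ","),
              nrow(x$data), x$fs, nrow(x$data) / x$fs))
  invisible(x)
}

#' Recording duration in seconds
#' @param rec an `eeg_recording`.
#' @export
recording_duration <- function(rec) nrow(rec$data) / rec$fs

check_required_channels <- function(rec, required = REQUIRED_CHANNELS) {
  missing <- setdiff(required, rec$channels)
  if (length(missing))
    stop("recording is missing required channel(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  invisible(rec)
}

#' Read an EEG recording from disk
#'
#' Reads either the package's CSV dialect (one row per sample, channels as
#' columns, sampling rate carried in a `# fs=<Hz>` comment line) or a
#' standard 16-bit EDF file.
#'
#' @param path file path.
#' @param format `"csv"` or `"edf"`; default guesses from the extension.
#' @param require_channels channels that must be present (set `NULL` to
#'   skip the check). Defaults to FP1, FP2, FZ, O2 — the montage the
#'   pipeline consumes.
#' @return an [eeg_recording()].
#' @export
read_recording <- function(path, format = c("auto", "csv", "edf"),
                           require_channels = REQUIRED_CHANNELS) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  }
  rec <- switch(format,
    csv = read_recording_csv(path),
    edf = read_edf(path)
  )
  if (!is.null(require_channels)) check_required_channels(rec, require_channels)
  rec
}

read_recording_csv <- function(path) {
  head_lines <- readLines(path, n = 20L)
  fs_line <- grep("^#\\s*fs\\s*=", head_lines, value = TRUE)
  if (!length(fs_line))
    stop("CSV recording lacks a '# fs=<Hz>' metadata line: ", path)
  fs <- suppressWarnings(as.numeric(sub("^#\\s*fs\\s*=\\s*", "", fs_line[1L])))
  if (is.na(fs) || fs <= 0) stop("unreadable sampling rate in ", path)
  subj_line <- grep("^#\\s*subject\\s*=", head_lines, value = TRUE)
  subject <- if (length(subj_line))
    sub("^#\\s*subject\\s*=\\s*", "", subj_line[1L]) else NA_character_
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  eeg_recording(as.matrix(df), fs = fs, subject_id = subject)
}

#' Write a recording to the package's CSV dialect
#'
#' @param rec an [eeg_recording()].
#' @param path output path.
#' @export
write_recording_csv <- function(rec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%g", rec$fs), con)
  if (!is.na(rec$subject_id))
    writeLines(sprintf("# subject=%s", rec$subject_id), con)
  utils::write.table(rec$data, con, sep = ",", row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  invisible(path)
}

#' Read a reaction-time log
#'
#' CSV with columns `subject`, `order_time_s`, `rt_s`: one row per rudder
#' order, `order_time_s` the session time at which the order was issued and
#' `rt_s` the operator's reaction time in seconds.
#'
#' @param path CSV path.
#' @return data frame with those three columns.
#' @export
read_rt_log <- function(path) {
  if (!file.exists(path)) stop("RT log not found: ", path)
  df <- utils::read.csv(path)
  need <- c("subject", "order_time_s", "rt_s")
  if (!all(need %in% names(df)))
    stop("RT log must have columns: ", paste(need, collapse = ", "))
  if (any(df$rt_s <= 0)) stop("reaction times must be positive")
  df
}

#' @rdname read_rt_log
#' @param rt_log data frame as returned by [read_rt_log()].
#' @export
write_rt_log <- function(rt_log, path) {
  utils::write.csv(rt_log[, c("subject", "order_time_s", "rt_s")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
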