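# Eyelid closure degree estimated from occipital (O2) alpha power.
#
# Per 1.8 s epoch, a Hamming taper is applied and band powers are read off
# the squared FFT magnitude; the alpha share of the theta+alpha+beta power
# feeds a published linear model ECD = intercept + slope * Per(alpha).

#' Linear eyelid-closure model
#'
#' Coefficients of the linear map from occipital alpha-power percentage to
#' eyelid closure degree. The defaults are the published fit
#' (slope 1.56, intercept -31.37, R^2 = 0.904 on eye-tracking ground
#' truth); this package does not refit the model.
#'
#' @param slope dimensionless slope (> 0).
#' @param intercept intercept in ECD units.
#' @export
ecd_model <- function(slope = 1.56, intercept = -31.37) {
  if (slope <= 0) stop("slope must be positive")
  structure(list(slope = slope, intercept = intercept), class = "ecd_model")
}

#' FFT band power of an epoch
#'
#' Applies a Hamming taper over the whole epoch, computes the FFT, and sums
#' squared magnitudes over bins whose frequency f satisfies
#' `low <= f < high` (half-open, so adjacent rhythm bands never
#' double-count a bin: 8 Hz belongs to alpha, 13 Hz to beta).
#'
#' @param epoch an [eeg_epoch()] or numeric vector.
#' @param band one of `"theta"`, `"alpha"`, `"beta"`, or a numeric
#'   `c(low, high)` in Hz.
#' @param fs sampling rate, required when `epoch` is a bare vector.
#' @return nonnegative scalar power (arbitrary FFT scale).
#' @export
band_power_fft <- function(epoch, band, fs = NULL) {
  x <- epoch_samples(epoch)
  if (inherits(epoch, "eeg_epoch")) fs <- epoch$fs
  if (is.null(fs)) stop("fs required for bare numeric input")
  if (length(x) < 2L) stop("epoch must contain at least 2 samples")
  if (is.character(band)) {
    if (!band %in% names(EEG_BANDS)) stop("unknown band: ", band)
    band <- EEG_BANDS[[band]]
  }
  n <- length(x)
  w <- 0.54 - 0.46 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))  # Hamming
  spec <- Mod(stats::fft(x * w))^2
  freqs <- (seq_len(n) - 1) * fs / n
  # keep only the one-sided spectrum; bands live well below Nyquist
  keep <- freqs >= band[1] & freqs < band[2] & freqs <= fs / 2
  sum(spec[keep])
}

#' Alpha power percentage Per(alpha)
#'
#' 100 x alpha power / (theta + alpha + beta power) of one epoch, each
#' power from [band_power_fft()].
#'
#' @inheritParams band_power_fft
#' @return percentage in \[0, 100\].
#' @export
alpha_power_percentage <- function(epoch, fs = NULL) {
  p <- vapply(names(EEG_BANDS), function(b) band_power_fft(epoch, b, fs = fs),
              numeric(1))
  tot <- sum(p)
  if (tot <= 0) stop("degenerate epoch: zero power in theta+alpha+beta")
  100 * p[["alpha"]] / tot
}

#' Eyelid closure degree from alpha power percentage
#'
#' Evaluates the linear model `intercept + slope * per_alpha`. Raw values
#' can be negative (the model's offset error); they are only removed by
#' [normalize_eecd()].
#'
#' @param per_alpha alpha power percentage in \[0, 100\] (vectorized).
#' @param model an [ecd_model()].
#' @return eECD estimate(s), percent-like scale.
#' @export
eecd <- function(per_alpha, model = ecd_model()) {
  stopifnot(all(per_alpha >= 0 & per_alpha <= 100))
  model$intercept + model$slope * per_alpha
}

#' Per-epoch eECD series for one recording section
#'
#' Convenience wrapper: epochs the O2 channel and maps each epoch through
#' Per(alpha) and the linear closure model.
#'
#' @param rec a band-passed [eeg_recording()] containing O2.
#' @param model an [ecd_model()].
#' @param window_s epoch length in seconds.
#' @return numeric vector of raw eECD values, one per epoch.
#' @export
eecd_series <- function(rec, model = ecd_model(), window_s = 1.8) {
  epochs <- segment_epochs(rec, "O2", window_s = window_s)
  vapply(epochs, function(ep) eecd(alpha_power_percentage(ep), model),
         numeric(1))
}

#' Min-max normalize an eECD series to \[0, 1\]
#'
#' Scaled over the subject's full series (the linear model's offset errors
#' are subject-specific, so normalization is per subject per session). A
#' constant series maps to all 0.5. Idempotent and order-preserving.
#'
#' @param values numeric eECD series.
#' @return numeric vector in \[0, 1\].
#' @export
normalize_eecd <- function(values) {
  if (!length(values)) stop("empty eECD series")
  rng <- range(values)
  if (diff(rng) < .Machine$double.eps * max(1, abs(rng[2])))
    return(rep(0.5, length(values)))
  (values - rng[1]) / diff(rng)
}

#' PERCLOS: percentage of time with ECD at or above a threshold
#'
#' The classic video-based drowsiness statistic, retained as an auxiliary
#' op (this pipeline feeds ECD values to the classifier directly). The
#' series is trimmed to whole windows and the overall exceedance fraction
#' is returned.
#'
#' @param values ECD series, one value per epoch.
#' @param epoch_s seconds covered by each value (default 1.8).
#' @param threshold ECD threshold (default 80).
#' @param window window length in seconds (default 60).
#' @return percentage in \[0, 100\].
#' @export
perclos <- function(values, epoch_s = 1.8, threshold = 80, window = 60) {
  per_win <- floor(window / epoch_s)
  n_win <- floor(length(values) / per_win)
  if (n_win < 1) stop("series shorter than one ", window, " s window")
  use <- values[seq_len(n_win * per_win)]
  100 * mean(use >= threshold)
}
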