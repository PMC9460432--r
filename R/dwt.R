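# Periodized discrete wavelet transform (Mallat cascade).
#
# Boundary handling is periodization: the signal is treated as circular
# (odd lengths are first extended by duplicating the last sample). For the
# orthonormal Daubechies filters this makes the transform an orthogonal
# change of basis whenever every level has even length, so subband energies
# add up to the input energy exactly and reconstruction is exact to
# rounding.

# Daubechies-5 decomposition low-pass taps (orthonormal, sum = sqrt(2)).
DB5_DEC_LO <- c(
   0.003335725285473771, -0.012580751999081999, -0.006241490212798274,
   0.077571493840045740, -0.032244869584638375, -0.242294887066382030,
   0.138428145901320740,  0.724308528437772900,  0.603829269797189600,
   0.160102397974192930)

wavelet_filters <- function(wavelet = "db5") {
  if (!identical(wavelet, "db5"))
    stop("only the db5 wavelet is provided")
  lo <- DB5_DEC_LO
  L <- length(lo)
  # quadrature mirror: hi[m] = (-1)^(m+1) * lo[L-1-m] (0-based)
  hi <- rev(lo) * (-1)^seq_len(L)
  # reconstruction filters are the time-reversed decomposition filters
  list(dec_lo = lo, dec_hi = hi, rec_lo = rev(lo), rec_hi = rev(hi), L = L)
}

# One analysis level, periodized: out[i] = sum_m f[m] x[(2i + L/2 - m) mod n]
dwt_step <- function(x, f) {
  n <- length(x)
  if (n %% 2L) { x <- c(x, x[n]); n <- n + 1L }
  L <- length(f)
  half <- L %/% 2L
  idx0 <- 2L * (seq_len(n %/% 2L) - 1L) + half   # 0-based anchor per output
  out <- numeric(n %/% 2L)
  for (m in seq_len(L)) {
    out <- out + f[m] * x[((idx0 - (m - 1L)) %% n) + 1L]
  }
  out
}

# One synthesis level: scatter x[(2i + m - (L/2 - 1)) mod n] += c[i] f[m],
# then truncate to the stored original length.
idwt_step <- function(cA, cD, flt, out_len) {
  n <- 2L * length(cA)
  L <- flt$L
  half <- L %/% 2L
  rec <- numeric(n)
  pos0 <- 2L * (seq_along(cA) - 1L) - (half - 1L)  # 0-based
  for (m in seq_len(L)) {
    tgt <- ((pos0 + (m - 1L)) %% n) + 1L   # distinct for fixed m
    rec[tgt] <- rec[tgt] + cA * flt$rec_lo[m] + cD * flt$rec_hi[m]
  }
  rec[seq_len(out_len)]
}

#' Five-level db5 wavelet decomposition of an epoch
#'
#' Runs the Mallat cascade: at each level the current approximation passes
#' through the high-pass and low-pass analysis filters with downsampling
#' by 2, producing details D1..D5 and the final approximation A5 (six
#' sub-signals).
#'
#' @param epoch an [eeg_epoch()] or numeric vector.
#' @param wavelet wavelet name (only `"db5"`).
#' @param levels decomposition depth (default 5).
#' @return object of class `wavelet_decomposition`: list with `details`
#'   (list D1..D5), `approximation` (A5), `wavelet`, `levels`, `fs`, and
#'   `input_lengths` (per-level lengths needed for exact reconstruction).
#' @export
dwt_decompose <- function(epoch, wavelet = "db5", levels = 5) {
  x <- epoch_samples(epoch)
  fs <- if (inherits(epoch, "eeg_epoch")) epoch$fs else NA_real_
  if (length(x) < 2^levels)
    stop("epoch too short for a ", levels, "-level decomposition")
  flt <- wavelet_filters(wavelet)
  details <- vector("list", levels)
  input_lengths <- integer(levels)
  approx <- x
  for (j in seq_len(levels)) {
    input_lengths[j] <- length(approx)
    details[[j]] <- dwt_step(approx, flt$dec_hi)
    approx <- dwt_step(approx, flt$dec_lo)
  }
  names(details) <- paste0("D", seq_len(levels))
  structure(list(details = details, approximation = approx,
                 wavelet = wavelet, levels = levels, fs = fs,
                 input_lengths = input_lengths),
            class = "wavelet_decomposition")
}

#' Reconstruct a signal from its wavelet decomposition
#'
#' Inverts the periodized Mallat cascade; exact to numerical rounding.
#'
#' @param decomp a `wavelet_decomposition` from [dwt_decompose()].
#' @return numeric vector of the original length.
#' @export
dwt_reconstruct <- function(decomp) {
  flt <- wavelet_filters(decomp$wavelet)
  approx <- decomp$approximation
  for (j in rev(seq_len(decomp$levels))) {
    cD <- decomp$details[[j]]
    # if the analysis step padded an odd input, coefficients describe the
    # padded (even) signal; rebuild at even length then truncate
    approx <- idwt_step(approx, cD, flt, decomp$input_lengths[j])
  }
  approx
}

#' Nominal dyadic subband frequency ranges
#'
#' For a sampling rate `fs`, detail Dj spans (fs/2^(j+1), fs/2^j) and the
#' final approximation spans (0, fs/2^(levels+1)); at fs = 500 and 5
#' levels, D5 covers 7.8125-15.625 Hz (the alpha-carrying subband) and A5
#' 0-7.8125 Hz.
#'
#' @param fs sampling rate in Hz.
#' @param levels decomposition depth.
#' @return named list of `c(low, high)` pairs for D1..D5 then A5.
#' @export
subband_ranges <- function(fs, levels = 5) {
  stopifnot(fs > 0)
  out <- lapply(seq_len(levels), function(j) c(fs / 2^(j + 1), fs / 2^j))
  names(out) <- paste0("D", seq_len(levels))
  out[[paste0("A", levels)]] <- c(0, fs / 2^(levels + 1))
  out
}
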