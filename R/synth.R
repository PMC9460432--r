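# Seeded synthetic cohort generator.
#
# Emulates the statistical structure the pipeline assumes: each subject
# contributes three 180 s state sections (alert, middle, fatigue) of
# 4-channel EEG in which the occipital (O2) alpha share of the
# theta+alpha+beta power rises with fatigue, plus a 30-order reaction-time
# log whose values are drawn from the three published, non-overlapping RT
# regimes. Rhythms are band-limited Gaussian noise with controlled band
# power; frontal channels carry a deliberately weaker copy of the state
# effect so that fusing the occipital closure estimate with frontal EEG
# features genuinely adds information. This is not physiological EEG: no
# 1/f background, eye-blink artifacts or electrode noise are simulated.

#' Synthetic cohort configuration
#'
#' Defaults are the study conditions the pipeline targets: 21 subjects,
#' 500 Hz, 180 s sections, RT regimes 0.8-1.4 / 1.4-1.9 / 1.9-2.5 s, and
#' occipital alpha fractions rising 25/40/55 percent across states.
#'
#' @param n_subjects cohort size.
#' @param fs sampling rate (Hz).
#' @param section_s section length per state (seconds).
#' @param state_alpha_fraction target O2 Per(alpha)/100 per state,
#'   strictly increasing.
#' @param rt_ranges list of `c(lo, hi)` reaction-time ranges (seconds)
#'   per state, non-overlapping and increasing.
#' @param n_orders_per_state rudder orders (hence RT records) per state
#'   section; 10 gives the 21 x 30 = 630 RT points of the full design.
#' @param rhythm_rms total theta+alpha+beta RMS amplitude (microvolts).
#' @param frontal_effect fraction (0..1) of the occipital alpha-state
#'   effect expressed at FP1/FP2/FZ.
#' @param state_theta_share per-state share of the non-alpha rhythm power
#'   given to theta (drowsiness shifts the theta/beta balance toward
#'   theta).
#' @param state_amp_gain per-state multiplier on the overall rhythm
#'   amplitude at the frontal channels (EEG amplitude grows modestly with
#'   drowsiness).
#' @param noise_sd broadband white-noise amplitude (microvolts RMS).
#' @param seed master seed.
#' @export
synth_config <- function(n_subjects = 21, fs = 500, section_s = 180,
                         state_alpha_fraction = c(alert = 0.25, middle = 0.40,
                                                  fatigue = 0.55),
                         rt_ranges = list(alert = c(0.8, 1.4),
                                          middle = c(1.4, 1.9),
                                          fatigue = c(1.9, 2.5)),
                         n_orders_per_state = 10, rhythm_rms = 10,
                         frontal_effect = 0.8,
                         state_theta_share = c(0.55, 0.65, 0.75),
                         state_amp_gain = c(1, 1.12, 1.25),
                         noise_sd = 1, seed = 1) {
  if (any(diff(state_alpha_fraction) <= 0))
    stop("state_alpha_fraction must increase alert -> fatigue")
  edges <- unlist(rt_ranges)
  if (any(diff(edges) < 0)) stop("rt_ranges must be non-overlapping and increasing")
  structure(list(n_subjects = n_subjects, fs = fs, section_s = section_s,
                 state_alpha_fraction = state_alpha_fraction,
                 rt_ranges = rt_ranges,
                 n_orders_per_state = n_orders_per_state,
                 rhythm_rms = rhythm_rms, frontal_effect = frontal_effect,
                 state_theta_share = state_theta_share,
                 state_amp_gain = state_amp_gain,
                 noise_sd = noise_sd, seed = seed),
            class = "synth_config")
}

# Gaussian noise confined to [low, high) Hz with a prescribed RMS.
bandlimited_noise <- function(n, fs, low, high, rms) {
  x <- stats::rnorm(n)
  spec <- stats::fft(x)
  freqs <- (seq_len(n) - 1) * fs / n
  freqs <- pmin(freqs, fs - freqs)             # two-sided frequency axis
  spec[freqs < low | freqs >= high] <- 0i
  y <- Re(stats::fft(spec, inverse = TRUE)) / n
  y * rms / sqrt(mean(y^2))
}

# Mean Hamming-FFT band powers of a component over all whole epochs,
# using the same estimator the pipeline applies (one FFT per epoch).
measured_band_powers <- function(x, fs, window_s = 1.8) {
  n_win <- round(window_s * fs)
  n_ep <- floor(length(x) / n_win)
  w <- 0.54 - 0.46 * cos(2 * pi * (seq_len(n_win) - 1) / (n_win - 1))
  freqs <- (seq_len(n_win) - 1) * fs / n_win
  sel <- lapply(EEG_BANDS, function(b)
    freqs >= b[1] & freqs < b[2] & freqs <= fs / 2)
  acc <- c(theta = 0, alpha = 0, beta = 0)
  for (i in seq_len(n_ep)) {
    ep <- x[((i - 1) * n_win + 1):(i * n_win)]
    spec <- Mod(stats::fft(ep * w))^2
    acc <- acc + vapply(sel, function(s) sum(spec[s]), numeric(1))
  }
  acc / n_ep
}

state_channel_signal <- function(n, fs, alpha_frac, rhythm_rms, theta_share,
                                 noise_sd) {
  p_tot <- rhythm_rms^2
  p_alpha <- alpha_frac * p_tot
  p_theta <- theta_share * (1 - alpha_frac) * p_tot
  p_beta <- (1 - theta_share) * (1 - alpha_frac) * p_tot
  theta <- bandlimited_noise(n, fs, 4, 8, sqrt(p_theta))
  alpha <- bandlimited_noise(n, fs, 8, 13, sqrt(p_alpha))
  beta <- bandlimited_noise(n, fs, 13, 30, sqrt(p_beta))
  # Spectral leakage of the finite Hamming-window band-power estimator
  # biases the realized alpha share toward the middle; rescale the alpha
  # component so that the estimator the pipeline uses sees the target
  # fraction. With per-component measured band powers M (additive for
  # independent components), solve for the alpha scale c:
  #   target = (off + c^2 * a_alpha) / (rest + c^2 * a_tot)
  m_theta <- measured_band_powers(theta, fs)
  m_alpha <- measured_band_powers(alpha, fs)
  m_beta <- measured_band_powers(beta, fs)
  off <- m_theta[["alpha"]] + m_beta[["alpha"]]
  rest <- sum(m_theta) + sum(m_beta)
  c2 <- (alpha_frac * rest - off) /
    (m_alpha[["alpha"]] - alpha_frac * sum(m_alpha))
  if (is.finite(c2) && c2 > 0) alpha <- alpha * sqrt(c2)
  theta + alpha + beta + stats::rnorm(n, sd = noise_sd)
}

#' Generate one synthetic subject
#'
#' The recording is the concatenation of the subject's three extracted
#' state sections (alert, middle, fatigue, in that order). Each section
#' carries `n_orders_per_state` RT records; the state-defining order (the
#' subject's minimum RT, the pooled lower-median RT, and the maximum RT)
#' sits at its section's center, emulating sections cut from a longer
#' session around exactly those orders — so the min/median/max section
#' selection recovers the generated sections.
#'
#' @param config a [synth_config()].
#' @param subject_id identifier.
#' @param seed subject-level seed (fully determines the subject).
#' @return list of class `synth_subject`: `recording` ([eeg_recording()]),
#'   `rt_log` (data frame), `true_states` (per-section labels 1..3),
#'   `section_spans` (list of `c(start, end)` seconds).
#' @export
generate_subject <- function(config, subject_id = "S01", seed = 1) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(seed)
  fs <- config$fs
  n_sec <- round(config$section_s * fs)
  channels <- c("FP1", "FP2", "FZ", "O2")
  # per-subject individual differences: overall amplitude scale and a
  # theta/beta tilt (the alpha fraction itself is left at target)
  amp_scale <- exp(stats::rnorm(1, 0, 0.08))
  theta_tilt <- exp(stats::rnorm(1, 0, 0.08))
  alpha0 <- config$state_alpha_fraction[[1]]
  data <- matrix(NA_real_, nrow = 3L * n_sec, ncol = length(channels),
                 dimnames = list(NULL, channels))
  for (s in 1:3) {
    rows <- ((s - 1L) * n_sec + 1L):(s * n_sec)
    a_o2 <- config$state_alpha_fraction[[s]]
    a_front <- alpha0 + config$frontal_effect * (a_o2 - alpha0)
    theta_share <- min(max(config$state_theta_share[s] * theta_tilt, 0.3), 0.85)
    for (ch in channels) {
      a <- if (ch == "O2") a_o2 else a_front
      gain <- if (ch == "O2") 1 else config$state_amp_gain[s]
      data[rows, ch] <- state_channel_signal(
        n_sec, fs, a, config$rhythm_rms * amp_scale * gain, theta_share,
        config$noise_sd)
    }
  }
  rec <- eeg_recording(data, fs = fs, subject_id = subject_id)

  # reaction-time log: n orders per section, anchor order at section center
  k <- config$n_orders_per_state
  # RT values concentrate mid-regime (Beta(3,3) over the printed range):
  # clustered RT groups show thin density at the regime boundaries, which
  # touch at 1.4 s and 1.9 s
  rt_vals <- lapply(config$rt_ranges, function(rg)
    rg[1] + (rg[2] - rg[1]) * stats::rbeta(k, 3, 3))
  pooled_median <- sort(unlist(rt_vals))[ceiling(3 * k / 2)]
  spacing <- config$section_s / k
  logs <- vector("list", 3L)
  for (s in 1:3) {
    t0 <- (s - 1) * config$section_s
    times <- t0 + (seq_len(k) - 0.5) * spacing
    center_slot <- which.min(abs(times - (t0 + config$section_s / 2)))
    times[center_slot] <- t0 + config$section_s / 2
    vals <- rt_vals[[s]]
    anchor <- switch(s, `1` = min(vals), `2` = pooled_median, `3` = max(vals))
    rest <- vals[-which(vals == anchor)[1L]]
    ordered <- append(rest, anchor, after = center_slot - 1L)
    logs[[s]] <- data.frame(subject = subject_id, order_time_s = times,
                            rt_s = ordered)
  }
  rt_log <- do.call(rbind, logs)
  structure(list(
    recording = rec, rt_log = rt_log, true_states = 1:3,
    section_spans = lapply(1:3, function(s)
      c(start = (s - 1) * config$section_s, end = s * config$section_s))
  ), class = "synth_subject")
}

#' Generate a synthetic cohort
#'
#' Subject seeds are drawn reproducibly from the master seed, so the whole
#' cohort is a pure function of `(config, seed)`.
#'
#' @param config a [synth_config()].
#' @param n number of subjects (default `config$n_subjects`).
#' @param seed master seed (default `config$seed`).
#' @return list of `synth_subject`, named `S01`, `S02`, ...
#' @export
generate_cohort <- function(config = synth_config(), n = config$n_subjects,
                            seed = config$seed) {
  stopifnot(n >= 1)
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n)
  ids <- sprintf("S%02d", seq_len(n))
  stats::setNames(lapply(seq_len(n), function(i)
    generate_subject(config, subject_id = ids[i], seed = sub_seeds[i])), ids)
}

#' Write a synthetic subject to disk
#'
#' Emits the same formats the reading side consumes: the recording in the
#' package CSV dialect (or EDF) and the RT log CSV.
#'
#' @param subject a `synth_subject`.
#' @param dir output directory (created if needed).
#' @param format `"csv"` or `"edf"` for the recording.
#' @return invisibly, the two file paths.
#' @export
write_subject <- function(subject, dir, format = c("csv", "edf")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  id <- subject$recording$subject_id
  rec_path <- file.path(dir, paste0(id, "_eeg.", format))
  if (format == "csv") write_recording_csv(subject$recording, rec_path)
  else write_edf(subject$recording, rec_path)
  rt_path <- file.path(dir, paste0(id, "_rt.csv"))
  write_rt_log(subject$rt_log, rt_path)
  invisible(c(recording = rec_path, rt_log = rt_path))
}
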