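# Fixtures built in code: pure-tone epochs, small recordings, and a cached
# miniature cohort (short sections keep the unit tests fast; the
# acceptance tests use the full default configuration).

tone_epoch <- function(freq, fs = 500, dur = 1.8, amp = 1, channel = "O2") {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  eeg_epoch(amp * sin(2 * pi * freq * t), fs = fs, channel = channel,
            duration = dur)
}

noise_recording <- function(dur_s, fs = 500, channels = c("FP1", "FP2", "FZ", "O2"),
                            seed = 1, subject_id = "T01") {
  set.seed(seed)
  n <- round(dur_s * fs)
  m <- matrix(rnorm(n * length(channels)), ncol = length(channels),
              dimnames = list(NULL, channels))
  eeg_recording(m, fs = fs, subject_id = subject_id)
}

# small cohort shared across test files (computed once per test run)
.fixture_env <- new.env()

mini_cohort <- function(n_subjects = 3, section_s = 36, seed = 42) {
  key <- sprintf("cohort_%d_%d_%d", n_subjects, section_s, seed)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- generate_cohort(
      synth_config(n_subjects = n_subjects, section_s = section_s, seed = seed))
  }
  .fixture_env[[key]]
}

mini_rows <- function(n_subjects = 3, section_s = 36, seed = 42) {
  key <- sprintf("rows_%d_%d_%d", n_subjects, section_s, seed)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- build_cohort_rows(
      mini_cohort(n_subjects, section_s, seed),
      pipeline_config(section_s = section_s, seed = seed))
  }
  .fixture_env[[key]]
}

# independent elementwise evaluation of the GRU equations (loops only, no
# matrix algebra) used as the oracle for gru_step
gru_step_oracle <- function(cell, h_prev, x) {
  hs <- cell$hidden_size
  a <- c(h_prev, x)
  out <- numeric(hs)
  r <- z <- hc <- numeric(hs)
  for (j in seq_len(hs)) {
    sr <- cell$b_r[j]; sz <- cell$b_z[j]
    for (i in seq_along(a)) {
      sr <- sr + a[i] * cell$W_r[i, j]
      sz <- sz + a[i] * cell$W_z[i, j]
    }
    r[j] <- 1 / (1 + exp(-sr))
    z[j] <- 1 / (1 + exp(-sz))
  }
  a2 <- c(h_prev * r, x)
  for (j in seq_len(hs)) {
    sh <- cell$b_h[j]
    for (i in seq_along(a2)) sh <- sh + a2[i] * cell$W_h[i, j]
    hc[j] <- tanh(sh)
    out[j] <- (1 - z[j]) * h_prev[j] + z[j] * hc[j]
  }
  out
}
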