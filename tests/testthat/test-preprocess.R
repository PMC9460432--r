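test_that("CSV recording round-trip preserves data, fs and subject", {
  rec <- noise_recording(2, seed = 7, subject_id = "S05")
  path <- withr::local_tempfile(fileext = ".csv")
  write_recording_csv(rec, path)
  back <- read_recording(path, format = "csv")
  expect_equal(back$fs, 500)
  expect_equal(back$subject_id, "S05")
  expect_equal(back$channels, rec$channels)
  expect_equal(back$data, rec$data, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("EDF round-trip recovers amplitudes within quantization", {
  rec <- noise_recording(2, seed = 8)
  rec$data <- rec$data * 50                      # physical range ~ +/-200 uV
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, path)
  back <- read_recording(path, format = "edf")
  expect_equal(back$fs, 500)
  expect_equal(back$channels, rec$channels)
  span <- max(rec$data) - min(rec$data)
  expect_lt(max(abs(back$data - rec$data)), span / 65536 + 1e-3)
})

test_that("reading rejects a recording missing a required channel", {
  rec <- noise_recording(1, channels = c("FP1", "FP2", "FZ"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_recording_csv(rec, path)
  expect_error(read_recording(path), "O2")
})

test_that("CSV without an fs line is a format error", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("FP1,FP2,FZ,O2", "1,2,3,4"), path)
  expect_error(read_recording(path), "fs")
})

test_that("band-pass attenuates stopband, preserves passband, removes DC", {
  fs <- 500
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  mk <- function(x) eeg_recording(
    matrix(rep(x, 4), ncol = 4,
           dimnames = list(NULL, c("FP1", "FP2", "FZ", "O2"))), fs = fs)
  pw <- function(x, f) band_power_fft(x[1000:4000], c(f - 1, f + 1), fs = fs)
  mains <- bandpass(mk(sin(2 * pi * 50 * t)))
  expect_lt(10 * log10(pw(mains$data[, "O2"], 50) /
                       pw(sin(2 * pi * 50 * t), 50)), -20)
  alpha <- bandpass(mk(sin(2 * pi * 10 * t)))
  mid <- 1000:4000
  expect_lt(max(abs(alpha$data[mid, "O2"] - sin(2 * pi * 10 * t)[mid])), 0.05)
  dc <- bandpass(mk(rep(100, length(t))))
  expect_lt(abs(mean(dc$data[mid, "FZ"])), 0.5)
})

test_that("band edges outside (0, fs/2) are rejected", {
  rec <- noise_recording(1)
  expect_error(bandpass(rec, 1, 300), "fs/2")
  expect_error(bandpass(rec, 0, 40), "fs/2")
})

test_that("band_split concentrates a pure tone in its own rhythm band", {
  ep10 <- tone_epoch(10)
  parts <- band_split(ep10)
  amp <- vapply(parts, function(p) sqrt(mean(p$samples[300:600]^2)), numeric(1))
  in_amp <- sqrt(mean(ep10$samples[300:600]^2))
  expect_gt(amp[["alpha"]] / in_amp, 0.9)
  expect_lt(amp[["theta"]] / in_amp, 0.1)
  expect_lt(amp[["beta"]] / in_amp, 0.1)

  ep6 <- tone_epoch(6)
  pow6 <- vapply(band_split(ep6), function(p) mean(p$samples^2), numeric(1))
  expect_equal(names(which.max(pow6)), "theta")

  zero <- eeg_epoch(numeric(900), fs = 500, duration = 1.8)
  expect_true(all(vapply(band_split(zero),
                         function(p) max(abs(p$samples)), numeric(1)) < 1e-10))
})

test_that("a single-frequency input lands >= 90% of band energy in one band", {
  for (f in c(5, 10, 20)) {
    pow <- vapply(band_split(tone_epoch(f)), function(p) sum(p$samples^2),
                  numeric(1))
    expect_gt(max(pow) / sum(pow), 0.9)
  }
})

test_that("epoching yields floor(len / window) non-overlapping windows", {
  expect_length(segment_epochs(noise_recording(180), "O2"), 100)
  expect_length(segment_epochs(noise_recording(1.7), "O2"), 0)
  eps <- segment_epochs(noise_recording(3.7), "O2")
  expect_length(eps, 2)
  expect_equal(vapply(eps, function(e) length(e$samples), integer(1)),
               c(900L, 900L))
  expect_error(segment_epochs(noise_recording(2), "CZ"), "unknown channel")
})

test_that("epoching conserves samples up to one trailing window", {
  set.seed(31)
  for (dur in runif(6, 2, 40)) {
    rec <- noise_recording(dur)
    n <- length(segment_epochs(rec, "FP1"))
    total <- nrow(rec$data)
    expect_gte(total, n * 900)
    expect_lt(total, (n + 1) * 900)
  }
})

test_that("epochs are baseline-corrected and respect the length contract", {
  eps <- segment_epochs(noise_recording(4), "FZ")
  expect_lt(max(abs(vapply(eps, function(e) mean(e$samples), numeric(1)))),
            1e-12)
  expect_error(eeg_epoch(rnorm(100), fs = 500, duration = 1.8), "length")
})

test_that("band-pass filtering is idempotent on already band-limited noise", {
  rec <- noise_recording(10, seed = 9)
  once <- bandpass(rec)
  twice <- bandpass(once)
  r1 <- sqrt(mean(once$data[, "O2"]^2))
  r2 <- sqrt(mean(twice$data[, "O2"]^2))
  expect_lt(abs(r2 - r1) / r1, 0.05)
})
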