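test_that("a 900-sample epoch decomposes into six sub-signals", {
  set.seed(11)
  d <- dwt_decompose(eeg_epoch(rnorm(900), fs = 500, duration = 1.8))
  expect_named(d$details, paste0("D", 1:5))
  expect_equal(vapply(d$details, length, integer(1)),
               c(D1 = 450L, D2 = 225L, D3 = 113L, D4 = 57L, D5 = 29L))
  expect_length(d$approximation, 29L)
  expect_error(dwt_decompose(rnorm(16)), "too short")
})

test_that("a constant signal has vanishing detail coefficients", {
  d <- dwt_decompose(rep(3.7, 256))
  expect_lt(max(vapply(d$details, function(v) max(abs(v)), numeric(1))), 1e-12)
})

test_that("the transform inverts exactly (perfect reconstruction)", {
  set.seed(12)
  for (n in c(900, 321, 256, 100)) {
    x <- rnorm(n)
    expect_lt(max(abs(dwt_reconstruct(dwt_decompose(x)) - x)), 1e-8)
  }
})

test_that("subband energies sum to signal energy (orthonormal filter bank)", {
  # exact whenever every level has even length, i.e. length divisible by 2^5
  set.seed(13)
  for (n in c(960, 512, 1600)) {
    x <- rnorm(n)
    d <- dwt_decompose(x)
    e <- sum(vapply(d$details, function(v) sum(v^2), numeric(1))) +
      sum(d$approximation^2)
    expect_lt(abs(e - sum(x^2)) / sum(x^2), 1e-6)
  }
})

test_that("coefficients match an independent DWT implementation", {
  # frozen reference values for db5/periodization on a deterministic input
  t <- (0:899) / 500
  x <- sin(2 * pi * 7 * t) + 0.5 * cos(2 * pi * 19 * t)
  d <- dwt_decompose(eeg_epoch(x, fs = 500, duration = 1.8))
  expect_equal(d$details$D1[1:3],
               c(0.052971388676, -0.009209500988, 0.000176987819),
               tolerance = 1e-10)
  expect_equal(d$details$D5[1:3],
               c(2.411083297518, -0.970113153224, 0.193896839312),
               tolerance = 1e-10)
  expect_equal(d$approximation[1:3],
               c(-4.299891054521, 2.240967482111, 1.936664317473),
               tolerance = 1e-10)
  expect_equal(sum(d$details$D5^2), 160.6309136516, tolerance = 1e-8)
  expect_equal(sum(d$approximation^2), 307.1456113655, tolerance = 1e-8)
})

test_that("nominal subband ranges follow the dyadic splits", {
  r <- subband_ranges(500)
  expect_equal(r$D5, c(7.8125, 15.625))
  expect_equal(r$A5, c(0, 7.8125))
  expect_equal(r$D1, c(125, 250))
  expect_equal(subband_ranges(64)$D1, c(16, 32))
})

test_that("time-domain statistics match hand computations", {
  expect_equal(mav(c(1, -1, 1, -1)), 1)
  expect_equal(mav(c(0, 0, 0)), 0)
  expect_equal(mav(c(3, -4)), 3.5)
  expect_equal(rms(c(1, -1)), 1)
  expect_equal(rms(c(3, -4)), sqrt(12.5))
  expect_equal(sd(c(1, 1, 1)), 0)
  expect_equal(sd(c(0, 2)), sqrt(2))
  set.seed(14)
  x <- rnorm(40)
  expect_equal(sd(x + 17.3), sd(x))                  # shift invariance
  expect_error(mav(numeric(0)), "empty")
})

test_that("mav never exceeds rms (power-mean inequality)", {
  set.seed(15)
  for (i in 1:1000) {
    x <- rnorm(sample(2:50, 1), sd = runif(1, 0.1, 10))
    expect_lte(mav(x), rms(x) + 1e-12)
  }
})

test_that("wavelet-energy entropy matches closed forms and is scale-free", {
  expect_equal(shannon_entropy(c(0, 0, 5, 0)), 0)          # point mass
  expect_equal(shannon_entropy(rep(2, 8)), 3)              # uniform: log2(8)
  expect_equal(shannon_entropy(c(1, 1, sqrt(2))), 1.5)
  set.seed(16)
  x <- rnorm(30)
  expect_equal(shannon_entropy(x), shannon_entropy(100 * x))
  expect_lte(shannon_entropy(x), log2(length(x)))
  expect_warning(se0 <- shannon_entropy(numeric(3) * 0), "all-zero")
  expect_equal(se0, 0)
})

test_that("extract_features returns the 19 named features, deterministically", {
  set.seed(17)
  ep <- eeg_epoch(rnorm(900), fs = 500, duration = 1.8)
  f1 <- extract_features(ep)
  expect_length(f1, 19)
  expect_named(f1, EEG_FEATURE_NAMES)
  expect_identical(f1, extract_features(ep))
  expect_true(all(f1[c("A1", "A3")] >= 0))
  # A4 is the D1 entropy: bounded by log2 of the D1 length
  expect_lte(f1[["A4"]], log2(450))
  suppressWarnings(
    expect_equal(unname(extract_features(numeric(900))), rep(0, 19)))
})

test_that("standardization uses training statistics only", {
  tr <- data.frame(matrix(rep(c(1, 2, 3), 19), nrow = 3))
  names(tr) <- EEG_FEATURE_NAMES
  sc <- fit_feature_scaling(tr)
  trs <- standardize_features(tr, sc)
  expect_equal(trs$A1, c(-1, 0, 1))
  te <- tr; te[] <- te[] + 5
  tes <- standardize_features(te, sc)
  expect_equal(tes$A1, c(4, 5, 6))                 # scaled by train stats
  degen <- tr; degen$B1 <- 1
  expect_warning(standardize_features(degen, fit_feature_scaling(degen)),
                 "zero-variance")
})

test_that("fusing replicates the closure value over exactly 3 channel rows", {
  f <- setNames(as.numeric(1:19), EEG_FEATURE_NAMES)
  rows <- fuse("Sample_1", 0.261, list(FP1 = f, FP2 = f + 1, FZ = f - 1), 1L)
  expect_equal(nrow(rows), 3)
  expect_equal(rows$ecd, rep(0.261, 3))
  expect_equal(rows$label, rep(1L, 3))
  expect_equal(rows$channel, c("FP1", "FP2", "FZ"))
  expect_error(fuse("s", 0.5, list(FP1 = f, FP2 = f), 1L), "FZ")
  many <- do.call(rbind, lapply(1:5, function(i)
    fuse(paste0("s", i), 0.5, list(FP1 = f, FP2 = f, FZ = f), 2L)))
  expect_equal(nrow(many), 15)
})
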