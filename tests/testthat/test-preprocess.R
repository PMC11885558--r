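test_that("windowing drops trailing remainders and short signals", {
  w <- ecg_window(stats::rnorm(12500), 100, 50)
  expect_length(w, 2)
  expect_true(all(lengths(w) == 5000))
  expect_length(ecg_window(stats::rnorm(18000), 360, 50), 1)
  expect_length(ecg_window(stats::rnorm(18000), 360, 50)[[1]], 18000)
  expect_length(ecg_window(stats::rnorm(3000), 100, 50), 0)
  expect_error(ecg_window(stats::rnorm(10), 3, 0.1), "positive integer")
})

test_that("zero-phase low-pass keeps the passband and kills the stopband", {
  t <- (0:(360 * 10 - 1)) / 360
  passband <- sin(2 * pi * 1 * t)
  out <- ecg_lowpass(passband, 360, 30, 4)
  expect_gte(sqrt(mean(out^2)) / sqrt(mean(passband^2)), 0.999)
  stopband <- sin(2 * pi * 45 * t)
  out2 <- ecg_lowpass(stopband, 360, 30, 4)
  expect_lte(sqrt(mean(out2^2)) / sqrt(mean(stopband^2)), 0.05)
  const <- rep(2.5, 1000)
  expect_lt(max(abs(ecg_lowpass(const, 360) - 2.5)), 1e-9)
  expect_error(ecg_lowpass(passband, 360, 200), "Nyquist")
})

test_that("resampling has exact lengths and preserves in-band tones", {
  x <- stats::rnorm(18000)
  expect_length(ecg_resample(x, 360, 100), 5000)
  expect_identical(ecg_resample(x, 100, 100), x)
  expect_error(ecg_resample(x, 100, 360), "out of scope")
  t360 <- (0:17999) / 360
  tone <- sin(2 * pi * 5 * t360)
  y <- ecg_resample(tone, 360, 100)
  ref <- sin(2 * pi * 5 * (0:4999) / 100)
  expect_gte(stats::cor(y, ref), 0.999)
})

test_that("filtering and resampling commute with scalar multiplication", {
  set.seed(12)
  x <- stats::rnorm(3600)
  a <- 3.7
  l1 <- ecg_lowpass(a * x, 360); l2 <- a * ecg_lowpass(x, 360)
  expect_lt(max(abs(l1 - l2)) / max(abs(l2)), 1e-9)
  r1 <- ecg_resample(a * x, 360, 100); r2 <- a * ecg_resample(x, 360, 100)
  expect_lt(max(abs(r1 - r2)) / max(abs(r2)), 1e-9)
})

test_that("smoothness-priors detrending annihilates affine signals", {
  t <- seq_len(500)
  for (lam in c(0, 1, 500)) {
    out <- detrend_sp(2 + 0.03 * t, lam)
    expect_lt(max(abs(out)), 1e-8)
  }
  expect_error(detrend_sp(c(1, 2), 500), "3 samples")
})

test_that("banded detrending solve matches a dense direct solve", {
  set.seed(13)
  z <- stats::rnorm(200)
  expect_lt(max(abs(detrend_sp(z, 500) - dense_detrend_oracle(z, 500))), 1e-8)
  expect_lt(max(abs(detrend_sp(z, 10) - dense_detrend_oracle(z, 10))), 1e-8)
  # lambda 0: the trend is the signal itself
  expect_true(all(detrend_sp(z, 0) == 0))
})

test_that("IQR rejection applies Tukey fences to segment features", {
  mk <- function(amp) amp * sin(seq(0, 2 * pi, length.out = 50))
  segs <- c(lapply(rep(1, 9), mk), list(mk(10)))
  keep <- iqr_keep(segs, 1.5, "peak_to_peak")
  expect_equal(keep, c(rep(TRUE, 9), FALSE))
  expect_true(all(iqr_keep(lapply(rep(2, 6), mk))))        # identical: IQR 0
  expect_true(all(iqr_keep(lapply(c(1, 5, 9), mk))))       # < 4 segments
})

test_that("min-max normalisation lands exactly on [0, 1]", {
  out <- minmax(c(2, 4, 6))
  expect_equal(as.numeric(out), c(0, 0.5, 1))
  expect_false(attr(out, "degenerate"))
  flat <- minmax(c(3, 3, 3))
  expect_true(all(flat == 0))
  expect_true(attr(flat, "degenerate"))
  set.seed(14)
  r <- minmax(stats::rnorm(100))
  expect_equal(range(r), c(0, 1))
})

test_that("the full pipeline emits normalised fixed-length labelled segments", {
  cfg <- synth_config(duration_s = 150, seed = 21)
  rec <- synth_record(cfg)
  segs <- run_pipeline(rec, preprocess_config(), class_scheme("mitbih"))
  expect_lte(nrow(segs), 15)
  expect_true(all(lengths(segs$samples) == 1000))
  kept <- segs[segs$kept & !segs$degenerate, ]
  for (s in kept$samples) expect_equal(range(s), c(0, 1))
  expect_true(all(kept$label == "N"))
  # a record shorter than one long window yields nothing
  short <- synth_record(synth_config(duration_s = 30, seed = 22))
  expect_equal(nrow(run_pipeline(short, preprocess_config(),
                                 class_scheme("mitbih"))), 0)
})

test_that("pipeline is pure: identical input gives identical output", {
  rec <- synth_record(synth_config(duration_s = 50, seed = 23))
  a <- run_pipeline(rec, preprocess_config(), class_scheme("mitbih"))
  b <- run_pipeline(rec, preprocess_config(), class_scheme("mitbih"))
  expect_identical(a, b)
})

test_that("clean records lose few segments to outlier rejection", {
  segs <- dplyr::bind_rows(lapply(31:34, function(sd)
    run_pipeline(synth_record(synth_config(duration_s = 100, seed = sd)),
                 preprocess_config(), class_scheme("mitbih"))))
  expect_lte(mean(!segs$kept), 0.10)
})
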