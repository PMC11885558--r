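test_that("beat templates encode the class morphology rules", {
  fs <- 360
  n <- beat_template("N", fs); v <- beat_template("V", fs)
  f <- beat_template("F", fs); q <- beat_template("Q", fs)
  s <- beat_template("S", fs)
  # fusion is the pointwise average of normal and ventricular
  expect_equal(f$samples, (n$samples + v$samples) / 2, tolerance = 1e-12)
  # ventricular QRS at least twice as wide (width of the central complex
  # above 20% of the R amplitude, restricted to +/- 0.15 s around R)
  width <- function(tp) {
    ctr <- tp$r_offset + 1 + seq(-round(0.15 * fs), round(0.15 * fs))
    qrs <- abs(tp$samples[ctr])
    sum(qrs > 0.2 * max(qrs)) / fs
  }
  expect_gte(width(v) / width(n), 2)
  # supraventricular template omits the P wave: no deflection at the P site
  p_win <- n$r_offset + 1 + seq(-round(0.24 * fs), -round(0.16 * fs))
  expect_lt(max(abs(s$samples[p_win])), 0.05)
  expect_gt(max(abs(n$samples[p_win])), 0.09)
  # determinism
  expect_identical(beat_template("V", 250), beat_template("V", 250))
  expect_error(beat_template("X", fs), "unknown beat class")
})

test_that("synthetic records have contracted length, beats and determinism", {
  cfg <- synth_config(duration_s = 50, seed = 42)
  rec <- synth_record(cfg)
  expect_length(rec$samples, 18000)
  r2 <- synth_record(cfg)
  expect_identical(rec$samples, r2$samples)
  expect_identical(rec$annotations, r2$annotations)
  r3 <- synth_record(synth_config(duration_s = 50, seed = 43))
  expect_false(identical(rec$samples, r3$samples))
  # beat count ~ duration * hr / 60 (120 s at 70 bpm ~ 140)
  long <- synth_record(synth_config(duration_s = 120, seed = 44))
  expect_true(abs(nrow(long$annotations) - 140) <= 4)
})

test_that("mixed-class records annotate ectopic beats prematurely", {
  cfg <- synth_config(duration_s = 60, class_mix = c(N = 0.6, V = 0.4),
                      seed = 45)
  rec <- synth_record(cfg)
  ann <- rec$annotations
  expect_setequal(unique(ann$symbol), c("N", "V"))
  rr <- diff(ann$sample_index) / rec$fs
  pre_v <- rr[which(ann$symbol[-1] == "V")]
  pre_n <- rr[which(ann$symbol[-1] == "N")]
  expect_lt(mean(pre_v), mean(pre_n))   # premature arrival
})

test_that("labelled datasets have the requested composition", {
  tbl <- make_labeled_dataset(2, classes = c("N", "V"),
                              scheme = class_scheme("icentia"),
                              config = synth_config(duration_s = 50, seed = 46))
  expect_equal(nrow(tbl), 4)
  expect_equal(sort(unique(tbl$class)), c("N", "V"))
  t2 <- make_labeled_dataset(2, classes = c("N", "V"),
                             scheme = class_scheme("icentia"),
                             config = synth_config(duration_s = 50, seed = 46))
  expect_identical(tbl$record_id, t2$record_id)
  expect_identical(tbl$record[[1]]$samples, t2$record[[1]]$samples)
  # generated class-c records yield class-c segment labels
  segs <- make_labeled_dataset(2, classes = c("N", "V"),
                               scheme = class_scheme("icentia"),
                               config = synth_config(duration_s = 50, seed = 46),
                               output = "segments")
  agree <- mean(segs$label == segs$class)
  expect_gte(agree, 0.9)
})

test_that("template spectral energy concentrates in the retained band", {
  # the 0-15 Hz band dominates the template spectrum (the QRS complex, a
  # ~50 ms deflection, necessarily spreads some energy above 15 Hz; the
  # bulk of the morphology information is retained by the band limit)
  for (cls in c("N", "V")) {
    tp <- beat_template(cls, 100)
    x <- tp$samples - mean(tp$samples)
    n <- length(x)
    p <- Mod(stats::fft(x))^2
    freq <- (seq_len(n) - 1) * 100 / n
    inband <- sum(p[freq <= 15 | freq >= 100 - 15]) / sum(p)
    expect_gte(inband, 0.80)
  }
  # and the wide ventricular complex is more band-concentrated than normal
  conc <- function(cls) {
    tp <- beat_template(cls, 100)
    x <- tp$samples - mean(tp$samples)
    p <- Mod(stats::fft(x))^2
    freq <- (seq_along(x) - 1) * 100 / length(x)
    sum(p[freq <= 15 | freq >= 85]) / sum(p)
  }
  expect_gt(conc("V"), conc("N"))
})

test_that("noise-free records reduce to the beat train after the pipeline", {
  cfg <- synth_config(duration_s = 50, seed = 47, baseline_mv = 0,
                      powerline_mv = 0, white_noise_sd = 0)
  rec <- synth_record(cfg)
  # detrended, filtered segments still carry beat peaks at annotated spots
  segs <- run_pipeline(rec, preprocess_config(), class_scheme("icentia"))
  kept <- segs[segs$kept & !segs$degenerate, ]
  ann100 <- round(rec$annotations$sample_index * 100 / rec$fs)
  hits <- 0; total <- 0
  for (i in seq_len(nrow(kept))) {
    s0 <- kept$start_time_s[i] * 100
    inside <- ann100[ann100 >= s0 & ann100 < s0 + 1000] - s0 + 1
    for (a in inside) {
      total <- total + 1
      win <- kept$samples[[i]][max(1, a - 10):min(1000, a + 10)]
      # R peak is the local maximum of the normalised segment
      if (max(win) > 0.7) hits <- hits + 1
    }
  }
  expect_gte(hits / total, 0.95)
})
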