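# shared fixtures, all generated in code

# a short annotated record with known beat positions
tiny_record <- function(fs = 360, duration_s = 4,
                        ann_idx = c(100, 450, 800),
                        ann_sym = c("N", "V", "N")) {
  n <- fs * duration_s
  x <- sin(2 * pi * 1.3 * (0:(n - 1)) / fs) * 0.5
  stecg:::new_raw_record("tiny01", x, fs, "MLII",
                         tibble::tibble(sample_index = as.numeric(ann_idx),
                                        symbol = ann_sym))
}

# dense direct solve of the smoothness-priors trend (independent oracle)
dense_detrend_oracle <- function(z, lambda) {
  n <- length(z)
  d2 <- matrix(0, n - 2, n)
  for (i in seq_len(n - 2)) d2[i, i:(i + 2)] <- c(1, -2, 1)
  trend <- solve(diag(n) + lambda^2 * t(d2) %*% d2, z)
  z - trend
}

# tiny model configuration for fast structural/training tests
tiny_model_config <- function(n_classes = 4L, dropout = 0.2, sd_p = 0.2) {
  model_config(stem_channels = 4L, stage_widths = c(4L, 8L, 8L, 16L),
               cardinality = 2L, se_reduction = 2L, embed_dim = 16L,
               n_heads = 2L, ffn_dim = 32L, head_hidden = 8L,
               n_classes = n_classes, dropout = dropout,
               stochastic_depth_p = sd_p)
}

expect_rel_equal <- function(a, b, tol) {
  expect_lt(max(abs(a - b)) / max(1e-12, max(abs(b))), tol)
}
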