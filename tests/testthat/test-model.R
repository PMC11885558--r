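test_that("configuration invariants are enforced", {
  expect_error(model_config(embed_dim = 500L), "final stage width")
  expect_error(model_config(stage_widths = c(64L, 128L, 256L, 516L),
                            embed_dim = 516L), "divisible by n_heads")
  expect_error(model_config(cardinality = 48L), "cardinality")
  cfg <- model_config()
  expect_equal(cfg$stage_widths, c(64L, 128L, 256L, 512L))
  expect_equal(cfg$n_heads, 8L)
  expect_equal(cfg$ffn_dim, 2048L)
  expect_equal(cfg$se_reduction, 16L)
  expect_equal(cfg$stochastic_depth_p, 0.2)
})

test_that("model structure matches the architecture table", {
  md <- build_model(tiny_model_config(), seed = 1)
  expect_length(md$stages, 4)
  expect_equal(sum(lengths(md$stages)), 8)            # 2 blocks x 4 stages
  expect_length(md$tblocks, 4)
  expect_equal(md$config$n_heads %% 1, 0)
  # head contract: n_classes columns out
  x <- array(stats::rnorm(2 * 33 * 40), dim = c(2, 33, 40, 1))
  z <- md$forward(x, train = FALSE)
  expect_equal(dim(z), c(4L, 1L))
  md5 <- build_model(tiny_model_config(n_classes = 5L), seed = 1)
  expect_equal(dim(md5$forward(x, FALSE)), c(5L, 1L))
})

test_that("spatial dimensions follow ceil-division through the extractor", {
  md <- build_model(tiny_model_config(), seed = 2)
  x <- array(stats::rnorm(2 * 38 * 50 * 2), dim = c(2, 38, 50, 2))
  f <- md$feature_extract(x, FALSE)
  expect_equal(dim(f), c(16L, 2L, 2L, 2L))   # ceil(38/32), ceil(50/32)
  p <- md$encode(f, FALSE)
  expect_equal(dim(p), c(16L, 2L))
  expect_equal(md$enc_t, 4L)                 # T = H' * W'
})

test_that("construction is deterministic in the seed", {
  a <- build_model(tiny_model_config(), seed = 7)
  b <- build_model(tiny_model_config(), seed = 7)
  expect_equal(n_parameters(a), n_parameters(b))
  pa <- a$param_layers(); pb <- b$param_layers()
  for (i in seq_along(pa)) expect_identical(pa[[i]]$params, pb[[i]]$params)
  c2 <- build_model(tiny_model_config(), seed = 8)
  expect_false(identical(pa[[1]]$params, c2$param_layers()[[1]]$params))
})

test_that("evaluation mode is deterministic and batch-invariant", {
  md <- build_model(tiny_model_config(), seed = 3)
  set.seed(30)
  x1 <- array(stats::rnorm(2 * 35 * 40), dim = c(2, 35, 40, 1))
  x2 <- array(stats::rnorm(2 * 35 * 40), dim = c(2, 35, 40, 1))
  expect_identical(md$forward(x1, FALSE), md$forward(x1, FALSE))
  pair <- array(c(x1, x2), dim = c(2, 35, 40, 2))
  zp <- md$forward(pair, FALSE)
  expect_equal(zp[, 1], md$forward(x1, FALSE)[, 1], tolerance = 1e-6)
  expect_equal(zp[, 2], md$forward(x2, FALSE)[, 1], tolerance = 1e-6)
  # permuting the batch permutes the logits identically
  perm <- array(c(x2, x1), dim = c(2, 35, 40, 2))
  expect_equal(md$forward(perm, FALSE)[, c(2, 1)], zp, tolerance = 1e-6)
})

test_that("SE gate stays in (0,1) and all-ones gating is plain ResNeXt", {
  se <- stecg:::nn_se_block(8, 2)
  set.seed(31)
  x <- array(stats::rnorm(8 * 5 * 6 * 2), dim = c(8, 5, 6, 2))
  y <- se$forward(x, FALSE)
  g <- se$cache$g
  expect_true(all(g > 0 & g < 1))
  # force the gate open: zero weights, huge positive bias -> sigmoid ~ 1
  se$params$w1[] <- 0; se$params$w2[] <- 0
  se$params$b2[] <- 60
  expect_equal(se$forward(x, FALSE), x, tolerance = 1e-12)
})

test_that("zeroing the transformer reduces encoding to the skip path", {
  md <- build_model(tiny_model_config(dropout = 0, sd_p = 0), seed = 4)
  set.seed(32)
  x <- array(stats::rnorm(2 * 38 * 50), dim = c(2, 38, 50, 1))
  f <- md$feature_extract(x, FALSE)
  s_ref <- aperm(f, c(1, 3, 2, 4))
  dim(s_ref) <- c(dim(f)[1], dim(f)[3] * dim(f)[2], dim(f)[4])
  # zero every transformer-block weight (incl. layer-norm affine)
  for (tb in md$tblocks)
    for (ly in stecg:::collect_param_layers(tb))
      for (nm in names(ly$params)) ly$params[[nm]][] <- 0
  p <- md$encode(f, FALSE)
  pe <- md$posenc$forward(s_ref, FALSE)
  manual <- apply(pe, c(1, 3), mean)
  expect_equal(p, manual, tolerance = 1e-12)
})

test_that("one small optimisation step reduces the loss on a single sample", {
  md <- build_model(tiny_model_config(dropout = 0, sd_p = 0), seed = 5)
  set.seed(33)
  x <- array(stats::rnorm(2 * 33 * 40), dim = c(2, 33, 40, 1))
  yb <- 2L
  opt <- stecg:::radam_new(md$param_layers(), lr = 1e-3)
  # several steps so the rectified-Adam warmup takes effect
  for (i in 1:8) {
    md$zero_grads()
    z <- md$forward(x, train = TRUE)
    fl <- focal_loss(z, yb, gamma = 2)
    if (i == 1) first <- fl$loss
    md$backward(fl$grad)
    stecg:::radam_step(opt)
  }
  final <- focal_loss(md$forward(x, TRUE), yb, gamma = 2)$loss
  expect_lt(final, first)
})

test_that("weight snapshots restore the exact state", {
  md <- build_model(tiny_model_config(), seed = 6)
  set.seed(34)
  x <- array(stats::rnorm(2 * 33 * 40), dim = c(2, 33, 40, 2))
  z0 <- md$forward(x, FALSE)
  snap <- snapshot_weights(md)
  opt <- stecg:::radam_new(md$param_layers(), lr = 1e-2)
  md$zero_grads()
  z <- md$forward(x, TRUE)
  md$backward(focal_loss(z, c(1L, 2L), 2)$grad)
  stecg:::radam_step(opt)
  expect_false(isTRUE(all.equal(md$forward(x, FALSE), z0)))
  restore_weights(md, snap)
  expect_identical(md$forward(x, FALSE), z0)
})
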