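test_that("focal loss with gamma 0 is exactly cross-entropy", {
  set.seed(51)
  for (i in 1:10) {
    z <- matrix(stats::rnorm(5 * 8, sd = 2), 5)
    y <- sample(5, 8, replace = TRUE)
    p <- exp(z) / rep(colSums(exp(z)), each = 5)
    ce <- mean(-log(p[cbind(y, 1:8)]))
    expect_equal(focal_loss(z, y, gamma = 0)$loss, ce, tolerance = 1e-7)
  }
})

test_that("focal loss closed-form check at p = 0.9, gamma = 2", {
  # logits chosen so softmax gives exactly (0.9, 0.1)
  z <- matrix(c(log(0.9), log(0.1)), 2)
  expect_equal(focal_loss(z, 1L, gamma = 2)$loss, 0.01 * (-log(0.9)),
               tolerance = 1e-12)
})

test_that("focal loss decreases as the true-class probability grows", {
  losses <- vapply(seq(0.05, 0.95, by = 0.05), function(p) {
    z <- matrix(c(log(p), log(1 - p)), 2)
    focal_loss(z, 1L, gamma = 2)$loss
  }, numeric(1))
  expect_true(all(diff(losses) < 0))
  # perfectly confident correct prediction: loss -> 0
  z <- matrix(c(40, 0), 2)
  expect_lt(focal_loss(z, 1L, gamma = 2)$loss, 1e-12)
})

test_that("focal gradient matches a numerical derivative", {
  set.seed(52)
  z <- matrix(stats::rnorm(4 * 3), 4)
  y <- c(2L, 1L, 4L)
  for (gm in c(0, 2)) {
    g <- focal_loss(z, y, gamma = gm)$grad
    num <- array(0, dim(z))
    for (i in seq_along(z)) {
      zp <- z; zp[i] <- zp[i] + 1e-6
      zm <- z; zm[i] <- zm[i] - 1e-6
      num[i] <- (focal_loss(zp, y, gamma = gm)$loss -
                   focal_loss(zm, y, gamma = gm)$loss) / 2e-6
    }
    expect_lt(max(abs(g - num)), 1e-6)
  }
  # per-class alpha weights scale the loss
  a <- c(2, 1, 1, 1)
  z1 <- matrix(c(3, 0, 0, 0), 4)
  expect_equal(focal_loss(z1, 1L, gamma = 0, alpha = a)$loss,
               2 * focal_loss(z1, 1L, gamma = 0)$loss, tolerance = 1e-12)
})

test_that("SMOTE equalises counts with convex same-class interpolants", {
  set.seed(53)
  x <- rbind(matrix(stats::rnorm(100 * 4), 100),
             matrix(stats::rnorm(10 * 4, mean = 6), 10))
  y <- c(rep("N", 100), rep("V", 10))
  out <- smote_oversample(x, y, k = 5, seed = 9)
  expect_equal(as.vector(table(out$y)), c(100, 100))
  # originals untouched, in order
  expect_identical(out$x[1:110, ], x)
  # every synthetic row solves x_i + u (x_nn - x_i) for some same-class
  # neighbour pair with u in [0, 1]
  xc <- x[y == "V", ]
  synth <- out$x[-(1:110), , drop = FALSE]
  for (i in seq_len(nrow(synth))) {
    found <- FALSE
    for (a in seq_len(nrow(xc))) for (b in seq_len(nrow(xc))) {
      if (a == b) next
      dir <- xc[b, ] - xc[a, ]
      u <- sum((synth[i, ] - xc[a, ]) * dir) / sum(dir^2)
      if (u >= -1e-9 && u <= 1 + 1e-9 &&
          max(abs(synth[i, ] - (xc[a, ] + u * dir))) < 1e-8) {
        found <- TRUE; break
      }
    }
    expect_true(found)
  }
})

test_that("SMOTE is a seeded deterministic no-op on balanced data", {
  set.seed(54)
  x <- matrix(stats::rnorm(40), 10)
  y <- rep(c("a", "b"), each = 5)
  expect_identical(smote_oversample(x, y, seed = 1), list(x = x, y = y))
  xi <- rbind(x, matrix(stats::rnorm(8), 2))
  yi <- c(y, "c", "c")
  o1 <- smote_oversample(xi, yi, k = 3, seed = 11)
  o2 <- smote_oversample(xi, yi, k = 3, seed = 11)
  expect_identical(o1, o2)
  o3 <- smote_oversample(xi, yi, k = 3, seed = 12)
  expect_false(identical(o1$x, o3$x))
  # singleton class: instructed duplication fallback
  expect_error(smote_oversample(rbind(x, stats::rnorm(4)), c(y, "z"), seed = 1),
               "single member")
})

test_that("prediction takes the argmax with ties toward lower classes", {
  stub <- new.env()
  stub$forward <- function(x, train) {
    n <- dim(x)[4]
    z <- matrix(0, 4, n)
    z[, 1] <- c(0, 0, 3, 0)
    if (n > 1) z[, 2] <- c(1, 1, 0, 0)
    z
  }
  x <- array(0, dim = c(2, 3, 3, 2))
  expect_equal(predict_model(stub, x), c(3L, 1L))
})

test_that("training stops early, restores the best weights, and is seeded", {
  set.seed(55)
  # tiny separable two-prototype problem
  proto <- list(array(stats::rnorm(2 * 33 * 40), dim = c(2, 33, 40)),
                array(stats::rnorm(2 * 33 * 40), dim = c(2, 33, 40)))
  mk <- function(n, noise = 0.4) {
    y <- rep(1:2, length.out = n)
    x <- array(0, dim = c(2, 33, 40, n))
    for (i in 1:n) x[, , , i] <- proto[[y[i]]] +
        array(stats::rnorm(2 * 33 * 40, 0, noise), dim = c(2, 33, 40))
    list(x = x, y = y)
  }
  tr <- mk(24); va <- mk(8)
  cfg <- train_config(lr = 3e-3, batch_size = 8L, max_epochs = 10L,
                      patience = 3L, scheduler = "none", seed = 77L)
  fit1 <- fit_model(build_model(tiny_model_config(n_classes = 2L), seed = 9),
                    tr$x, tr$y, va$x, va$y, cfg)
  fit2 <- fit_model(build_model(tiny_model_config(n_classes = 2L), seed = 9),
                    tr$x, tr$y, va$x, va$y, cfg)
  expect_equal(fit1$history$train_loss, fit2$history$train_loss,
               tolerance = 1e-6)
  expect_equal(fit1$history$val_loss, fit2$history$val_loss, tolerance = 1e-6)
  # never returns weights from after the best validation epoch
  expect_lte(fit1$best_epoch, max(fit1$history$epoch))
  # restored checkpoint reproduces the recorded best validation loss
  ev <- stecg:::evaluate_split(fit1$model, va$x, va$y, cfg)
  expect_equal(ev$loss, min(fit1$history$val_loss), tolerance = 1e-9)
  expect_identical(predict_model(fit1$model, va$x),
                   predict_model(fit2$model, va$x))
})

test_that("learning-rate schedules follow their formulas", {
  expect_equal(lr_schedule("none", 17), 1)
  expect_equal(lr_schedule("exponential", 3, gamma = 0.9), 0.81)
  # cosine warm restarts: fresh restart at epochs 1, 11, 31 (T0=10, mult=2)
  expect_equal(lr_schedule("cosine_warm_restarts", 1), 1)
  expect_equal(lr_schedule("cosine_warm_restarts", 11), 1)
  expect_equal(lr_schedule("cosine_warm_restarts", 31), 1)
  expect_equal(lr_schedule("cosine_warm_restarts", 6),
               (1 + cos(pi * 5 / 10)) / 2)
  expect_lt(lr_schedule("cosine_warm_restarts", 10),
            lr_schedule("cosine_warm_restarts", 9))
})
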