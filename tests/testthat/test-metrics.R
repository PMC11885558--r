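test_that("confusion matrix counts truth rows against prediction columns", {
  cm <- confusion(c(0, 0, 1), c(0, 1, 1), labels = c(0, 1))
  expect_equal(unclass(cm), matrix(c(1L, 0L, 1L, 1L), 2,
                                   dimnames = list(true = c("0", "1"),
                                                   predicted = c("0", "1"))))
  ident <- confusion(c("a", "b", "b"), c("a", "b", "b"))
  expect_true(all(ident[row(ident) != col(ident)] == 0))
  expect_error(confusion(1, c(1, 2)), "equal length")
})

test_that("metric hand-checks on a 2x2 matrix agree with the definitions", {
  cm <- matrix(c(8, 1, 2, 9), 2)   # [[8,2],[1,9]] rows = truth
  expect_equal(overall_accuracy(cm), 0.85, tolerance = 1e-12)
  expect_equal(cohen_kappa(cm), 0.7, tolerance = 1e-12)
  expect_equal(mcc_multiclass(cm), 70 / sqrt(9900), tolerance = 1e-12)
  pc <- per_class_metrics(cm)
  expect_equal(pc$se[1], 0.8, tolerance = 1e-12)
  expect_equal(pc$ppv[1], 8 / 9, tolerance = 1e-12)
  expect_equal(pc$f1[1], 16 / 19, tolerance = 1e-12)
})

test_that("generalised MCC reduces to the binary formula on 2x2 matrices", {
  set.seed(7)
  binary_mcc <- function(tp, fn, fp, tn) {
    den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
    if (den == 0) 0 else (tp * tn - fp * fn) / den
  }
  for (i in 1:100) {
    m <- matrix(rpois(4, 6), 2)
    expect_equal(mcc_multiclass(m),
                 binary_mcc(m[1, 1], m[1, 2], m[2, 1], m[2, 2]),
                 tolerance = 1e-12)
  }
})

test_that("degenerate counts follow the stated zero rules", {
  perfect <- diag(c(5L, 3L, 2L))
  expect_equal(overall_accuracy(perfect), 1)
  expect_equal(cohen_kappa(perfect), 1)
  expect_equal(mcc_multiclass(perfect), 1)
  expect_true(all(per_class_metrics(perfect)$f1 == 1))
  # one predicted column only -> MCC 0 by the degenerate-denominator rule
  onecol <- matrix(c(4, 3, 0, 0), 2)
  expect_equal(mcc_multiclass(onecol), 0)
  # uniform matrix: predictions independent of truth -> kappa 0
  expect_equal(cohen_kappa(matrix(2, 3, 3)), 0)
  # absent class: all three per-class metrics 0, flagged
  m <- matrix(c(5, 0, 0, 0), 2)
  pc <- per_class_metrics(m)
  expect_equal(unlist(pc[2, c("se", "ppv", "f1")], use.names = FALSE),
               c(0, 0, 0))
  expect_true(pc$degenerate[2])
})

test_that("metrics are invariant under simultaneous class permutation", {
  set.seed(11)
  m <- matrix(rpois(16, 5), 4)
  for (i in 1:5) {
    p <- sample(4)
    mp <- m[p, p]
    expect_equal(overall_accuracy(mp), overall_accuracy(m), tolerance = 1e-12)
    expect_equal(cohen_kappa(mp), cohen_kappa(m), tolerance = 1e-12)
    expect_equal(mcc_multiclass(mp), mcc_multiclass(m), tolerance = 1e-12)
  }
})

test_that("kappa never exceeds accuracy and report tidiers are consistent", {
  set.seed(3)
  for (i in 1:20) {
    m <- matrix(rpois(9, 4), 3)
    if (sum(m) == 0) next
    expect_lte(cohen_kappa(m), overall_accuracy(m) + 1e-12)
  }
  rep <- metric_report(c("N", "V", "N", "V"), c("N", "V", "V", "V"))
  g <- glance(rep)
  expect_equal(g$overall_acc, 0.75)
  expect_equal(g$overall_acc_pct, 75)
  td <- tidy(rep)
  expect_setequal(unique(td$metric), c("se", "ppv", "f1"))
  # every reported value is reproducible from the emitted matrix alone
  expect_equal(g$kappa, cohen_kappa(rep$cm))
  expect_equal(g$mcc, mcc_multiclass(rep$cm))
})
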