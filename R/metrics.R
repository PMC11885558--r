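# Confusion matrix and classification metrics.

#' Confusion matrix
#'
#' @param y_true,y_pred equal-length vectors of class labels; either
#'   integer codes in `1..K` (or `0..K-1`) or factors/characters over
#'   `labels`.
#' @param labels class labels in display order; inferred from factor
#'   levels or sorted unique values when omitted.
#' @return A K x K integer matrix of class `confusion_matrix`; rows are
#'   true classes, columns predicted classes.
#' @examples
#' confusion(c("N", "N", "V"), c("N", "V", "V"), labels = c("N", "V"))
#' @export
confusion <- function(y_true, y_pred, labels = NULL) {
  if (length(y_true) != length(y_pred))
    rlang::abort("`y_true` and `y_pred` must have equal length.")
  if (is.null(labels)) {
    labels <- if (is.factor(y_true)) levels(y_true)
              else sort(unique(c(as.character(y_true), as.character(y_pred))))
  }
  labels <- as.character(labels)
  ft <- factor(as.character(y_true), levels = labels)
  fp <- factor(as.character(y_pred), levels = labels)
  if (anyNA(ft) || anyNA(fp))
    rlang::abort("labels outside the declared label set.")
  cm <- table(true = ft, predicted = fp)
  cm <- matrix(as.integer(cm), nrow = length(labels),
               dimnames = list(true = labels, predicted = labels))
  structure(cm, class = c("confusion_matrix", "matrix", "array"))
}

as_cm <- function(cm) {
  m <- unclass(cm)
  stopifnot(is.matrix(m), nrow(m) == ncol(m), all(m >= 0))
  m
}

#' Per-class sensitivity, precision and F1
#'
#' For each class: sensitivity (recall) `Se = TP/(TP+FN)`, positive
#' predictive value (precision) `PPV = TP/(TP+FP)`, and their harmonic
#' mean F1. Any 0/0 is defined as 0 so reports are always numeric; the
#' `degenerate` column flags classes where that rule fired.
#'
#' @param cm a square confusion matrix (rows true, columns predicted).
#' @return A tibble with one row per class: `class`, `se`, `ppv`, `f1`,
#'   `support`, `degenerate`.
#' @export
per_class_metrics <- function(cm) {
  m <- as_cm(cm)
  tp <- diag(m)
  fn <- rowSums(m) - tp
  fp <- colSums(m) - tp
  div0 <- function(num, den) ifelse(den > 0, num / den, 0)
  se <- div0(tp, tp + fn)
  ppv <- div0(tp, tp + fp)
  f1 <- div0(2 * se * ppv, se + ppv)
  labs <- rownames(m) %||% as.character(seq_len(nrow(m)))
  tibble::tibble(class = labs, se = unname(se), ppv = unname(ppv),
                 f1 = unname(f1), support = unname(rowSums(m)),
                 degenerate = unname((tp + fn) == 0 | (tp + fp) == 0))
}

#' Overall accuracy of a confusion matrix
#' @inheritParams per_class_metrics
#' @return trace / total, a fraction in \[0, 1\].
#' @export
overall_accuracy <- function(cm) {
  m <- as_cm(cm)
  n <- sum(m)
  if (n == 0) rlang::abort("empty confusion matrix.")
  sum(diag(m)) / n
}

#' Cohen's kappa
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` with expected
#' agreement `p_e = sum_c row_c * col_c / n^2`; defined as 0 when
#' `p_e = 1`.
#' @inheritParams per_class_metrics
#' @export
cohen_kappa <- function(cm) {
  m <- as_cm(cm)
  n <- sum(m)
  if (n == 0) rlang::abort("empty confusion matrix.")
  po <- sum(diag(m)) / n
  pe <- sum(rowSums(m) * colSums(m)) / n^2
  if (abs(1 - pe) < .Machine$double.eps^0.5) return(0)
  (po - pe) / (1 - pe)
}

#' Multiclass Matthews correlation coefficient
#'
#' Gorodkin's generalisation:
#' `(n * tr(C) - sum_k r_k c_k) / sqrt((n^2 - sum r^2)(n^2 - sum c^2))`
#' with row sums `r` and column sums `c`; a zero denominator (all mass in
#' one true or one predicted class) yields 0. On 2x2 matrices this equals
#' the classical binary MCC.
#' @inheritParams per_class_metrics
#' @export
mcc_multiclass <- function(cm) {
  m <- as_cm(cm)
  n <- sum(m)
  if (n == 0) rlang::abort("empty confusion matrix.")
  r <- rowSums(m); cs <- colSums(m)
  num <- n * sum(diag(m)) - sum(r * cs)
  den2 <- (n^2 - sum(r^2)) * (n^2 - sum(cs^2))
  if (den2 <= 0) return(0)
  num / sqrt(den2)
}

#' Full metric report
#'
#' Bundles the confusion matrix with every reported metric: overall
#' accuracy, per-class F1/Se/PPV, Cohen's kappa and multiclass MCC.
#'
#' @param y_true,y_pred label vectors, or pass a ready confusion matrix
#'   as `cm` instead.
#' @param labels optional label order (see [confusion()]).
#' @param cm optional precomputed confusion matrix.
#' @return An object of class `metric_report` with elements `cm`,
#'   `overall_acc`, `per_class` (tibble), `kappa`, `mcc`.
#' @export
metric_report <- function(y_true = NULL, y_pred = NULL, labels = NULL, cm = NULL) {
  if (is.null(cm)) cm <- confusion(y_true, y_pred, labels)
  structure(
    list(cm = cm,
         overall_acc = overall_accuracy(cm),
         per_class = per_class_metrics(cm),
         kappa = cohen_kappa(cm),
         mcc = mcc_multiclass(cm)),
    class = "metric_report"
  )
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("<metric_report>  n = %d\n", sum(x$cm)))
  cat(sprintf("  overall accuracy: %.4f (%.2f%%)\n", x$overall_acc, 100 * x$overall_acc))
  cat(sprintf("  Cohen's kappa:    %.4f\n  MCC:              %.4f\n", x$kappa, x$mcc))
  print(x$per_class)
  invisible(x)
}

#' @describeIn metric_report per-class rows plus overall rows, with both
#'   fraction and percent forms.
#' @param x a `metric_report`.
#' @param ... unused.
#' @export
tidy.metric_report <- function(x, ...) {
  pc <- x$per_class
  tidyr::pivot_longer(pc, cols = c("se", "ppv", "f1"),
                      names_to = "metric", values_to = "value") |>
    dplyr::mutate(percent = 100 * .data$value) |>
    dplyr::select("class", "metric", "value", "percent", "support")
}

#' @describeIn metric_report one-row summary (accuracy, kappa, MCC,
#'   macro-F1, n).
#' @export
glance.metric_report <- function(x, ...) {
  tibble::tibble(
    overall_acc = x$overall_acc,
    overall_acc_pct = 100 * x$overall_acc,
    macro_f1 = mean(x$per_class$f1),
    kappa = x$kappa,
    mcc = x$mcc,
    n = sum(x$cm)
  )
}

#' @export
autoplot.metric_report <- function(object, ...) {
  m <- as_cm(object$cm)
  df <- as.data.frame(as.table(m))
  names(df) <- c("true", "predicted", "count")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$true,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), colour = "grey20") +
    ggplot2::scale_y_discrete(limits = rev(rownames(m))) +
    ggplot2::scale_fill_gradient(low = "white", high = "#2c7fb8") +
    ggplot2::labs(x = "predicted class", y = "true class",
                  title = "Confusion matrix") +
    ggplot2::theme_minimal()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
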