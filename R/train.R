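# Training harness: focal loss, SMOTE, fit with early stopping.

#' Training configuration
#'
#' Defaults follow the training protocol implemented by this package:
#' rectified Adam at learning rate 3e-4, batch size 64, up to 200
#' epochs with early stopping at patience 15 on validation loss, cosine
#' warm-restart scheduling, focal loss (gamma 2, uniform alpha), SMOTE
#' oversampling of the training split enabled with 5 neighbours.
#'
#' @param lr learning rate.
#' @param batch_size minibatch size (64 or 256 are the explored values).
#' @param max_epochs epoch cap.
#' @param patience early-stopping patience (epochs without validation
#'   improvement); must be below `max_epochs`.
#' @param scheduler `"cosine_warm_restarts"`, `"exponential"` or
#'   `"none"`.
#' @param weight_decay decoupled L2 penalty added to every gradient
#'   (0 disables; small positive values curb overfitting on desk-scale
#'   datasets).
#' @param focal_gamma focusing parameter, >= 0.
#' @param focal_alpha per-class weight vector or `NULL` for uniform.
#' @param smote_enabled oversample the training split with SMOTE.
#' @param smote_k SMOTE neighbour count.
#' @param seed integer seed covering initialisation order, shuffling,
#'   dropout and stochastic depth.
#' @return A `train_config` list.
#' @export
train_config <- function(lr = 3e-4, batch_size = 64L, max_epochs = 200L,
                         patience = 15L,
                         scheduler = c("cosine_warm_restarts",
                                       "exponential", "none"),
                         weight_decay = 0, focal_gamma = 2,
                         focal_alpha = NULL,
                         smote_enabled = TRUE, smote_k = 5L, seed = 1L) {
  scheduler <- match.arg(scheduler)
  if (lr <= 0) rlang::abort("lr must be positive.")
  if (patience >= max_epochs)
    rlang::abort("patience must be below max_epochs.")
  structure(list(lr = lr, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), scheduler = scheduler,
                 weight_decay = weight_decay,
                 focal_gamma = focal_gamma, focal_alpha = focal_alpha,
                 smote_enabled = smote_enabled, smote_k = as.integer(smote_k),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Focal loss (multiclass) and its gradient
#'
#' Mean over the batch of `-alpha_y (1 - p_y)^gamma log p_y` with
#' `p = softmax(logits)`. `gamma = 0` with uniform alpha reduces exactly
#' to cross-entropy. Probabilities are clamped at 1e-12 so the loss is
#' finite for any finite logits.
#'
#' @param logits matrix `[K, B]` of unnormalised scores.
#' @param targets integer vector in `1..K`.
#' @param gamma focusing parameter >= 0.
#' @param alpha per-class weights (length K) or `NULL` for 1.
#' @return List with `loss` (scalar) and `grad` (`[K, B]`, gradient of
#'   the mean loss w.r.t. the logits).
#' @export
focal_loss <- function(logits, targets, gamma = 2, alpha = NULL) {
  if (is.null(dim(logits))) logits <- matrix(logits, ncol = 1)
  k <- nrow(logits); b <- ncol(logits)
  if (length(targets) != b || any(targets < 1L) || any(targets > k))
    rlang::abort("targets must be integers in 1..K, one per column.")
  if (gamma < 0) rlang::abort("gamma must be >= 0.")
  a <- if (is.null(alpha)) rep(1, k) else alpha
  p <- softmax_cols(logits)
  ii <- matrix(c(targets, seq_len(b)), ncol = 2)   # (class, sample) pairs
  py <- pmax(p[ii], 1e-12)
  ay <- a[targets]
  loss <- mean(-ay * (1 - py)^gamma * log(py))
  # d/dp [-a (1-p)^g log p] = a g (1-p)^(g-1) log p - a (1-p)^g / p;
  # chained through softmax: dL/dz_j = w (delta_jy - p_j), w = dL/dp * p_y
  dLdpy <- if (gamma > 0) {
    ay * gamma * (1 - py)^(gamma - 1) * log(py) - ay * (1 - py)^gamma / py
  } else {
    -ay / py
  }
  w <- dLdpy * py / b
  grad <- -sweep(p, 2, w, `*`)
  grad[ii] <- grad[ii] + w
  list(loss = loss, grad = grad)
}

#' SMOTE oversampling
#'
#' Equalises every class count to the majority count by synthesising
#' minority rows `x_i + u (x_nn - x_i)` with `u ~ Uniform(0, 1)` and
#' `x_nn` one of the `k` nearest same-class neighbours of `x_i`
#' (Euclidean). Original rows are never modified; the result is
#' deterministic given `seed`.
#'
#' @param x numeric matrix, one feature row per sample.
#' @param y class labels (vector, length `nrow(x)`).
#' @param k neighbour count (capped at class size - 1).
#' @param seed integer seed.
#' @return List with `x` (original rows first, synthetic rows appended)
#'   and `y`.
#' @export
smote_oversample <- function(x, y, k = 5L, seed = 1L) {
  stopifnot(is.matrix(x), nrow(x) == length(y))
  counts <- table(y)
  target <- max(counts)
  if (all(counts == target)) return(list(x = x, y = y))
  withr::local_seed(as.integer(seed))
  new_x <- list(); new_y <- list()
  for (cls in names(counts)) {
    need <- target - counts[[cls]]
    if (need == 0) next
    idx <- which(y == cls)
    if (length(idx) < 2L)
      rlang::abort(paste0("class ", cls,
                          " has a single member; duplicate it before SMOTE."))
    xc <- x[idx, , drop = FALSE]
    dm <- as.matrix(stats::dist(xc))
    diag(dm) <- Inf
    kk <- min(k, length(idx) - 1L)
    nn <- apply(dm, 1, function(dr) order(dr)[seq_len(kk)])
    nn <- matrix(nn, nrow = kk)   # [k, n_c]
    base <- sample.int(length(idx), need, replace = TRUE)
    pick <- vapply(base, function(bi) nn[sample.int(kk, 1L), bi], integer(1))
    u <- stats::runif(need)
    synth <- xc[base, , drop = FALSE] +
      u * (xc[pick, , drop = FALSE] - xc[base, , drop = FALSE])
    new_x[[cls]] <- synth
    new_y[[cls]] <- rep(cls, need)
  }
  list(x = rbind(x, do.call(rbind, new_x)),
       y = c(y, unlist(new_y, use.names = FALSE)))
}

#' Stack channel tensors into a batched model input
#' @param tensors list of `[C, H, W]` arrays (see [to_channels()]).
#' @return Array `[C, H, W, N]`.
#' @export
stack_tensors <- function(tensors) {
  d <- dim(tensors[[1]])
  out <- array(0, dim = c(d, length(tensors)))
  for (i in seq_along(tensors)) out[, , , i] <- tensors[[i]]
  out
}

#' Fit the hybrid classifier
#'
#' Minibatch training with rectified Adam, the configured learning-rate
#' schedule, focal loss, and early stopping on validation loss with
#' best-weight restoration. All randomness (shuffling, dropout,
#' stochastic depth) derives from `config$seed`.
#'
#' @param model an `st_model` from [build_model()].
#' @param x_train,y_train training inputs `[C, H, W, N]` and integer
#'   labels in `1..K`.
#' @param x_val,y_val validation split (disjoint from training).
#' @param config a [train_config()].
#' @param verbose print one line per epoch.
#' @return List with `model` (best weights restored), `history` (a
#'   `fit_history` tibble: epoch, lr_scale, train_loss, val_loss,
#'   val_acc), `best_epoch`, and `stopped` (`"early"` or `"max_epochs"`).
#' @export
fit_model <- function(model, x_train, y_train, x_val, y_val,
                      config = train_config(), verbose = FALSE) {
  n <- dim(x_train)[4]
  if (n == 0 || length(y_val) == 0) rlang::abort("empty train or val split.")
  if (length(y_train) != n) rlang::abort("y_train length mismatch.")
  withr::local_seed(config$seed)
  opt <- radam_new(model$param_layers(), lr = config$lr,
                   weight_decay = config$weight_decay %||% 0)
  best_loss <- Inf; best_epoch <- 0L; best_snap <- NULL
  hist <- list(); stopped <- "max_epochs"
  for (epoch in seq_len(config$max_epochs)) {
    scale <- lr_schedule(config$scheduler, epoch)
    ord <- sample.int(n)
    tl <- 0; nb <- 0L
    for (start in seq(1L, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, n)]
      xb <- x_train[, , , idx, drop = FALSE]
      yb <- y_train[idx]
      model$zero_grads()
      z <- model$forward(xb, train = TRUE)
      fl <- focal_loss(z, yb, config$focal_gamma, config$focal_alpha)
      model$backward(fl$grad)
      radam_step(opt, scale)
      tl <- tl + fl$loss; nb <- nb + 1L
    }
    ev <- evaluate_split(model, x_val, y_val, config)
    hist[[epoch]] <- tibble::tibble(epoch = epoch, lr_scale = scale,
                                    train_loss = tl / nb,
                                    val_loss = ev$loss, val_acc = ev$acc)
    if (verbose)
      message(sprintf("epoch %3d  train %.4f  val %.4f  acc %.3f",
                      epoch, tl / nb, ev$loss, ev$acc))
    if (ev$loss < best_loss - 1e-12) {
      best_loss <- ev$loss; best_epoch <- epoch
      best_snap <- snapshot_weights(model)
    } else if (epoch - best_epoch >= config$patience) {
      stopped <- "early"
      break
    }
  }
  if (!is.null(best_snap)) restore_weights(model, best_snap)
  history <- dplyr::bind_rows(hist)
  class(history) <- c("fit_history", class(history))
  list(model = model, history = history, best_epoch = best_epoch,
       best_val_loss = best_loss, stopped = stopped)
}

evaluate_split <- function(model, x, y, config, batch_size = 64L) {
  n <- dim(x)[4]
  loss <- 0; correct <- 0L; nb <- 0L
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    z <- model$forward(x[, , , idx, drop = FALSE], train = FALSE)
    fl <- focal_loss(z, y[idx], config$focal_gamma, config$focal_alpha)
    loss <- loss + fl$loss * length(idx)
    correct <- correct + sum(apply(z, 2, which.max) == y[idx])
    nb <- nb + length(idx)
  }
  list(loss = loss / nb, acc = correct / nb)
}

#' Predict class indices
#'
#' Argmax of the logits per sample, ties broken toward the lower class
#' index; evaluation mode (deterministic).
#'
#' @param model an `st_model`.
#' @param x input array `[C, H, W, N]`.
#' @param batch_size evaluation batch size.
#' @return Integer vector of predicted classes in `1..K`.
#' @export
predict_model <- function(model, x, batch_size = 64L) {
  n <- dim(x)[4]
  out <- integer(n)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    z <- model$forward(x[, , , idx, drop = FALSE], train = FALSE)
    out[idx] <- apply(z, 2, which.max)
  }
  out
}

#' @describeIn fit_model tidy the epoch history (it already is tidy; the
#'   method exists so `tidy()` works uniformly).
#' @param x a `fit_history`.
#' @param ... unused.
#' @export
tidy.fit_history <- function(x, ...) tibble::as_tibble(unclass(x))

#' @export
autoplot.fit_history <- function(object, ...) {
  df <- tidyr::pivot_longer(tibble::as_tibble(unclass(object)),
                            cols = c("train_loss", "val_loss"),
                            names_to = "split", values_to = "loss")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                   colour = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::labs(title = "Training history", x = "epoch", y = "focal loss") +
    ggplot2::theme_minimal()
}
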