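# Native neural-network engine: sequence layers.
#
# Sequence tensors are arrays [d, T, B] (feature dim first so linear
# projections act on a [d, T*B] matrix view).

#' @noRd
nn_linear <- function(in_dim, out_dim) {
  ly <- new_layer("linear")
  ly$in_dim <- in_dim; ly$out_dim <- out_dim
  ly$params$w <- he_init(c(out_dim, in_dim), fan_in = in_dim)
  ly$params$b <- array(0, out_dim)
  ly$forward <- function(x, train = FALSE) {
    d <- dim(x) %||% c(length(x), 1L)
    xm <- x; dim(xm) <- c(d[1], prod(d[-1]))
    ly$cache <- list(xm = xm, d = d)
    y <- ly$params$w %*% xm + as.vector(ly$params$b)
    dim(y) <- c(ly$out_dim, d[-1])
    y
  }
  ly$backward <- function(dy) {
    ch <- ly$cache
    dym <- dy; dim(dym) <- c(ly$out_dim, prod(ch$d[-1]))
    ly$grads$w <- acc(ly$grads$w, tcrossprod(dym, ch$xm))
    ly$grads$b <- acc(ly$grads$b, rowSums(dym))
    dx <- crossprod(ly$params$w, dym)
    dim(dx) <- ch$d
    dx
  }
  ly
}

#' @noRd
nn_layernorm <- function(dim_feat, eps = 1e-5) {
  ly <- new_layer("layernorm")
  ly$eps <- eps; ly$dim_feat <- dim_feat
  ly$params$gamma <- array(1, dim_feat)
  ly$params$beta <- array(0, dim_feat)
  ly$forward <- function(x, train = FALSE) {
    d <- dim(x) %||% c(length(x), 1L)
    xm <- x; dim(xm) <- c(d[1], prod(d[-1]))
    mu <- colMeans(xm)
    xc <- sweep(xm, 2, mu)
    v <- colMeans(xc^2)
    istd <- 1 / sqrt(v + ly$eps)
    xhat <- sweep(xc, 2, istd, `*`)
    ly$cache <- list(xhat = xhat, istd = istd, d = d)
    y <- xhat * as.vector(ly$params$gamma) + as.vector(ly$params$beta)
    dim(y) <- d
    y
  }
  ly$backward <- function(dy) {
    ch <- ly$cache; d <- ch$d
    dym <- dy; dim(dym) <- c(d[1], prod(d[-1]))
    ly$grads$gamma <- acc(ly$grads$gamma, rowSums(dym * ch$xhat))
    ly$grads$beta <- acc(ly$grads$beta, rowSums(dym))
    dxhat <- dym * as.vector(ly$params$gamma)
    mean_dxhat <- colMeans(dxhat)
    mean_dxhat_xhat <- colMeans(dxhat * ch$xhat)
    dxm <- sweep(dxhat, 2, mean_dxhat) -
      sweep(ch$xhat, 2, mean_dxhat_xhat, `*`)
    dxm <- sweep(dxm, 2, ch$istd, `*`)
    dim(dxm) <- d
    dxm
  }
  ly
}

#' @noRd
nn_dropout <- function(p = 0.2) {
  ly <- new_layer("dropout")
  ly$p <- p
  ly$forward <- function(x, train = FALSE) {
    if (!train || ly$p <= 0) { ly$cache <- NULL; return(x) }
    mask <- (stats::runif(length(x)) >= ly$p) / (1 - ly$p)
    dim(mask) <- dim(x)
    ly$cache <- mask
    x * mask
  }
  ly$backward <- function(dy) if (is.null(ly$cache)) dy else dy * ly$cache
  ly
}

softmax_cols <- function(z) {
  mx <- z[cbind(max.col(t(z), ties.method = "first"), seq_len(ncol(z)))]
  e <- exp(sweep(z, 2, mx))
  sweep(e, 2, colSums(e), `/`)
}

# row-wise softmax without transposes (attention hot path)
softmax_rows <- function(z) {
  mx <- z[cbind(seq_len(nrow(z)), max.col(z, ties.method = "first"))]
  e <- exp(z - mx)
  e / rowSums(e)
}

#' @noRd
nn_mha <- function(d_model, n_heads, p_drop = 0.2) {
  if (d_model %% n_heads != 0L)
    rlang::abort("embed dim must be divisible by the head count.")
  ly <- new_layer("mha")
  ly$d <- d_model; ly$h <- n_heads; ly$dh <- d_model %/% n_heads
  ly$proj_q <- nn_linear(d_model, d_model)
  ly$proj_k <- nn_linear(d_model, d_model)
  ly$proj_v <- nn_linear(d_model, d_model)
  ly$proj_o <- nn_linear(d_model, d_model)
  ly$children <- list(ly$proj_q, ly$proj_k, ly$proj_v, ly$proj_o)
  ly$forward <- function(x, train = FALSE) {
    d <- dim(x)  # [d_model, T, B]
    tt <- d[2]; bb <- d[3]
    q <- ly$proj_q$forward(x, train)
    k <- ly$proj_k$forward(x, train)
    v <- ly$proj_v$forward(x, train)
    dim(q) <- dim(k) <- dim(v) <- c(ly$dh, ly$h, tt, bb)
    att <- array(0, dim = c(tt, tt, ly$h, bb))
    o <- array(0, dim = c(ly$dh, ly$h, tt, bb))
    for (b in seq_len(bb)) for (hh in seq_len(ly$h)) {
      qm <- matrix(q[, hh, , b], ly$dh); km <- matrix(k[, hh, , b], ly$dh)
      vm <- matrix(v[, hh, , b], ly$dh)
      sc <- crossprod(qm, km) / sqrt(ly$dh)       # [T, T]: rows query
      a <- softmax_rows(sc)                        # softmax over keys
      att[, , hh, b] <- a
      o[, hh, , b] <- tcrossprod(vm, a)
    }
    ly$cache <- list(q = q, k = k, v = v, att = att, tt = tt, bb = bb)
    dim(o) <- c(ly$d, tt, bb)
    ly$proj_o$forward(o, train)
  }
  ly$backward <- function(dy) {
    ch <- ly$cache
    do_ <- ly$proj_o$backward(dy)
    dim(do_) <- c(ly$dh, ly$h, ch$tt, ch$bb)
    dq <- array(0, dim = dim(ch$q)); dk <- dq; dv <- dq
    for (b in seq_len(ch$bb)) for (hh in seq_len(ly$h)) {
      a <- ch$att[, , hh, b]
      if (is.null(dim(a))) a <- matrix(a, ch$tt)
      qm <- matrix(ch$q[, hh, , b], ly$dh); km <- matrix(ch$k[, hh, , b], ly$dh)
      vm <- matrix(ch$v[, hh, , b], ly$dh)
      dom <- matrix(do_[, hh, , b], ly$dh)
      dv[, hh, , b] <- dom %*% a
      da <- crossprod(dom, vm)                     # [T_query, T_keys]
      # softmax backward per query row
      dsc <- a * (da - rowSums(da * a))
      dsc <- dsc / sqrt(ly$dh)
      dq[, hh, , b] <- tcrossprod(km, dsc)
      dk[, hh, , b] <- qm %*% dsc
    }
    dim(dq) <- dim(dk) <- dim(dv) <- c(ly$d, ch$tt, ch$bb)
    ly$proj_q$backward(dq) + ly$proj_k$backward(dk) + ly$proj_v$backward(dv)
  }
  ly
}

#' @noRd
nn_transformer_block <- function(d_model, n_heads, ffn_dim, p_drop = 0.2) {
  ly <- new_layer("transformer_block")
  ly$mha <- nn_mha(d_model, n_heads, p_drop)
  ly$drop1 <- nn_dropout(p_drop)
  ly$ln1 <- nn_layernorm(d_model)
  ly$ff1 <- nn_linear(d_model, ffn_dim)
  ly$ffrelu <- nn_relu()
  ly$dropff <- nn_dropout(p_drop)
  ly$ff2 <- nn_linear(ffn_dim, d_model)
  ly$drop2 <- nn_dropout(p_drop)
  ly$ln2 <- nn_layernorm(d_model)
  ly$children <- list(ly$mha, ly$drop1, ly$ln1, ly$ff1, ly$ffrelu,
                      ly$dropff, ly$ff2, ly$drop2, ly$ln2)
  ly$forward <- function(x, train = FALSE) {
    a <- ly$drop1$forward(ly$mha$forward(x, train), train)
    x1 <- ly$ln1$forward(x + a, train)
    f <- ly$ff2$forward(
      ly$dropff$forward(ly$ffrelu$forward(ly$ff1$forward(x1, train), train), train),
      train)
    ly$ln2$forward(x1 + ly$drop2$forward(f, train), train)
  }
  ly$backward <- function(dy) {
    d2 <- ly$ln2$backward(dy)
    df <- ly$drop2$backward(d2)
    dx1 <- d2 + ly$ff1$backward(
      ly$ffrelu$backward(ly$dropff$backward(ly$ff2$backward(df))))
    d1 <- ly$ln1$backward(dx1)
    da <- ly$drop1$backward(d1)
    d1 + ly$mha$backward(da)
  }
  ly
}

# learnable factorised 2-D positional encoding: one vector per frequency
# row plus one per time column, summed; sequence order is row-major with
# the column index varying fastest
#' @noRd
nn_posenc2d <- function(d_model, n_rows, n_cols) {
  ly <- new_layer("posenc2d")
  ly$nr <- n_rows; ly$nc <- n_cols; ly$d <- d_model
  ly$params$prow <- array(stats::rnorm(d_model * n_rows, 0, 0.02),
                          dim = c(d_model, n_rows))
  ly$params$pcol <- array(stats::rnorm(d_model * n_cols, 0, 0.02),
                          dim = c(d_model, n_cols))
  ly$forward <- function(x, train = FALSE) {
    d <- dim(x)   # [d, T = nr*nc, B]
    pe <- ly$params$prow[, rep(seq_len(ly$nr), each = ly$nc), drop = FALSE] +
          ly$params$pcol[, rep(seq_len(ly$nc), times = ly$nr), drop = FALSE]
    ly$cache <- d
    x + array(rep(pe, d[3]), dim = d)
  }
  ly$backward <- function(dy) {
    d <- ly$cache
    dpe <- dy
    dim(dpe) <- c(d[1], d[2] * d[3])
    # sum over batch, then fold T back to (row, col)
    dsum <- array(rowSums(array(dpe, dim = c(d[1] * d[2], d[3]))),
                  dim = c(d[1], ly$nc, ly$nr))
    ly$grads$pcol <- acc(ly$grads$pcol, apply(dsum, c(1, 2), sum))
    ly$grads$prow <- acc(ly$grads$prow, apply(dsum, c(1, 3), sum))
    dy
  }
  ly
}
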