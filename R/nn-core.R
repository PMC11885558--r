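# Native neural-network engine: convolutional layers.
#
# Feature maps are arrays [C, H, W, B] (channel first, so im2col and the
# conv matrix product need no transposition). Every layer is an
# environment with $params / $grads (named lists of arrays),
# $forward(x, train) and $backward(dy); backward accumulates parameter
# gradients and returns the input gradient. Heavy lifting is im2col +
# BLAS matrix products.

new_layer <- function(kind) {
  ly <- new.env(parent = emptyenv())
  ly$kind <- kind
  ly$params <- list()
  ly$grads <- list()
  ly
}

he_init <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), 0, sqrt(2 / fan_in)), dim = dims)
}

# "same"-style padding so out = ceil(in / stride)
same_pad <- function(n, k, s) {
  n <- as.integer(unname(n))
  out <- as.integer(ceiling(n / s))
  tot <- max((out - 1L) * s + k - n, 0L)
  list(beg = tot %/% 2L, end = tot - tot %/% 2L, out = out)
}

pad_hw <- function(x, pt, pb, pl, pr, fill = 0) {
  d <- dim(x)
  if (pt + pb + pl + pr == 0L) return(x)
  xp <- array(fill, dim = c(d[1], d[2] + pt + pb, d[3] + pl + pr, d[4]))
  xp[, (pt + 1L):(pt + d[2]), (pl + 1L):(pl + d[3]), ] <- x
  xp
}

# im2col (compiled): lowers the padded map [C, Hp, Wp, B] to the matrix
# [C*k^2, outH*outW*B], rows ordered channel-fastest within each tap
im2col <- function(xp, k, s, out_h, out_w) {
  d <- dim(xp)
  im2col_cpp(xp, d[1], d[2], d[3], d[4], k, s, out_h, out_w)
}

# adjoint of im2col: scatter-add columns back into the padded input
col2im <- function(dm, dpad_dim, k, s, out_h, out_w) {
  out <- col2im_cpp(dm, dpad_dim[1], dpad_dim[2], dpad_dim[3], dpad_dim[4],
                    k, s, out_h, out_w)
  dim(out) <- dpad_dim
  out
}

#' @noRd
nn_conv2d <- function(in_ch, out_ch, k = 3L, stride = 1L, groups = 1L,
                      bias = TRUE, input_grad = TRUE) {
  if (in_ch %% groups != 0L || out_ch %% groups != 0L)
    rlang::abort("channel counts must be divisible by the group count.")
  ly <- new_layer("conv2d")
  ly$k <- as.integer(k); ly$s <- as.integer(stride); ly$g <- as.integer(groups)
  ly$in_ch <- in_ch; ly$out_ch <- out_ch
  ly$input_grad <- input_grad
  cg <- in_ch %/% groups
  # weight stored [Cg*k^2, out_ch]: column j = filter for output channel j,
  # rows ordered (channel within group) fastest, kernel tap slowest
  ly$params$w <- he_init(c(cg * k * k, out_ch), fan_in = cg * k * k)
  if (bias) ly$params$b <- array(0, out_ch)
  ly$group_rows <- if (groups > 1L)
    lapply(seq_len(groups), function(gi)
      as.vector(outer(((gi - 1L) * cg + 1L):(gi * cg),
                      (0:(k * k - 1L)) * in_ch, `+`)))
  ly$forward <- function(x, train = FALSE) {
    d <- dim(x)
    ph <- same_pad(d[2], ly$k, ly$s); pw <- same_pad(d[3], ly$k, ly$s)
    xp <- pad_hw(x, ph$beg, ph$end, pw$beg, pw$end)
    m <- im2col(xp, ly$k, ly$s, ph$out, pw$out)
    if (ly$g == 1L) {
      y <- crossprod(ly$params$w, m)
    } else {
      og <- ly$out_ch %/% ly$g
      y <- matrix(0, ly$out_ch, ncol(m))
      for (gi in seq_len(ly$g)) {
        oc <- ((gi - 1L) * og + 1L):(gi * og)
        y[oc, ] <- crossprod(ly$params$w[, oc, drop = FALSE],
                             m[ly$group_rows[[gi]], , drop = FALSE])
      }
    }
    if (!is.null(ly$params$b)) y <- y + as.vector(ly$params$b)
    ly$cache <- list(m = m, dimx = d, ph = ph, pw = pw)
    dim(y) <- c(ly$out_ch, ph$out, pw$out, d[4])
    y
  }
  ly$backward <- function(dy) {
    ch <- ly$cache
    dmat <- dy
    dim(dmat) <- c(ly$out_ch, ch$ph$out * ch$pw$out * ch$dimx[4])
    if (!is.null(ly$params$b))
      ly$grads$b <- acc(ly$grads$b, rowSums(dmat))
    if (ly$g == 1L) {
      ly$grads$w <- acc(ly$grads$w, tcrossprod(ch$m, dmat))
      if (!ly$input_grad) return(NULL)
      dm <- ly$params$w %*% dmat
    } else {
      og <- ly$out_ch %/% ly$g
      dw <- if (is.null(ly$grads$w)) array(0, dim(ly$params$w)) else ly$grads$w
      dm <- if (ly$input_grad) matrix(0, nrow(ch$m), ncol(ch$m))
      for (gi in seq_len(ly$g)) {
        rows <- ly$group_rows[[gi]]
        oc <- ((gi - 1L) * og + 1L):(gi * og)
        dw[, oc] <- dw[, oc, drop = FALSE] +
          tcrossprod(ch$m[rows, , drop = FALSE], dmat[oc, , drop = FALSE])
        if (ly$input_grad)
          dm[rows, ] <- ly$params$w[, oc, drop = FALSE] %*% dmat[oc, , drop = FALSE]
      }
      ly$grads$w <- dw
      if (!ly$input_grad) return(NULL)
    }
    dpad <- col2im(dm, c(ch$dimx[1],
                         ch$dimx[2] + ch$ph$beg + ch$ph$end,
                         ch$dimx[3] + ch$pw$beg + ch$pw$end,
                         ch$dimx[4]),
                   ly$k, ly$s, ch$ph$out, ch$pw$out)
    dpad[, (ch$ph$beg + 1L):(ch$ph$beg + ch$dimx[2]),
         (ch$pw$beg + 1L):(ch$pw$beg + ch$dimx[3]), , drop = FALSE]
  }
  ly
}

acc <- function(g, delta) if (is.null(g)) delta else g + delta

#' @noRd
nn_batchnorm2d <- function(ch, eps = 1e-5, momentum = 0.1) {
  ly <- new_layer("batchnorm2d")
  ly$eps <- eps; ly$momentum <- momentum; ly$ch <- ch
  ly$params$gamma <- array(1, ch)
  ly$params$beta <- array(0, ch)
  ly$running_mean <- rep(0, ch)
  ly$running_var <- rep(1, ch)
  ly$forward <- function(x, train = FALSE) {
    d <- dim(x)
    xm <- x
    dim(xm) <- c(d[1], prod(d[-1]))
    if (train) {
      mu <- rowMeans(xm)
      xc <- xm - mu
      v <- rowMeans(xc^2)
      ly$running_mean <- (1 - ly$momentum) * ly$running_mean + ly$momentum * mu
      n <- ncol(xm)
      ly$running_var <- (1 - ly$momentum) * ly$running_var +
        ly$momentum * v * n / max(n - 1, 1)
    } else {
      mu <- ly$running_mean
      v <- ly$running_var
      xc <- xm - mu
    }
    istd <- 1 / sqrt(v + ly$eps)
    xhat <- xc * istd
    y <- xhat * as.vector(ly$params$gamma) + as.vector(ly$params$beta)
    ly$cache <- list(xhat = if (train) xhat else NULL, istd = istd, d = d,
                     train = train)
    dim(y) <- d
    y
  }
  ly$backward <- function(dy) {
    ch_ <- ly$cache; d <- ch_$d
    dym <- dy
    dim(dym) <- c(d[1], prod(d[-1]))
    if (!ch_$train) {
      dxm <- dym * (as.vector(ly$params$gamma) * ch_$istd)
    } else {
      xhat <- ch_$xhat
      ly$grads$gamma <- acc(ly$grads$gamma, rowSums(dym * xhat))
      ly$grads$beta <- acc(ly$grads$beta, rowSums(dym))
      dxhat <- dym * as.vector(ly$params$gamma)
      dxm <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) *
        ch_$istd
    }
    dim(dxm) <- d
    dxm
  }
  ly
}

#' @noRd
nn_relu <- function() {
  ly <- new_layer("relu")
  ly$forward <- function(x, train = FALSE) {
    ly$cache <- x > 0
    x * ly$cache
  }
  ly$backward <- function(dy) dy * ly$cache
  ly
}

#' @noRd
nn_maxpool2d <- function(k = 3L, stride = 2L) {
  ly <- new_layer("maxpool2d")
  ly$k <- as.integer(k); ly$s <- as.integer(stride)
  ly$forward <- function(x, train = FALSE) {
    d <- dim(x)
    ph <- same_pad(d[2], ly$k, ly$s); pw <- same_pad(d[3], ly$k, ly$s)
    xp <- pad_hw(x, ph$beg, ph$end, pw$beg, pw$end, fill = -Inf)
    dp <- dim(xp)
    res <- maxpool_fwd_cpp(xp, dp[1], dp[2], dp[3], dp[4], ly$k, ly$s,
                           ph$out, pw$out)
    best <- res$best
    dim(best) <- c(d[1], ph$out, pw$out, d[4])
    ly$cache <- list(arg = res$arg, d = d, dp = dp, ph = ph, pw = pw)
    best
  }
  ly$backward <- function(dy) {
    ch <- ly$cache
    dpad <- maxpool_bwd_cpp(dy, ch$arg, ch$dp[1], ch$dp[2], ch$dp[3],
                            ch$dp[4], ly$k, ly$s, ch$ph$out, ch$pw$out)
    dim(dpad) <- ch$dp
    dpad[, (ch$ph$beg + 1L):(ch$ph$beg + ch$d[2]),
         (ch$pw$beg + 1L):(ch$pw$beg + ch$d[3]), , drop = FALSE]
  }
  ly
}

#' @noRd
nn_se_block <- function(ch, reduction = 16L) {
  ly <- new_layer("se")
  cr <- max(1L, ch %/% reduction)
  ly$ch <- ch; ly$cr <- cr
  ly$params$w1 <- he_init(c(cr, ch), fan_in = ch)
  ly$params$b1 <- array(0, cr)
  ly$params$w2 <- he_init(c(ch, cr), fan_in = cr)
  ly$params$b2 <- array(0, ch)
  ly$forward <- function(x, train = FALSE) {
    d <- dim(x)
    hw <- d[2] * d[3]
    # squeeze: per-(channel, sample) spatial mean
    s <- matrix(0, d[1], d[4])
    xm2 <- x; dim(xm2) <- c(d[1], hw, d[4])
    for (b in seq_len(d[4])) s[, b] <- rowMeans(xm2[, , b, drop = FALSE], dims = 1)
    z1 <- ly$params$w1 %*% s + as.vector(ly$params$b1)
    r <- z1 * (z1 > 0)
    z2 <- ly$params$w2 %*% r + as.vector(ly$params$b2)
    g <- 1 / (1 + exp(-z2))                        # excitation gate [C, B]
    garr <- array(0, dim = d)
    gm <- garr; dim(gm) <- c(d[1], hw, d[4])
    for (b in seq_len(d[4])) gm[, , b] <- g[, b]
    dim(gm) <- d
    ly$cache <- list(x = x, s = s, z1 = z1, r = r, g = g, garr = gm, d = d)
    x * gm
  }
  ly$backward <- function(dy) {
    ch_ <- ly$cache; d <- ch_$d
    hw <- d[2] * d[3]
    dgm <- dy * ch_$x
    dim(dgm) <- c(d[1], hw, d[4])
    dg <- matrix(0, d[1], d[4])
    for (b in seq_len(d[4])) dg[, b] <- rowSums(dgm[, , b, drop = FALSE], dims = 1)
    dz2 <- dg * ch_$g * (1 - ch_$g)
    ly$grads$w2 <- acc(ly$grads$w2, tcrossprod(dz2, ch_$r))
    ly$grads$b2 <- acc(ly$grads$b2, rowSums(dz2))
    dr <- crossprod(ly$params$w2, dz2)
    dz1 <- dr * (ch_$z1 > 0)
    ly$grads$w1 <- acc(ly$grads$w1, tcrossprod(dz1, ch_$s))
    ly$grads$b1 <- acc(ly$grads$b1, rowSums(dz1))
    ds <- crossprod(ly$params$w1, dz1) / hw
    dsm <- array(0, dim = c(d[1], hw, d[4]))
    for (b in seq_len(d[4])) dsm[, , b] <- ds[, b]
    dim(dsm) <- d
    dy * ch_$garr + dsm
  }
  ly
}
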