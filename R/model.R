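# Hybrid ResNeXt-SE + Transformer classifier.

#' Model configuration
#'
#' The default configuration is the full-size hybrid network: a 7x7/2
#' convolutional stem to 64 channels with 3x3/2 max-pooling, four stages
#' of two ResNeXt bottleneck blocks (widths 64/128/256/512, stages 2-4
#' downsampling by stride 2, cardinality 32, squeeze-and-excitation
#' reduction 16, stochastic depth 0.2), a 1x1 channel-mixing
#' convolution, learnable factorised 2-D positional encoding, four
#' post-norm Transformer encoder blocks (8 heads, feed-forward 2048,
#' dropout 0.2), a global residual skip around the encoder, mean pooling
#' over the sequence and a Linear-LayerNorm-Linear head.
#'
#' All sizes are configurable so that desk-scale studies can train a
#' narrower instance of the same topology.
#'
#' @param in_channels input channels (2: real and imaginary S-transform
#'   parts).
#' @param stem_channels stem output channels.
#' @param stage_widths output width of each of the 4 stages.
#' @param blocks_per_stage ResNeXt blocks per stage.
#' @param cardinality grouped-convolution group count.
#' @param se_reduction squeeze-and-excitation reduction ratio.
#' @param stochastic_depth_p residual-branch drop probability.
#' @param embed_dim Transformer embedding dim (must equal the last stage
#'   width and be divisible by `n_heads`).
#' @param n_transformer_blocks,n_heads,ffn_dim,dropout Transformer
#'   geometry and dropout.
#' @param head_hidden hidden width of the classification head.
#' @param n_classes output classes (5 for N/S/V/F/Q, 4 for N/S/V/Q).
#' @return A `model_config` list.
#' @export
model_config <- function(in_channels = 2L, stem_channels = 64L,
                         stage_widths = c(64L, 128L, 256L, 512L),
                         blocks_per_stage = 2L, cardinality = 32L,
                         se_reduction = 16L, stochastic_depth_p = 0.2,
                         embed_dim = 512L, n_transformer_blocks = 4L,
                         n_heads = 8L, ffn_dim = 2048L, dropout = 0.2,
                         head_hidden = 256L, n_classes = 5L) {
  cfg <- list(in_channels = as.integer(in_channels),
              stem_channels = as.integer(stem_channels),
              stage_widths = as.integer(stage_widths),
              blocks_per_stage = as.integer(blocks_per_stage),
              cardinality = as.integer(cardinality),
              se_reduction = as.integer(se_reduction),
              stochastic_depth_p = stochastic_depth_p,
              embed_dim = as.integer(embed_dim),
              n_transformer_blocks = as.integer(n_transformer_blocks),
              n_heads = as.integer(n_heads), ffn_dim = as.integer(ffn_dim),
              dropout = dropout, head_hidden = as.integer(head_hidden),
              n_classes = as.integer(n_classes))
  if (length(cfg$stage_widths) != 4L)
    rlang::abort("stage_widths must have length 4.")
  if (cfg$embed_dim != cfg$stage_widths[4])
    rlang::abort("embed_dim must equal the final stage width.")
  if (cfg$embed_dim %% cfg$n_heads != 0L)
    rlang::abort("embed_dim must be divisible by n_heads.")
  for (w in cfg$stage_widths)
    if ((w %/% 2L) %% cfg$cardinality != 0L)
      rlang::abort(sprintf(
        "bottleneck width %d is not divisible by cardinality %d.",
        w %/% 2L, cfg$cardinality))
  structure(cfg, class = "model_config")
}

#' A narrow instance of the hybrid topology for desk-scale training
#'
#' Same structure as [model_config()] — stem, 4 x 2 SE-ResNeXt blocks,
#' 1x1 mix, positional encoding, 4 Transformer blocks, global skip, mean
#' pooling, 2-layer head — with reduced widths so CPU training of a few
#' hundred segments completes in minutes.
#' @param n_classes output classes.
#' @export
model_config_small <- function(n_classes = 4L) {
  model_config(stem_channels = 8L, stage_widths = c(8L, 16L, 32L, 64L),
               cardinality = 4L, se_reduction = 4L, embed_dim = 64L,
               n_heads = 8L, ffn_dim = 128L, head_hidden = 32L,
               n_classes = n_classes)
}

# one SE-ResNeXt bottleneck block (1x1 down -> grouped 3x3 -> 1x1 up ->
# SE -> stochastic depth -> identity add -> relu)
nn_resnext_block <- function(in_planes, out_planes, stride, cardinality,
                             se_reduction, drop_prob) {
  gw <- out_planes %/% 2L     # bottleneck (grouped) width
  ly <- new_layer("resnext_block")
  ly$drop_prob <- drop_prob
  ly$conv1 <- nn_conv2d(in_planes, gw, k = 1L, bias = FALSE)
  ly$bn1 <- nn_batchnorm2d(gw)
  ly$relu1 <- nn_relu()
  ly$conv2 <- nn_conv2d(gw, gw, k = 3L, stride = stride,
                        groups = cardinality, bias = FALSE)
  ly$bn2 <- nn_batchnorm2d(gw)
  ly$relu2 <- nn_relu()
  ly$conv3 <- nn_conv2d(gw, out_planes, k = 1L, bias = FALSE)
  ly$bn3 <- nn_batchnorm2d(out_planes)
  ly$se <- nn_se_block(out_planes, se_reduction)
  ly$project <- stride != 1L || in_planes != out_planes
  if (ly$project) {
    ly$convp <- nn_conv2d(in_planes, out_planes, k = 1L, stride = stride,
                          bias = FALSE)
    ly$bnp <- nn_batchnorm2d(out_planes)
  }
  ly$relu_out <- nn_relu()
  ly$children <- c(list(ly$conv1, ly$bn1, ly$relu1, ly$conv2, ly$bn2,
                        ly$relu2, ly$conv3, ly$bn3, ly$se, ly$relu_out),
                   if (ly$project) list(ly$convp, ly$bnp))
  ly$forward <- function(x, train = FALSE) {
    br <- ly$relu1$forward(ly$bn1$forward(ly$conv1$forward(x, train), train), train)
    br <- ly$relu2$forward(ly$bn2$forward(ly$conv2$forward(br, train), train), train)
    br <- ly$bn3$forward(ly$conv3$forward(br, train), train)
    br <- ly$se$forward(br, train)
    idn <- if (ly$project)
      ly$bnp$forward(ly$convp$forward(x, train), train) else x
    if (train && ly$drop_prob > 0) {
      bsz <- dim(br)[4]
      keep <- stats::runif(bsz) >= ly$drop_prob
      scale <- as.numeric(keep) / (1 - ly$drop_prob)
      ly$sd_scale <- scale
      br <- br * rep(scale, each = prod(dim(br)[1:3]))
    } else ly$sd_scale <- NULL
    ly$relu_out$forward(idn + br, train)
  }
  ly$backward <- function(dy) {
    ds <- ly$relu_out$backward(dy)
    dbr <- ds
    if (!is.null(ly$sd_scale))
      dbr <- dbr * rep(ly$sd_scale, each = prod(dim(dbr)[1:3]))
    dbr <- ly$se$backward(dbr)
    dbr <- ly$conv3$backward(ly$bn3$backward(dbr))
    dbr <- ly$conv2$backward(ly$bn2$backward(ly$relu2$backward(dbr)))
    dbr <- ly$conv1$backward(ly$bn1$backward(ly$relu1$backward(dbr)))
    didn <- if (ly$project) ly$convp$backward(ly$bnp$backward(ds)) else ds
    dbr + didn
  }
  ly
}

collect_param_layers <- function(ly) {
  out <- list()
  if (length(ly$params)) out <- list(ly)
  for (ch in ly$children %||% list())
    out <- c(out, collect_param_layers(ch))
  out
}

#' Build the hybrid classifier
#'
#' Constructs the full module graph of the configuration: stem, four
#' ResNeXt-SE stages, 1x1 mixing convolution, sequence reshape with
#' learnable 2-D positional encoding, Transformer encoder with a global
#' residual skip, mean pooling and the classification head. Parameter
#' initialisation is He-normal and fully determined by `seed`.
#'
#' @param config a [model_config()].
#' @param seed integer seed for weight initialisation.
#' @return An `st_model` environment with `$forward(x, train)`,
#'   `$backward(dlogits)`, `$config` and parameter access helpers.
#' @export
build_model <- function(config = model_config(), seed = 1L) {
  stopifnot(inherits(config, "model_config"))
  withr::local_seed(as.integer(seed))
  md <- new_layer("st_model")
  md$config <- config
  md$stem_conv <- nn_conv2d(config$in_channels, config$stem_channels,
                            k = 7L, stride = 2L, bias = FALSE,
                            input_grad = FALSE)
  md$stem_bn <- nn_batchnorm2d(config$stem_channels)
  md$stem_relu <- nn_relu()
  md$stem_pool <- nn_maxpool2d(3L, 2L)
  widths <- config$stage_widths
  ins <- c(config$stem_channels, widths[-4])
  md$stages <- list()
  for (st in 1:4) {
    blocks <- list()
    for (bi in seq_len(config$blocks_per_stage)) {
      in_p <- if (bi == 1L) ins[st] else widths[st]
      stride <- if (bi == 1L && st > 1L) 2L else 1L
      blocks[[bi]] <- nn_resnext_block(in_p, widths[st], stride,
                                       config$cardinality,
                                       config$se_reduction,
                                       config$stochastic_depth_p)
    }
    md$stages[[st]] <- blocks
  }
  md$mix <- nn_conv2d(widths[4], config$embed_dim, k = 1L, bias = TRUE)
  md$posenc <- NULL   # lazily sized on the first forward
  md$tblocks <- lapply(seq_len(config$n_transformer_blocks), function(i)
    nn_transformer_block(config$embed_dim, config$n_heads, config$ffn_dim,
                         config$dropout))
  md$head_fc1 <- nn_linear(config$embed_dim, config$head_hidden)
  md$head_ln <- nn_layernorm(config$head_hidden)
  md$head_fc2 <- nn_linear(config$head_hidden, config$n_classes)
  md$posenc_seed <- as.integer(seed) + 7919L
  md$children <- c(list(md$stem_conv, md$stem_bn, md$stem_relu, md$stem_pool),
                   unlist(md$stages, recursive = FALSE),
                   list(md$mix), md$tblocks,
                   list(md$head_fc1, md$head_ln, md$head_fc2))

  md$feature_extract <- function(x, train = FALSE) {
    if (dim(x)[1] != md$config$in_channels)
      rlang::abort("input channel count does not match the model config.")
    h <- md$stem_pool$forward(
      md$stem_relu$forward(md$stem_bn$forward(md$stem_conv$forward(x, train), train), train))
    for (st in md$stages) for (bl in st) h <- bl$forward(h, train)
    md$mix$forward(h, train)
  }
  md$feature_backward <- function(dh) {
    dh <- md$mix$backward(dh)
    for (st in rev(md$stages)) for (bl in rev(st)) dh <- bl$backward(dh)
    md$stem_conv$backward(md$stem_bn$backward(md$stem_relu$backward(
      md$stem_pool$backward(dh))))
  }

  md$encode <- function(f, train = FALSE) {
    d <- dim(f)   # [C, H', W', B]
    if (d[1] != md$config$embed_dim)
      rlang::abort("feature map channel count must equal embed_dim.")
    if (is.null(md$posenc) || md$posenc$nr != d[2] || md$posenc$nc != d[3]) {
      withr::with_seed(md$posenc_seed, {
        md$posenc <- nn_posenc2d(md$config$embed_dim, d[2], d[3])
      })
      md$children <- c(md$children, list(md$posenc))
    }
    # frequency-row-major flattening: t = (row - 1) * W' + col
    s <- aperm(f, c(1, 3, 2, 4))
    dim(s) <- c(d[1], d[3] * d[2], d[4])
    s <- md$posenc$forward(s, train)
    md$enc_dim <- d
    h <- s
    for (tb in md$tblocks) h <- tb$forward(h, train)
    h <- h + s          # global residual skip around the encoder
    md$enc_t <- dim(h)[2]
    dd <- dim(h)
    pool <- matrix(0, dd[1], dd[3])
    for (b in seq_len(dd[3]))
      pool[, b] <- rowMeans(matrix(h[, , b], dd[1]))  # mean over T
    pool
  }
  md$encode_backward <- function(dpool) {
    d <- md$enc_dim
    tt <- md$enc_t
    dh <- array(dpool / tt, dim = c(d[1], 1, dim(dpool)[2]))
    dh <- dh[, rep(1, tt), , drop = FALSE]
    ds_skip <- dh
    for (tb in rev(md$tblocks)) dh <- tb$backward(dh)
    dh <- dh + ds_skip
    dh <- md$posenc$backward(dh)
    dim(dh) <- c(d[1], d[3], d[2], dim(dpool)[2])
    aperm(dh, c(1, 3, 2, 4))
  }

  md$forward <- function(x, train = FALSE) {
    f <- md$feature_extract(x, train)
    p <- md$encode(f, train)
    z <- md$head_fc2$forward(md$head_ln$forward(md$head_fc1$forward(p, train), train), train)
    z   # logits [n_classes, B]
  }
  md$backward <- function(dz) {
    dp <- md$head_fc1$backward(md$head_ln$backward(md$head_fc2$backward(dz)))
    df <- md$encode_backward(dp)
    md$feature_backward(df)
  }

  md$param_layers <- function() collect_param_layers(md)
  md$zero_grads <- function() {
    for (ly in md$param_layers()) ly$grads <- list()
  }
  class(md) <- c("st_model", "environment")
  md
}

#' Total trainable parameter count of a model
#' @param model an `st_model`.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$param_layers(),
             function(ly) sum(vapply(ly$params, length, integer(1))), numeric(1)))
}

#' Snapshot all parameters (and batch-norm running statistics)
#' @param model an `st_model`.
#' @return An opaque list restorable with [restore_weights()].
#' @export
snapshot_weights <- function(model) {
  lapply(model$param_layers(), function(ly)
    list(params = ly$params,
         running = if (ly$kind == "batchnorm2d")
           list(mean = ly$running_mean, var = ly$running_var)))
}

#' Restore parameters saved by [snapshot_weights()]
#' @param model an `st_model`.
#' @param snap a snapshot list.
#' @export
restore_weights <- function(model, snap) {
  lys <- model$param_layers()
  stopifnot(length(lys) == length(snap))
  for (i in seq_along(lys)) {
    lys[[i]]$params <- snap[[i]]$params
    if (!is.null(snap[[i]]$running)) {
      lys[[i]]$running_mean <- snap[[i]]$running$mean
      lys[[i]]$running_var <- snap[[i]]$running$var
    }
  }
  invisible(model)
}

#' @export
print.st_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<st_model> stem %d -> stages [%s] x%d blocks, cardinality %d, SE 1/%d\n",
    cfg$stem_channels, paste(cfg$stage_widths, collapse = ", "),
    cfg$blocks_per_stage, cfg$cardinality, cfg$se_reduction))
  cat(sprintf("  transformer: %d blocks, %d heads, ffn %d, dropout %.2f\n",
              cfg$n_transformer_blocks, cfg$n_heads, cfg$ffn_dim, cfg$dropout))
  cat(sprintf("  head: %d -> %d -> %d classes; %s parameters\n",
              cfg$embed_dim, cfg$head_hidden, cfg$n_classes,
              format(n_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Forward pass to logits
#'
#' @param model an `st_model`.
#' @param x input array: `[C, H, W, B]`, or `[C, H, W]` (a single
#'   [to_channels()] tensor, promoted to batch 1).
#' @param train logical; enables dropout, stochastic depth and
#'   batch-statistics normalisation.
#' @return Logits matrix `[n_classes, B]`.
#' @export
model_forward <- function(model, x, train = FALSE) {
  if (length(dim(x)) == 3L && dim(x)[1] == model$config$in_channels)
    x <- array(x, dim = c(dim(x), 1L))
  model$forward(x, train)
}
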