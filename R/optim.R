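# Rectified Adam and learning-rate schedules.

#' @noRd
radam_new <- function(layers, lr = 3e-4, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 0) {
  opt <- new.env(parent = emptyenv())
  opt$layers <- layers
  opt$lr <- lr; opt$beta1 <- beta1; opt$beta2 <- beta2; opt$eps <- eps
  opt$weight_decay <- weight_decay
  opt$t <- 0L
  opt$state <- lapply(layers, function(ly)
    lapply(ly$params, function(p) list(m = array(0, dim(p) %||% length(p)),
                                       v = array(0, dim(p) %||% length(p)))))
  opt
}

# one RAdam update over every accumulated gradient; lr_scale multiplies
# the base learning rate (scheduler hook)
radam_step <- function(opt, lr_scale = 1) {
  opt$t <- opt$t + 1L
  b1 <- opt$beta1; b2 <- opt$beta2; t <- opt$t
  rho_inf <- 2 / (1 - b2) - 1
  rho_t <- rho_inf - 2 * t * b2^t / (1 - b2^t)
  lr <- opt$lr * lr_scale
  for (i in seq_along(opt$layers)) {
    ly <- opt$layers[[i]]
    for (nm in names(ly$params)) {
      g <- ly$grads[[nm]]
      if (is.null(g)) next
      if (opt$weight_decay > 0) g <- g + opt$weight_decay * ly$params[[nm]]
      st <- opt$state[[i]][[nm]]
      st$m <- b1 * st$m + (1 - b1) * g
      st$v <- b2 * st$v + (1 - b2) * g^2
      mhat <- st$m / (1 - b1^t)
      if (rho_t > 5) {
        # variance-rectified adaptive step
        rt <- sqrt(((rho_t - 4) * (rho_t - 2) * rho_inf) /
                     ((rho_inf - 4) * (rho_inf - 2) * rho_t))
        vhat <- sqrt(st$v / (1 - b2^t))
        upd <- lr * rt * mhat / (vhat + opt$eps)
      } else {
        upd <- lr * mhat    # un-adapted (SGD-with-momentum-like) step
      }
      ly$params[[nm]] <- ly$params[[nm]] - upd
      opt$state[[i]][[nm]] <- st
    }
  }
  invisible(opt)
}

#' Learning-rate schedule factor
#'
#' Returns the multiplier applied to the base learning rate at a given
#' (1-based) epoch. `"cosine_warm_restarts"` implements cosine annealing
#' with warm restarts (initial period `t0`, period multiplier `t_mult`);
#' `"exponential"` decays by `gamma` per epoch; `"none"` is constant 1.
#'
#' @param scheduler one of `"cosine_warm_restarts"`, `"exponential"`,
#'   `"none"`.
#' @param epoch 1-based epoch index.
#' @param t0,t_mult,gamma,eta_min schedule parameters.
#' @export
lr_schedule <- function(scheduler, epoch, t0 = 10, t_mult = 2,
                        gamma = 0.98, eta_min = 0) {
  switch(scheduler,
    none = 1,
    exponential = gamma^(epoch - 1),
    cosine_warm_restarts = {
      e <- epoch - 1
      ti <- t0
      while (e >= ti) { e <- e - ti; ti <- ti * t_mult }
      eta_min + (1 - eta_min) * (1 + cos(pi * e / ti)) / 2
    },
    rlang::abort(paste0("unknown scheduler: ", scheduler)))
}
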