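# AdamW with decoupled weight decay, plus the learning-rate schedules used
# in pretraining (cosine annealing) and fine-tuning (reduce-on-plateau).

adamw_init <- function(params, lr = 3e-4, weight_decay = 1e-4,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  list(lr = lr, weight_decay = weight_decay, beta1 = beta1, beta2 = beta2,
       eps = eps, t = 0L,
       m = map_leaves(params, function(p) p * 0),
       v = map_leaves(params, function(p) p * 0))
}

# One AdamW update. `decay_mask` (optional tree of 0/1) switches weight decay
# off for parameters such as batch-norm scales and biases.
adamw_step <- function(opt, params, grads) {
  opt$t <- opt$t + 1L
  b1 <- opt$beta1; b2 <- opt$beta2
  bc1 <- 1 - b1^opt$t
  bc2 <- 1 - b2^opt$t
  opt$m <- map2_leaves(opt$m, grads, function(m, g) b1 * m + (1 - b1) * g)
  opt$v <- map2_leaves(opt$v, grads, function(v, g) b2 * v + (1 - b2) * g^2)
  lr <- opt$lr
  new_params <- params
  upd <- function(p, m, v) {
    p - lr * ((m / bc1) / (sqrt(v / bc2) + opt$eps) + opt$weight_decay * p)
  }
  # three-way map: walk params with (m, v) zipped
  walk <- function(p, m, v) {
    if (is.list(p)) {
      out <- p
      for (nm in names(p)) out[[nm]] <- walk(p[[nm]], m[[nm]], v[[nm]])
      out
    } else if (is.null(p)) NULL else upd(p, m, v)
  }
  list(opt = opt, params = walk(params, opt$m, opt$v))
}

#' Cosine annealing learning rate
#'
#' Standard cosine decay from `lr_max` to `lr_min` over `horizon` epochs;
#' epochs beyond the horizon stay at `lr_min`.
#'
#' @param epoch 1-based epoch index.
#' @param lr_max Initial learning rate.
#' @param horizon Number of epochs over which the rate anneals.
#' @param lr_min Floor learning rate (default 0).
#' @return The learning rate for `epoch`.
#' @export
cosine_lr <- function(epoch, lr_max, horizon, lr_min = 0) {
  if (epoch >= horizon) return(lr_min)
  lr_min + 0.5 * (lr_max - lr_min) * (1 + cos(pi * (epoch - 1) / horizon))
}

# Reduce-on-plateau tracker for a maximized quantity (validation accuracy).
plateau_init <- function(lr, factor = 0.5, patience = 3L) {
  list(lr = lr, factor = factor, patience = as.integer(patience),
       best = -Inf, wait = 0L)
}

plateau_step <- function(sched, metric) {
  if (metric > sched$best + 1e-12) {
    sched$best <- metric
    sched$wait <- 0L
  } else {
    sched$wait <- sched$wait + 1L
    if (sched$wait >= sched$patience) {
      sched$lr <- sched$lr * sched$factor
      sched$wait <- 0L
    }
  }
  sched
}
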