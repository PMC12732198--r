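# Minimal neural-network layer system used by the encoder and all heads.
#
# An architecture ("arch") is a nested list of layer specs; parameters and
# batch-norm running statistics live in separate nested lists mirroring the
# arch, so forward/backward are pure functions of (arch, params, state).
# 4-d activations use the (H, W, C, N) array convention of the C++ kernels;
# vector activations are (N, C) matrices.

nn_conv <- function(in_ch, out_ch, k, stride = 1L, pad = 0L, bias = TRUE) {
  list(type = "conv", in_ch = in_ch, out_ch = out_ch, k = as.integer(k),
       stride = as.integer(stride), pad = as.integer(pad), bias = bias)
}
nn_bn2d <- function(ch) list(type = "bn2d", ch = ch)
nn_bn1d <- function(ch) list(type = "bn1d", ch = ch)
nn_relu <- function() list(type = "relu")
nn_maxpool <- function(k, stride, pad) {
  list(type = "maxpool", k = as.integer(k), stride = as.integer(stride),
       pad = as.integer(pad))
}
nn_linear <- function(in_ch, out_ch) list(type = "linear", in_ch = in_ch, out_ch = out_ch)
nn_dropout <- function(p) list(type = "dropout", p = p)
nn_gap <- function() list(type = "gap")  # global average pool -> (N, C)
nn_seq <- function(...) {
  layers <- list(...)
  if (is.null(names(layers)) || any(names(layers) == "")) {
    names(layers) <- sprintf("l%02d", seq_along(layers))
  }
  list(type = "seq", layers = layers)
}

# Bottleneck residual block: 1x1 reduce, 3x3, 1x1 expand (x4), with a
# projection shortcut when the shape changes.
nn_bottleneck <- function(in_ch, width, stride = 1L) {
  out_ch <- 4L * width
  spec <- list(type = "bottleneck", in_ch = in_ch, width = width,
               out_ch = out_ch, stride = as.integer(stride),
               downsample = (stride != 1L || in_ch != out_ch))
  spec$conv1 <- nn_conv(in_ch, width, 1L, 1L, 0L, bias = FALSE)
  spec$bn1 <- nn_bn2d(width)
  spec$conv2 <- nn_conv(width, width, 3L, stride, 1L, bias = FALSE)
  spec$bn2 <- nn_bn2d(width)
  spec$conv3 <- nn_conv(width, out_ch, 1L, 1L, 0L, bias = FALSE)
  spec$bn3 <- nn_bn2d(out_ch)
  if (spec$downsample) {
    spec$down_conv <- nn_conv(in_ch, out_ch, 1L, stride, 0L, bias = FALSE)
    spec$down_bn <- nn_bn2d(out_ch)
  }
  spec
}

bottleneck_children <- function(spec) {
  ch <- c("conv1", "bn1", "conv2", "bn2", "conv3", "bn3")
  if (spec$downsample) ch <- c(ch, "down_conv", "down_bn")
  ch
}

# ---- initialization ---------------------------------------------------------

kaiming_sd <- function(fan_in) sqrt(2 / fan_in)

nn_init <- function(arch) {
  switch(arch$type,
    conv = {
      k <- arch$k
      sd <- kaiming_sd(k * k * arch$in_ch)
      p <- list(w = array(stats::rnorm(k * k * arch$in_ch * arch$out_ch, sd = sd),
                          dim = c(k, k, arch$in_ch, arch$out_ch)))
      if (arch$bias) p$b <- numeric(arch$out_ch)
      list(params = p, state = NULL)
    },
    bn2d = ,
    bn1d = list(params = list(gamma = rep(1, arch$ch), beta = numeric(arch$ch)),
                state = list(run_mean = numeric(arch$ch), run_var = rep(1, arch$ch))),
    linear = {
      sd <- kaiming_sd(arch$in_ch)
      list(params = list(w = matrix(stats::rnorm(arch$in_ch * arch$out_ch, sd = sd),
                                    arch$in_ch, arch$out_ch),
                         b = numeric(arch$out_ch)),
           state = NULL)
    },
    relu = ,
    maxpool = ,
    dropout = ,
    gap = list(params = NULL, state = NULL),
    seq = {
      sub <- lapply(arch$layers, nn_init)
      list(params = lapply(sub, `[[`, "params"),
           state = lapply(sub, `[[`, "state"))
    },
    bottleneck = {
      nm <- bottleneck_children(arch)
      sub <- lapply(arch[nm], nn_init)
      list(params = lapply(sub, `[[`, "params"),
           state = lapply(sub, `[[`, "state"))
    },
    stop("unknown layer type: ", arch$type)
  )
}

# ---- forward ----------------------------------------------------------------

nn_forward <- function(arch, params, state, x, training = FALSE) {
  switch(arch$type,
    conv = {
      d <- dim(x)
      if (d[3] != arch$in_ch) {
        stop(sprintf("conv expects %d input channels, got %d", arch$in_ch, d[3]))
      }
      out <- cpp_conv2d_forward(x, params$w, if (arch$bias) params$b else NULL,
                                arch$stride, arch$pad)
      list(out = out, cache = list(x = x), state = state)
    },
    bn2d = {
      r <- cpp_bn2d_forward(x, params$gamma, params$beta,
                            state$run_mean, state$run_var,
                            training, 0.1, 1e-5)
      list(out = r$out, cache = list(x = x, mean = r$mean, var = r$var,
                                     training = training),
           state = list(run_mean = r$run_mean, run_var = r$run_var))
    },
    bn1d = {
      bn1d_forward(x, params, state, training)
    },
    relu = {
      out <- x * (x > 0)
      list(out = out, cache = list(mask = x > 0), state = state)
    },
    maxpool = {
      r <- cpp_maxpool_forward(x, arch$k, arch$stride, arch$pad)
      list(out = r$out, cache = list(argmax = r$argmax, H = dim(x)[1], W = dim(x)[2]),
           state = state)
    },
    linear = {
      if (ncol(x) != arch$in_ch) {
        stop(sprintf("linear expects %d input features, got %d", arch$in_ch, ncol(x)))
      }
      out <- x %*% params$w
      out <- sweep(out, 2, params$b, `+`)
      list(out = out, cache = list(x = x), state = state)
    },
    dropout = {
      if (training && arch$p > 0) {
        keep <- matrix(stats::runif(length(x)) >= arch$p, nrow(x), ncol(x))
        out <- x * keep / (1 - arch$p)
        list(out = out, cache = list(keep = keep, p = arch$p), state = state)
      } else {
        list(out = x, cache = list(keep = NULL), state = state)
      }
    },
    gap = {
      d <- dim(x)
      out <- global_pool(x)
      list(out = out, cache = list(dim = d), state = state)
    },
    seq = {
      caches <- vector("list", length(arch$layers))
      names(caches) <- names(arch$layers)
      new_state <- state
      for (nm in names(arch$layers)) {
        r <- nn_forward(arch$layers[[nm]], params[[nm]], state[[nm]], x, training)
        x <- r$out
        caches[[nm]] <- r$cache
        new_state[[nm]] <- r$state
      }
      list(out = x, cache = caches, state = new_state)
    },
    bottleneck = bottleneck_forward(arch, params, state, x, training),
    stop("unknown layer type: ", arch$type)
  )
}

bn1d_forward <- function(x, params, state, training) {
  if (training) {
    mu <- colMeans(x)
    v <- colMeans(x^2) - mu^2
    v[v < 0] <- 0
    m <- nrow(x)
    unbias <- if (m > 1) m / (m - 1) else 1
    new_state <- list(run_mean = 0.9 * state$run_mean + 0.1 * mu,
                      run_var = 0.9 * state$run_var + 0.1 * v * unbias)
  } else {
    mu <- state$run_mean
    v <- state$run_var
    new_state <- state
  }
  inv <- 1 / sqrt(v + 1e-5)
  xhat <- sweep(sweep(x, 2, mu, `-`), 2, inv, `*`)
  out <- sweep(sweep(xhat, 2, params$gamma, `*`), 2, params$beta, `+`)
  list(out = out, cache = list(xhat = xhat, inv = inv, training = training),
       state = new_state)
}

bottleneck_forward <- function(arch, params, state, x, training) {
  caches <- list()
  new_state <- state
  run <- function(nm, input) {
    r <- nn_forward(arch[[nm]], params[[nm]], state[[nm]], input, training)
    caches[[nm]] <<- r$cache
    new_state[[nm]] <<- r$state
    r$out
  }
  h <- run("conv1", x)
  h <- run("bn1", h)
  m1 <- h > 0; h <- h * m1
  h <- run("conv2", h)
  h <- run("bn2", h)
  m2 <- h > 0; h <- h * m2
  h <- run("conv3", h)
  h <- run("bn3", h)
  if (arch$downsample) {
    sc <- run("down_conv", x)
    sc <- run("down_bn", sc)
  } else {
    sc <- x
  }
  pre <- h + sc
  m3 <- pre > 0
  out <- pre * m3
  caches$relu <- list(m1 = m1, m2 = m2, m3 = m3)
  list(out = out, cache = caches, state = new_state)
}

# ---- backward ---------------------------------------------------------------

nn_backward <- function(arch, params, cache, gout, need_gx = TRUE) {
  switch(arch$type,
    conv = {
      r <- cpp_conv2d_backward(cache$x, params$w, gout, arch$stride, arch$pad,
                               arch$bias, need_gx)
      g <- list(w = r$gw)
      if (arch$bias) g$b <- r$gb
      list(gx = if (need_gx) r$gx else NULL, grads = g)
    },
    bn2d = {
      r <- cpp_bn2d_backward(cache$x, gout, params$gamma, cache$mean, cache$var,
                             1e-5, cache$training)
      list(gx = r$gx, grads = list(gamma = r$ggamma, beta = r$gbeta))
    },
    bn1d = {
      xhat <- cache$xhat
      ggamma <- colSums(gout * xhat)
      gbeta <- colSums(gout)
      gscaled <- sweep(gout, 2, params$gamma * cache$inv, `*`)
      if (cache$training) {
        m <- nrow(xhat)
        gx <- gscaled -
          matrix(colSums(gscaled) / m, m, ncol(xhat), byrow = TRUE) -
          xhat * matrix(colSums(gscaled * xhat) / m, m, ncol(xhat), byrow = TRUE)
      } else {
        gx <- gscaled
      }
      list(gx = gx, grads = list(gamma = ggamma, beta = gbeta))
    },
    relu = list(gx = gout * cache$mask, grads = NULL),
    maxpool = list(gx = cpp_maxpool_backward(gout, cache$argmax, cache$H, cache$W),
                   grads = NULL),
    linear = {
      list(gx = if (need_gx) gout %*% t(params$w) else NULL,
           grads = list(w = t(cache$x) %*% gout, b = colSums(gout)))
    },
    dropout = {
      if (is.null(cache$keep)) list(gx = gout, grads = NULL)
      else list(gx = gout * cache$keep / (1 - cache$p), grads = NULL)
    },
    gap = {
      d <- cache$dim
      hw <- d[1] * d[2]
      # gout is (N, C); spread evenly over the spatial plane
      gx <- array(0, dim = d)
      per <- gout / hw
      gx <- array(rep(as.vector(t(per)), each = hw), dim = c(d[1], d[2], d[3], d[4]))
      list(gx = gx, grads = NULL)
    },
    seq = {
      nms <- names(arch$layers)
      grads <- stats::setNames(vector("list", length(nms)), nms)
      for (i in rev(seq_along(nms))) {
        nm <- nms[i]
        need <- need_gx || i > 1
        r <- nn_backward(arch$layers[[nm]], params[[nm]], cache[[nm]], gout, need)
        grads[[nm]] <- r$grads
        gout <- r$gx
      }
      list(gx = gout, grads = grads)
    },
    bottleneck = bottleneck_backward(arch, params, cache, gout, need_gx),
    stop("unknown layer type: ", arch$type)
  )
}

bottleneck_backward <- function(arch, params, cache, gout, need_gx = TRUE) {
  grads <- list()
  back <- function(nm, g, need = TRUE) {
    r <- nn_backward(arch[[nm]], params[[nm]], cache[[nm]], g, need)
    grads[[nm]] <<- r$grads
    r$gx
  }
  g <- gout * cache$relu$m3
  # shortcut branch
  if (arch$downsample) {
    gsc <- back("down_bn", g)
    gsc <- back("down_conv", gsc, need_gx)
  } else {
    gsc <- g
  }
  # main branch
  gm <- back("bn3", g)
  gm <- back("conv3", gm)
  gm <- gm * cache$relu$m2
  gm <- back("bn2", gm)
  gm <- back("conv2", gm)
  gm <- gm * cache$relu$m1
  gm <- back("bn1", gm)
  gm <- back("conv1", gm, need_gx)
  gx <- if (need_gx) gm + gsc else NULL
  list(gx = gx, grads = grads)
}

# ---- parameter-tree helpers -------------------------------------------------

# Apply f(leaf_a, leaf_b) over two parameter trees, matching entries of `a`
# by name in `b`. NULL entries of `a` (parameter-free layers) are skipped;
# gradient trees may omit them entirely.
map2_leaves <- function(a, b, f, path = "") {
  if (is.null(a)) return(NULL)
  if (is.list(a)) {
    if (!is.list(b)) stop("parameter tree mismatch at ", path)
    out <- a
    for (nm in names(a)) {
      if (is.null(a[[nm]])) next
      out[[nm]] <- map2_leaves(a[[nm]], b[[nm]], f, paste0(path, "/", nm))
    }
    out
  } else {
    if (is.null(b)) stop("parameter tree mismatch at ", path)
    f(a, b)
  }
}

map_leaves <- function(a, f) {
  if (is.list(a)) lapply(a, map_leaves, f = f)
  else if (is.null(a)) NULL
  else f(a)
}

leaf_values <- function(a) {
  out <- list()
  walk <- function(x, path) {
    if (is.list(x)) {
      for (nm in names(x)) walk(x[[nm]], paste0(path, "/", nm))
    } else if (!is.null(x)) {
      out[[path]] <<- x
    }
  }
  walk(a, "")
  out
}

#' Count parameters in a parameter tree
#'
#' @param params A nested parameter list as produced by the model builders.
#' @return Total number of scalar parameters (a double, to avoid integer
#'   overflow for large models).
#' @keywords internal
param_count <- function(params) {
  sum(vapply(leaf_values(params), length, numeric(1)))
}

# Global gradient-norm clipping; returns the scaled tree.
clip_grad_norm <- function(grads, max_norm) {
  sq <- sum(vapply(leaf_values(grads), function(g) sum(g^2), numeric(1)))
  nrm <- sqrt(sq)
  if (is.finite(nrm) && nrm > max_norm) {
    scale <- max_norm / (nrm + 1e-6)
    grads <- map_leaves(grads, function(g) g * scale)
  }
  attr(grads, "grad_norm") <- nrm
  grads
}
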