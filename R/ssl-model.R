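# Spatial BYOL: dual-branch self-distillation model and hybrid loss.
#
# The online network carries encoder + global projector/predictor + spatial
# projector/predictor; the target network mirrors it without predictors and
# is updated only by an exponential moving average of the online weights.

EPS_NORM <- 1e-8

#' Cosine distance loss between two vectors
#'
#' Computes `2 - 2 * (a . b) / (||a|| * ||b||)`, the per-pair loss of the
#' BYOL objective: 0 for parallel, 2 for orthogonal, 4 for antiparallel
#' vectors. Norms are regularized by a small epsilon so zero vectors never
#' divide by zero.
#'
#' @param a,b Numeric vectors of equal length.
#' @return A scalar in `[0, 4]`.
#' @examples
#' cosine_loss(c(1, 2, 3), c(1, 2, 3))  # 0
#' cosine_loss(c(1, 0), c(0, 1))        # 2
#' @export
cosine_loss <- function(a, b) {
  if (length(a) != length(b)) stop("cosine_loss: length mismatch")
  na <- sqrt(sum(a^2)) + EPS_NORM
  nb <- sqrt(sum(b^2)) + EPS_NORM
  2 - 2 * sum(a * b) / (na * nb)
}

# Row-wise cosine loss for (N, D) matrices; returns per-row losses and the
# gradient of their SUM with respect to p.
rowwise_cos <- function(p, z) {
  np <- sqrt(rowSums(p^2)) + EPS_NORM
  nz <- sqrt(rowSums(z^2)) + EPS_NORM
  dots <- rowSums(p * z)
  cosv <- dots / (np * nz)
  gp <- -2 * (z / (np * nz) - (cosv / np^2) * p)
  list(loss = 2 - 2 * cosv, gp = gp)
}

#' Global BYOL loss
#'
#' Symmetric pooled-branch objective: the mean cosine loss between online
#' predictions and stop-gradient target projections, averaged over the two
#' view orders, `0.5 * [mean l_cos(p1g, z2g) + mean l_cos(p2g, z1g)]`.
#'
#' @param p1g,p2g Online predictions for views 1 and 2, `(N, D)` matrices.
#' @param z2g,z1g Target projections for the opposite views, `(N, D)`.
#' @return A scalar in `[0, 4]`.
#' @export
global_byol_loss <- function(p1g, z2g, p2g, z1g) {
  if (nrow(p1g) != nrow(z2g) || nrow(p2g) != nrow(z1g)) {
    stop("global_byol_loss: batch size mismatch")
  }
  0.5 * (mean(rowwise_cos(p1g, z2g)$loss) + mean(rowwise_cos(p2g, z1g)$loss))
}

# Per-location cosine loss over (H, W, C, N) maps; returns the mean loss over
# all (b, h, w) and the gradient of that mean with respect to P.
spatial_cos <- function(P, Z) {
  d <- dim(P)
  if (!identical(d, dim(Z))) {
    stop(sprintf("spatial map shape mismatch: (%s) vs (%s)",
                 paste(d, collapse = ","), paste(dim(Z), collapse = ",")))
  }
  HW <- d[1] * d[2]; C <- d[3]; N <- d[4]
  Pm <- matrix(P, nrow = HW)          # (HW, C*N)
  Zm <- matrix(Z, nrow = HW)
  sum_by_loc <- function(M) {
    a <- array(M, dim = c(HW, C, N))
    # sum over channels -> (HW, N)
    apply(a, c(1, 3), sum)
  }
  np <- sqrt(sum_by_loc(Pm^2)) + EPS_NORM   # (HW, N)
  nz <- sqrt(sum_by_loc(Zm^2)) + EPS_NORM
  dots <- sum_by_loc(Pm * Zm)
  cosv <- dots / (np * nz)
  expand <- function(f) f[, rep(seq_len(N), each = C), drop = FALSE]  # (HW, C*N)
  gP <- (-2 / (HW * N)) * (Zm / expand(np * nz) - expand(cosv / np^2) * Pm)
  dim(gP) <- d
  list(loss = mean(2 - 2 * cosv), gP = gP)
}

#' Spatial BYOL loss
#'
#' Dense per-location objective: at every spatial grid cell the channel
#' vectors of the online prediction map and the stop-gradient target
#' projection map are compared with the cosine loss, the result averaged
#' over all locations and samples, and symmetrized over the two view
#' orders.
#'
#' @param P1,P2 Online spatial prediction maps, `(H, W, C, N)` arrays.
#' @param Z2p,Z1p Target spatial projection maps for the opposite views.
#' @return A scalar in `[0, 4]`.
#' @export
spatial_byol_loss <- function(P1, Z2p, P2, Z1p) {
  0.5 * (spatial_cos(P1, Z2p)$loss + spatial_cos(P2, Z1p)$loss)
}

#' Combine global and spatial losses into the hybrid objective
#'
#' `l_hybrid = (1 - lambda) * l_global + lambda * l_spatial`, with equal
#' weighting (`lambda = 0.5`) by default.
#'
#' @param l_global,l_spatial Nonnegative scalar branch losses.
#' @param lambda_spatial Spatial-branch weight in `[0, 1]`.
#' @return An object of class `sbyol_loss_parts`: a list with `l_global`,
#'   `l_spatial`, `lambda_spatial` and `l_hybrid`.
#' @examples
#' hybrid_loss(2, 0)$l_hybrid  # 1
#' @export
hybrid_loss <- function(l_global, l_spatial, lambda_spatial = 0.5) {
  if (!is.finite(lambda_spatial) || lambda_spatial < 0 || lambda_spatial > 1) {
    stop("lambda_spatial must lie in [0, 1]")
  }
  structure(list(l_global = l_global, l_spatial = l_spatial,
                 lambda_spatial = lambda_spatial,
                 l_hybrid = (1 - lambda_spatial) * l_global +
                   lambda_spatial * l_spatial),
            class = "sbyol_loss_parts")
}

#' @export
print.sbyol_loss_parts <- function(x, ...) {
  cat(sprintf("hybrid loss %.4f  (global %.4f, spatial %.4f, lambda %.2f)\n",
              x$l_hybrid, x$l_global, x$l_spatial, x$lambda_spatial))
  invisible(x)
}

# ---- model construction -----------------------------------------------------

make_global_projector_arch <- function(in_dim, hidden, out_dim) {
  nn_seq(fc1 = nn_linear(in_dim, hidden), bn = nn_bn1d(hidden),
         relu = nn_relu(), fc2 = nn_linear(hidden, out_dim))
}

make_spatial_projector_arch <- function(in_ch, mid, out_ch) {
  nn_seq(conv1 = nn_conv(in_ch, mid, 3L, 1L, 1L, bias = TRUE),
         bn1 = nn_bn2d(mid), relu = nn_relu(),
         conv2 = nn_conv(mid, out_ch, 1L, 1L, 0L, bias = TRUE),
         bn2 = nn_bn2d(out_ch))
}

make_spatial_predictor_arch <- function(ch) {
  nn_seq(conv1 = nn_conv(ch, ch, 3L, 1L, 1L, bias = TRUE),
         bn1 = nn_bn2d(ch), relu = nn_relu(),
         conv2 = nn_conv(ch, ch, 3L, 1L, 1L, bias = TRUE),
         bn2 = nn_bn2d(ch))
}

#' Build a Spatial BYOL model
#'
#' Assembles the full dual-branch self-distillation model around an encoder:
#' a global branch (projection and prediction MLPs, 2048-4096-256 by
#' default) on the pooled deepest map `s2`, and a spatial branch
#' (convolutional projection and prediction heads preserving the grid,
#' 1024-256-128 by default) on the mid-depth map `s1`. The target network
#' duplicates the encoder and both projectors; predictors exist only on the
#' online side. Target parameters start as a copy of the online ones and
#' are coupled by an exponential moving average with decay `tau`.
#'
#' @param encoder An `sbyol_encoder` from [build_encoder()].
#' @param proj_hidden,proj_dim Hidden and output width of the global MLPs.
#' @param spatial_mid,spatial_dim Intermediate and output channels of the
#'   spatial heads.
#' @param tau EMA decay of the target network (default 0.996).
#' @param seed Optional seed for head initialization.
#' @return An object of class `sbyol_model`.
#' @examples
#' enc <- build_encoder(blocks = c(1, 1, 1, 1), base_width = 4, seed = 1)
#' m <- build_ssl_model(enc, proj_hidden = 32, proj_dim = 16,
#'                      spatial_mid = 16, spatial_dim = 8, seed = 1)
#' param_count(m$online$params)
#' @export
build_ssl_model <- function(encoder, proj_hidden = 4096L, proj_dim = 256L,
                            spatial_mid = 256L, spatial_dim = 128L,
                            tau = 0.996, seed = NULL) {
  stopifnot(inherits(encoder, "sbyol_encoder"))
  if (!is.null(seed)) set.seed(seed)
  arch <- list(
    gproj = make_global_projector_arch(encoder$c_s2, proj_hidden, proj_dim),
    gpred = make_global_projector_arch(proj_dim, proj_hidden, proj_dim),
    sproj = make_spatial_projector_arch(encoder$c_s1, spatial_mid, spatial_dim),
    spred = make_spatial_predictor_arch(spatial_dim)
  )
  heads <- lapply(arch, nn_init)
  online <- list(
    params = list(encoder = encoder$params,
                  gproj = heads$gproj$params, gpred = heads$gpred$params,
                  sproj = heads$sproj$params, spred = heads$spred$params),
    state = list(encoder = encoder$state,
                 gproj = heads$gproj$state, gpred = heads$gpred$state,
                 sproj = heads$sproj$state, spred = heads$spred$state)
  )
  target <- list(
    params = list(encoder = encoder$params,
                  gproj = heads$gproj$params, sproj = heads$sproj$params),
    state = list(encoder = encoder$state,
                 gproj = heads$gproj$state, sproj = heads$sproj$state)
  )
  structure(list(encoder = encoder, arch = arch, online = online,
                 target = target, tau = tau,
                 dims = list(proj_hidden = proj_hidden, proj_dim = proj_dim,
                             spatial_mid = spatial_mid,
                             spatial_dim = spatial_dim)),
            class = "sbyol_model")
}

#' @export
print.sbyol_model <- function(x, ...) {
  n_online <- param_count(x$online$params)
  n_target <- param_count(x$target$params)
  cat(sprintf("<sbyol_model> tau = %.3f\n", x$tau))
  cat(sprintf("  online:  %s parameters\n", format(n_online, big.mark = ",")))
  cat(sprintf("  target:  %s parameters\n", format(n_target, big.mark = ",")))
  cat(sprintf("  total:   %s parameters\n",
              format(n_online + n_target, big.mark = ",")))
  invisible(x)
}

#' Total parameter count of a model object
#'
#' For an `sbyol_model`, counts online and target parameters together; for
#' other objects with a `$params` tree, counts that tree.
#'
#' @param x An `sbyol_model`, `sbyol_encoder`, classifier, or a bare
#'   parameter tree.
#' @return Number of scalar parameters.
#' @export
model_param_count <- function(x) {
  if (inherits(x, "sbyol_model")) {
    param_count(x$online$params) + param_count(x$target$params)
  } else if (!is.null(x$params)) {
    param_count(x$params)
  } else {
    param_count(x)
  }
}

#' Exponential moving average update of the target network
#'
#' Every target parameter moves toward its online counterpart,
#' `xi <- tau * xi + (1 - tau) * theta`; batch-norm running statistics are
#' copied from the online side rather than mixed. The optimizer never
#' touches target parameters — EMA is their only source of change.
#'
#' @param model An `sbyol_model`.
#' @param tau Optional decay override (defaults to `model$tau`).
#' @return The model with updated target parameters.
#' @export
ema_update <- function(model, tau = NULL) {
  tau <- tau %||% model$tau
  for (part in names(model$target$params)) {
    model$target$params[[part]] <- map2_leaves(
      model$target$params[[part]], model$online$params[[part]],
      function(xi, theta) tau * xi + (1 - tau) * theta,
      path = part)
    model$target$state[[part]] <- model$online$state[[part]]
  }
  model
}

# ---- forward passes ---------------------------------------------------------

# Online forward for one view: returns predictions for both branches plus
# all caches required for backprop, and updated BN state.
online_forward <- function(model, images, training = TRUE) {
  enc <- encoder_forward(model$encoder, model$online$params$encoder,
                         model$online$state$encoder, images,
                         training = training, keep_cache = TRUE)
  v <- global_pool(enc$s2)
  gp <- nn_forward(model$arch$gproj, model$online$params$gproj,
                   model$online$state$gproj, v, training)
  gq <- nn_forward(model$arch$gpred, model$online$params$gpred,
                   model$online$state$gpred, gp$out, training)
  sp <- nn_forward(model$arch$sproj, model$online$params$sproj,
                   model$online$state$sproj, enc$s1, training)
  sq <- nn_forward(model$arch$spred, model$online$params$spred,
                   model$online$state$spred, sp$out, training)
  list(pg = gq$out, Pmap = sq$out,
       cache = list(enc = enc$cache, s2dim = dim(enc$s2),
                    gproj = gp$cache, gpred = gq$cache,
                    sproj = sp$cache, spred = sq$cache),
       state = list(encoder = enc$state, gproj = gp$state, gpred = gq$state,
                    sproj = sp$state, spred = sq$state))
}

# Target forward: stop-gradient projections for both branches. Uses batch
# statistics (training = TRUE) but its state updates are discarded; running
# statistics are kept in sync with the online network by ema_update().
target_forward <- function(model, images) {
  enc <- encoder_forward(model$encoder, model$target$params$encoder,
                         model$target$state$encoder, images,
                         training = TRUE, keep_cache = FALSE)
  v <- global_pool(enc$s2)
  zg <- nn_forward(model$arch$gproj, model$target$params$gproj,
                   model$target$state$gproj, v, training = TRUE)$out
  Zp <- nn_forward(model$arch$sproj, model$target$params$sproj,
                   model$target$state$sproj, enc$s1, training = TRUE)$out
  list(zg = zg, Zmap = Zp)
}

# Backward through the online network for one view, given gradients on the
# global prediction (N, D) and spatial prediction map (H, W, C, N).
online_backward <- function(model, cache, g_pg, g_Pmap) {
  gq <- nn_backward(model$arch$gpred, model$online$params$gpred,
                    cache$gpred, g_pg)
  gp <- nn_backward(model$arch$gproj, model$online$params$gproj,
                    cache$gproj, gq$gx)
  # pooled vector -> s2 map gradient (spread evenly across the plane)
  d <- cache$s2dim
  hw <- d[1] * d[2]
  gs2 <- array(rep(as.vector(t(gp$gx / hw)), each = hw), dim = d)
  sq <- nn_backward(model$arch$spred, model$online$params$spred,
                    cache$spred, g_Pmap)
  sp <- nn_backward(model$arch$sproj, model$online$params$sproj,
                    cache$sproj, sq$gx)
  enc <- encoder_backward(model$encoder, model$online$params$encoder,
                          cache$enc, gs1 = sp$gx, gs2 = gs2)
  list(encoder = enc$grads, gproj = gp$grads, gpred = gq$grads,
       sproj = sp$grads, spred = sq$grads)
}

# ---- training step ----------------------------------------------------------

new_accumulator <- function(steps = 4L, clip = 1.0) {
  list(grads = NULL, count = 0L, steps = as.integer(steps), clip = clip)
}

#' One pretraining step with gradient accumulation
#'
#' Forwards both augmented views through the online network (to predictions)
#' and the target network (to stop-gradient projections), computes the
#' hybrid loss, and accumulates gradients scaled by `1/steps`. On every
#' `steps`-th call the accumulated gradient norm is clipped, one AdamW
#' update is applied to the online parameters, the accumulator resets, and
#' the target network receives its EMA update. The returned loss parts are
#' the unscaled hybrid loss of this mini-batch.
#'
#' @param model An `sbyol_model`.
#' @param view_pair An `sbyol_views` pair from [make_views()], or any list
#'   with elements `view1` and `view2` of shape `(H, W, 3, N)`.
#' @param opt AdamW optimizer state from `adamw_init(model$online$params)`.
#' @param accum Accumulator from `new_accumulator()`; carries the gradient
#'   running sum and the step counter.
#' @param lambda_spatial Spatial-branch weight (default 0.5).
#' @return A list with `loss` (`sbyol_loss_parts`), `model`, `opt`, `accum`,
#'   and `stepped` (whether an optimizer update was applied).
#' @export
pretrain_step <- function(model, view_pair, opt, accum,
                          lambda_spatial = 0.5) {
  v1 <- view_pair$view1
  v2 <- view_pair$view2

  on1 <- online_forward(model, v1)
  model$online$state <- on1$state
  on2 <- online_forward(model, v2)
  model$online$state <- on2$state
  tg1 <- target_forward(model, v1)
  tg2 <- target_forward(model, v2)

  N <- dim(v1)[4]
  g1 <- rowwise_cos(on1$pg, tg2$zg)
  g2 <- rowwise_cos(on2$pg, tg1$zg)
  l_global <- 0.5 * (mean(g1$loss) + mean(g2$loss))
  s1 <- spatial_cos(on1$Pmap, tg2$Zmap)
  s2 <- spatial_cos(on2$Pmap, tg1$Zmap)
  l_spatial <- 0.5 * (s1$loss + s2$loss)
  parts <- hybrid_loss(l_global, l_spatial, lambda_spatial)
  if (!is.finite(parts$l_hybrid)) {
    stop(sprintf("non-finite loss (global %.6g, spatial %.6g)",
                 l_global, l_spatial))
  }

  # Gradients of the hybrid loss scaled by 1/steps so that the accumulated
  # gradient equals that of the mean over the effective batch.
  scale <- 1 / accum$steps
  wg <- (1 - lambda_spatial) * 0.5 * scale
  ws <- lambda_spatial * 0.5 * scale
  grads1 <- online_backward(model, on1$cache,
                            g_pg = wg * g1$gp / N, g_Pmap = ws * s1$gP)
  grads2 <- online_backward(model, on2$cache,
                            g_pg = wg * g2$gp / N, g_Pmap = ws * s2$gP)
  step_grads <- map2_leaves(grads1, grads2, `+`)

  accum$grads <- if (is.null(accum$grads)) step_grads
                 else map2_leaves(accum$grads, step_grads, `+`)
  accum$count <- accum$count + 1L

  stepped <- FALSE
  if (accum$count >= accum$steps) {
    grads <- clip_grad_norm(accum$grads, accum$clip)
    r <- adamw_step(opt, model$online$params, grads)
    opt <- r$opt
    model$online$params <- r$params
    accum$grads <- NULL
    accum$count <- 0L
    model <- ema_update(model)
    stepped <- TRUE
  }
  list(loss = parts, model = model, opt = opt, accum = accum,
       stepped = stepped)
}

#' Self-supervised pretraining loop
#'
#' Runs the hybrid-objective pretraining: AdamW (learning rate 3e-4, weight
#' decay 1e-4 by default) with cosine annealing of the learning rate,
#' gradient accumulation, gradient clipping at norm 1.0, an EMA target with
#' decay 0.996, and early stopping on the per-epoch mean training hybrid
#' loss (no labels exist in pretraining). The checkpoint with the minimum
#' epoch loss is retained as the best model.
#'
#' @param model An `sbyol_model`.
#' @param images A `(H, W, 3, N)` array of images in `[0, 1]` (pre-resize),
#'   or a dataset handle from [load_image_folder()].
#' @param config A list of overrides merged over [default_config()]'s `ssl`
#'   section: `epochs`, `patience`, `lr`, `weight_decay`, `batch`,
#'   `accum_steps`, `clip`, `lambda_spatial`, `cosine_horizon`, `size`,
#'   `seed`.
#' @param checkpoint Optional file path; the best model is saved there.
#' @return An object of class `sbyol_pretrain`: list with `model` (best),
#'   `history` (tibble: epoch, lr, l_global, l_spatial, l_hybrid),
#'   `best_epoch`.
#' @export
pretrain <- function(model, images, config = list(), checkpoint = NULL) {
  cfg <- utils::modifyList(default_config()$ssl, config)
  aug <- utils::modifyList(default_config()$augment, cfg$augment %||% list())
  n <- dataset_length(images)
  if (n == 0) stop("pretraining dataset is empty")
  if (!is.null(cfg$seed)) set.seed(cfg$seed)

  opt <- adamw_init(model$online$params, lr = cfg$lr,
                    weight_decay = cfg$weight_decay)
  accum <- new_accumulator(steps = cfg$accum_steps, clip = cfg$clip)

  history <- vector("list", cfg$epochs)
  best_loss <- Inf
  best_model <- model
  best_epoch <- 0L
  wait <- 0L

  for (epoch in seq_len(cfg$epochs)) {
    opt$lr <- cosine_lr(epoch, cfg$lr, cfg$cosine_horizon)
    idx <- sample.int(n)
    batches <- split(idx, ceiling(seq_along(idx) / cfg$batch))
    eg <- es <- eh <- 0
    for (b in batches) {
      imgs <- dataset_batch(images, b)
      vp <- make_views(imgs, size = cfg$size, scale = aug$scale,
                       flip_p = aug$flip_p, jitter = aug$jitter,
                       blur_p = aug$blur_p)
      r <- pretrain_step(model, vp, opt, accum,
                         lambda_spatial = cfg$lambda_spatial)
      model <- r$model; opt <- r$opt; accum <- r$accum
      eg <- eg + r$loss$l_global * length(b)
      es <- es + r$loss$l_spatial * length(b)
      eh <- eh + r$loss$l_hybrid * length(b)
    }
    history[[epoch]] <- tibble::tibble(
      epoch = epoch, lr = opt$lr,
      l_global = eg / n, l_spatial = es / n, l_hybrid = eh / n)
    eh_mean <- eh / n
    if (eh_mean < best_loss - 1e-12) {
      best_loss <- eh_mean
      best_model <- model
      best_epoch <- epoch
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= cfg$patience) break
    }
  }

  history <- dplyr::bind_rows(history)
  out <- structure(list(model = best_model, history = history,
                        best_epoch = best_epoch, config = cfg),
                   class = "sbyol_pretrain")
  if (!is.null(checkpoint)) save_checkpoint(out, checkpoint)
  out
}

#' @export
print.sbyol_pretrain <- function(x, ...) {
  cat(sprintf("<sbyol_pretrain> %d epochs run, best epoch %d (hybrid loss %.4f)\n",
              nrow(x$history), x$best_epoch,
              x$history$l_hybrid[x$best_epoch]))
  invisible(x)
}
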