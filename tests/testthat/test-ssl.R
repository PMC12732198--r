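# The hybrid self-distillation objective: loss identities against
# independent oracles, EMA target coupling, and the training-step
# contracts (accumulation, clipping, stop-gradient isolation).

test_that("cosine loss hits its analytic anchor points", {
  expect_equal(cosine_loss(c(1, 2, 3), c(1, 2, 3)), 0, tolerance = 1e-7)
  expect_equal(cosine_loss(c(1, 0), c(0, 1)), 2)
  expect_equal(cosine_loss(c(1, 0), c(-1, 0)), 4, tolerance = 1e-7)
  # epsilon guard: zero vectors do not divide by zero
  expect_true(is.finite(cosine_loss(c(0, 0), c(1, 1))))
  expect_error(cosine_loss(c(1, 2), c(1, 2, 3)), "length")
})

test_that("global loss equals a per-sample loop oracle and is symmetric", {
  set.seed(21)
  B <- 6; D <- 16
  mats <- replicate(4, matrix(rnorm(B * D), B, D), simplify = FALSE)
  p1 <- mats[[1]]; z2 <- mats[[2]]; p2 <- mats[[3]]; z1 <- mats[[4]]

  oracle <- 0.5 * (mean(sapply(seq_len(B), function(b)
    cosine_loss(p1[b, ], z2[b, ]))) +
    mean(sapply(seq_len(B), function(b) cosine_loss(p2[b, ], z1[b, ]))))
  expect_equal(global_byol_loss(p1, z2, p2, z1), oracle, tolerance = 1e-10)
  # symmetric in view order
  expect_equal(global_byol_loss(p2, z1, p1, z2),
               global_byol_loss(p1, z2, p2, z1))
  # identical predictions and targets give zero
  expect_equal(global_byol_loss(p1, p1, p2, p2), 0, tolerance = 1e-7)
  expect_error(global_byol_loss(p1, z2[1:3, ], p2, z1), "batch")
})

test_that("spatial loss equals a brute-force per-location oracle", {
  set.seed(22)
  d <- c(5, 5, 128, 2)
  P1 <- array(rnorm(prod(d)), d); Z2 <- array(rnorm(prod(d)), d)
  P2 <- array(rnorm(prod(d)), d); Z1 <- array(rnorm(prod(d)), d)

  loop_loss <- function(P, Z) {
    acc <- 0
    for (b in 1:d[4]) for (h in 1:d[1]) for (w in 1:d[2]) {
      acc <- acc + cosine_loss(P[h, w, , b], Z[h, w, , b])
    }
    acc / (d[1] * d[2] * d[4])
  }
  oracle <- 0.5 * (loop_loss(P1, Z2) + loop_loss(P2, Z1))
  expect_equal(spatial_byol_loss(P1, Z2, P2, Z1), oracle, tolerance = 1e-6)

  # exact zero for identical maps; 4 for constant antiparallel maps
  expect_equal(spatial_byol_loss(P1, P1, P2, P2), 0, tolerance = 1e-7)
  cpos <- array(1, dim = c(3, 3, 8, 1)); cneg <- -cpos
  expect_equal(spatial_byol_loss(cpos, cneg, cpos, cneg), 4, tolerance = 1e-7)
  expect_error(
    spatial_byol_loss(P1, array(0, dim = c(4, 4, 128, 2)), P2, Z1),
    "shape mismatch")
})

test_that("spatial loss reduces to the global form on a 1x1 grid", {
  set.seed(23)
  B <- 4; D <- 32
  p1 <- matrix(rnorm(B * D), B, D); z2 <- matrix(rnorm(B * D), B, D)
  p2 <- matrix(rnorm(B * D), B, D); z1 <- matrix(rnorm(B * D), B, D)
  as_map <- function(m) array(t(m), dim = c(1, 1, D, B))
  expect_equal(
    spatial_byol_loss(as_map(p1), as_map(z2), as_map(p2), as_map(z1)),
    global_byol_loss(p1, z2, p2, z1), tolerance = 1e-10)
})

test_that("spatial loss is invariant to a shared permutation of locations", {
  set.seed(24)
  d <- c(4, 4, 16, 2)
  maps <- replicate(4, array(rnorm(prod(d)), d), simplify = FALSE)
  perm <- sample(d[1] * d[2])
  permute <- function(A) {
    m <- matrix(A, nrow = d[1] * d[2])
    array(m[perm, ], dim = d)
  }
  pm <- lapply(maps, permute)
  expect_equal(
    spatial_byol_loss(pm[[1]], pm[[2]], pm[[3]], pm[[4]]),
    spatial_byol_loss(maps[[1]], maps[[2]], maps[[3]], maps[[4]]),
    tolerance = 1e-12)
})

test_that("hybrid loss is the stated convex combination", {
  expect_equal(hybrid_loss(2.0, 0.0, 0.5)$l_hybrid, 1.0)
  expect_equal(hybrid_loss(1.7, 1.7, 0.5)$l_hybrid, 1.7)
  expect_equal(hybrid_loss(1.2, 0.8, 0.5)$l_hybrid, 1.0)
  expect_equal(hybrid_loss(1.2, 0.8, 0.25)$l_hybrid, 0.75 * 1.2 + 0.25 * 0.8)
  expect_error(hybrid_loss(1, 1, 1.5), "lambda")
  expect_error(hybrid_loss(1, 1, -0.1), "lambda")
})

test_that("head architectures have the stated shapes and closed-form counts", {
  # projector 2048 -> 4096 -> 256: weights + biases + batch-norm scale/shift
  gproj <- sb$nn_init(sb$make_global_projector_arch(2048L, 4096L, 256L))
  expect_equal(sb$param_count(gproj$params),
               2048 * 4096 + 4096 + 2 * 4096 + 4096 * 256 + 256)  # 9,449,728
  gpred <- sb$nn_init(sb$make_global_projector_arch(256L, 4096L, 256L))
  expect_equal(sb$param_count(gpred$params), 2109696)
  sproj <- sb$nn_init(sb$make_spatial_projector_arch(1024L, 256L, 128L))
  expect_equal(sb$param_count(sproj$params),
               1024 * 256 * 9 + 256 + 2 * 256 + 256 * 128 + 128 + 2 * 128)  # 2,393,216
  spred <- sb$nn_init(sb$make_spatial_predictor_arch(128L))
  expect_equal(sb$param_count(spred$params), 2 * (128 * 128 * 9 + 128 + 2 * 128))

  # spatial heads preserve the grid and map channels 1024 -> 128 -> 128
  arch <- sb$make_spatial_projector_arch(1024L, 256L, 128L)
  x <- array(rnorm(4 * 4 * 1024 * 2), dim = c(4, 4, 1024, 2))
  out <- sb$nn_forward(arch, sproj$params, sproj$state, x, training = TRUE)$out
  expect_equal(dim(out), c(4, 4, 128, 2))
  parch <- sb$make_spatial_predictor_arch(128L)
  pout <- sb$nn_forward(parch, spred$params, spred$state, out,
                        training = TRUE)$out
  expect_equal(dim(pout), c(4, 4, 128, 2))
  # the predictor is not the identity for random weights
  expect_gt(max(abs(pout - out)), 1e-3)

  # global branch dimensions on a pooled vector
  v <- matrix(rnorm(3 * 2048), 3, 2048)
  gout <- sb$nn_forward(sb$make_global_projector_arch(2048L, 4096L, 256L),
                        gproj$params, gproj$state, v, training = TRUE)$out
  expect_equal(dim(gout), c(3, 256))
})

test_that("EMA update follows xi <- tau xi + (1 - tau) theta exactly", {
  m <- tiny_ssl_model(seed = 5)
  # target starts as a copy of online
  expect_identical(m$target$params$encoder, m$online$params$encoder)

  # perturb online, check the three tau anchor cases on a leaf
  m$online$params$gproj$fc1$b[] <- 1
  m$target$params$gproj$fc1$b[] <- 0

  m1 <- ema_update(m, tau = 1)
  expect_equal(m1$target$params$gproj$fc1$b[1], 0)
  m0 <- ema_update(m, tau = 0)
  expect_equal(m0$target$params$gproj$fc1$b, m$online$params$gproj$fc1$b)
  mt <- ema_update(m, tau = 0.996)
  expect_equal(mt$target$params$gproj$fc1$b[1], 0.004)
})

test_that("optimizer updates fire exactly every accumulation cycle", {
  set.seed(31)
  model <- tiny_ssl_model(seed = 6)
  opt <- sb$adamw_init(model$online$params, lr = 1e-3)
  accum <- sb$new_accumulator(steps = 4L, clip = 1.0)
  imgs <- tiny_images(n = 2, size = 64, seed = 8)
  vp <- make_views(imgs, size = 64, seed = 1)

  theta0 <- model$online$params
  xi0 <- model$target$params
  for (i in 1:3) {
    r <- pretrain_step(model, vp, opt, accum)
    model <- r$model; opt <- r$opt; accum <- r$accum
    expect_false(r$stepped)
  }
  # three calls: no optimizer update, online and target parameters untouched
  expect_identical(model$online$params, theta0)
  expect_identical(model$target$params, xi0)
  expect_equal(accum$count, 3L)

  r <- pretrain_step(model, vp, opt, accum)
  expect_true(r$stepped)
  expect_equal(r$accum$count, 0L)
  expect_false(identical(r$model$online$params, theta0))
  expect_false(identical(r$model$target$params, xi0))
  # loss parts are finite and within the theoretical range
  expect_true(r$loss$l_hybrid >= 0 && r$loss$l_hybrid <= 4)
  expect_true(r$loss$l_global >= 0 && r$loss$l_global <= 4)
  expect_true(r$loss$l_spatial >= 0 && r$loss$l_spatial <= 4)
})

test_that("target parameters follow the closed-form EMA of the online trajectory", {
  set.seed(32)
  model <- tiny_ssl_model(seed = 7)
  tau <- model$tau
  opt <- sb$adamw_init(model$online$params, lr = 1e-2)
  accum <- sb$new_accumulator(steps = 1L, clip = 1e9)
  imgs <- tiny_images(n = 2, size = 64, seed = 9)

  # closed form: xi_k = tau xi_{k-1} + (1 - tau) theta_k, computed
  # independently from the recorded online trajectory
  expected <- model$target$params
  for (k in 1:4) {
    vp <- make_views(imgs, size = 64, seed = 100 + k)
    r <- pretrain_step(model, vp, opt, accum)
    model <- r$model; opt <- r$opt; accum <- r$accum
    for (part in names(expected)) {
      expected[[part]] <- sb$map2_leaves(
        expected[[part]], model$online$params[[part]],
        function(xi, th) tau * xi + (1 - tau) * th)
    }
  }
  expect_equal(model$target$params, expected, tolerance = 1e-12)
})

test_that("loss gradient vanishes at the prediction = target fixed point", {
  set.seed(33)
  p <- matrix(rnorm(3 * 8), 3, 8)
  rc <- sb$rowwise_cos(p, p)
  expect_equal(rc$loss, rep(0, 3), tolerance = 1e-7)
  expect_lt(max(abs(rc$gp)), 1e-6)
  P <- array(rnorm(3 * 3 * 8 * 2), dim = c(3, 3, 8, 2))
  scm <- sb$spatial_cos(P, P)
  expect_equal(scm$loss, 0, tolerance = 1e-7)
  expect_lt(max(abs(scm$gP)), 1e-6)
})

test_that("pretraining runs epochs, decays the rate and reproduces with a seed", {
  model <- tiny_ssl_model(seed = 11)
  imgs <- tiny_images(n = 8, size = 64, seed = 12)
  cfg <- list(epochs = 3, batch = 4, accum_steps = 2, size = 64,
              seed = 41, cosine_horizon = 3)
  fit1 <- pretrain(model, imgs, cfg)
  expect_equal(nrow(fit1$history), 3)
  expect_true(all(diff(fit1$history$lr) <= 0))
  expect_true(all(fit1$history$l_hybrid >= 0 & fit1$history$l_hybrid <= 4))
  fit2 <- pretrain(model, imgs, cfg)
  expect_equal(fit1$history, fit2$history)
  expect_error(pretrain(model, imgs[, , , 0, drop = FALSE]), "empty")
})

test_that("early stopping halts after patience epochs without improvement", {
  # with a zero learning rate and deterministic views the loss is exactly
  # constant, so the second epoch triggers patience = 1
  model <- tiny_ssl_model(seed = 13)
  imgs <- tiny_images(n = 8, size = 64, seed = 14)
  fit <- pretrain(model, imgs, list(
    epochs = 5, patience = 1, batch = 8, accum_steps = 1, size = 64,
    seed = 42, cosine_horizon = 1,
    augment = list(scale = c(1, 1), flip_p = 0, jitter = 0, blur_p = c(0, 0))))
  expect_equal(nrow(fit$history), 2)
  expect_equal(fit$best_epoch, 1)
  expect_equal(fit$history$l_hybrid[1], fit$history$l_hybrid[2],
               tolerance = 1e-12)
})

test_that("cosine schedule anneals over the horizon and floors afterwards", {
  lrs <- sapply(1:125, cosine_lr, lr_max = 3e-4, horizon = 100)
  expect_equal(lrs[1], 3e-4)
  expect_true(all(diff(lrs) <= 0))
  expect_equal(lrs[101:125], rep(0, 25))
})
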