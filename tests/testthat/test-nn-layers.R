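# Backpropagation of every layer type is checked against central finite
# differences; the parameter-tree utilities against direct counting.

test_that("layer backward passes match finite differences", {
  set.seed(7)
  cases <- list(
    conv = list(arch = sb$nn_conv(3, 4, 3, stride = 2, pad = 1),
                x = array(rnorm(9 * 9 * 3 * 2), dim = c(9, 9, 3, 2))),
    conv1x1 = list(arch = sb$nn_conv(2, 5, 1),
                   x = array(rnorm(6 * 6 * 2 * 2), dim = c(6, 6, 2, 2))),
    maxpool = list(arch = sb$nn_maxpool(3, 2, 1),
                   x = array(rnorm(8 * 8 * 2 * 2), dim = c(8, 8, 2, 2))),
    bottleneck = list(arch = sb$nn_bottleneck(8, 4, stride = 2),
                      x = array(rnorm(6 * 6 * 8 * 2), dim = c(6, 6, 8, 2)))
  )
  for (nm in names(cases)) {
    cs <- cases[[nm]]
    init <- sb$nn_init(cs$arch)
    fn <- function(xx) {
      sum(sb$nn_forward(cs$arch, init$params, init$state, xx,
                        training = TRUE)$out^2) / 2
    }
    fw <- sb$nn_forward(cs$arch, init$params, init$state, cs$x,
                        training = TRUE)
    bw <- sb$nn_backward(cs$arch, init$params, fw$cache, fw$out)
    expect_lt(fd_gradient_check(fn, cs$x, bw$gx), 1e-6)
  }
})

test_that("conv weight gradients match finite differences", {
  set.seed(8)
  arch <- sb$nn_conv(2, 3, 3, stride = 1, pad = 1)
  init <- sb$nn_init(arch)
  x <- array(rnorm(5 * 5 * 2 * 2), dim = c(5, 5, 2, 2))
  fw <- sb$nn_forward(arch, init$params, NULL, x)
  bw <- sb$nn_backward(arch, init$params, fw$cache, fw$out)
  fn_w <- function(w) {
    p <- init$params; p$w <- w
    sum(sb$nn_forward(arch, p, NULL, x)$out^2) / 2
  }
  fn_b <- function(b) {
    p <- init$params; p$b <- b
    sum(sb$nn_forward(arch, p, NULL, x)$out^2) / 2
  }
  expect_lt(fd_gradient_check(fn_w, init$params$w, bw$grads$w), 1e-6)
  expect_lt(fd_gradient_check(fn_b, init$params$b, bw$grads$b), 1e-6)
})

test_that("batch norm backward is exact in training and frozen mode", {
  set.seed(9)
  arch <- sb$nn_bn2d(3)
  init <- sb$nn_init(arch)
  p <- init$params
  p$gamma <- runif(3, 0.5, 1.5)
  p$beta <- rnorm(3)
  x <- array(rnorm(5 * 5 * 3 * 4), dim = c(5, 5, 3, 4))
  for (training in c(TRUE, FALSE)) {
    st <- init$state
    if (!training) st$run_var <- runif(3, 0.5, 2)
    fn <- function(xx) {
      sum(sb$nn_forward(arch, p, st, xx, training = training)$out^3) / 3
    }
    fw <- sb$nn_forward(arch, p, st, x, training = training)
    bw <- sb$nn_backward(arch, p, fw$cache, fw$out^2)
    expect_lt(fd_gradient_check(fn, x, bw$gx), 1e-6)
  }
})

test_that("linear + 1-d batch norm + dropout chain backpropagates exactly", {
  set.seed(10)
  arch <- sb$nn_seq(fc = sb$nn_linear(6, 5), bn = sb$nn_bn1d(5),
                    relu = sb$nn_relu(), fc2 = sb$nn_linear(5, 3))
  init <- sb$nn_init(arch)
  x <- matrix(rnorm(4 * 6), 4, 6)
  fn <- function(xx) {
    sum(sb$nn_forward(arch, init$params, init$state,
                      matrix(xx, 4, 6), training = TRUE)$out^2) / 2
  }
  fw <- sb$nn_forward(arch, init$params, init$state, x, training = TRUE)
  bw <- sb$nn_backward(arch, init$params, fw$cache, fw$out)
  expect_lt(fd_gradient_check(fn, x, bw$gx), 1e-6)
})

test_that("parameter counting and clipping behave as direct arithmetic", {
  arch <- sb$nn_seq(fc = sb$nn_linear(10, 7), bn = sb$nn_bn1d(7))
  init <- sb$nn_init(arch)
  expect_equal(sb$param_count(init$params), 10 * 7 + 7 + 2 * 7)

  grads <- list(a = matrix(3, 2, 2), b = c(4, 0, 0))
  # norm = sqrt(4*9 + 16) = sqrt(52)
  clipped <- sb$clip_grad_norm(grads, 1.0)
  total <- sqrt(sum(vapply(sb$leaf_values(clipped), function(g) sum(g^2),
                           numeric(1))))
  expect_lt(total, 1.0 + 1e-8)
  expect_equal(attr(clipped, "grad_norm"), sqrt(52))
  # below the threshold nothing changes
  small <- sb$clip_grad_norm(list(a = c(0.1, 0.1)), 1.0)
  expect_equal(small$a, c(0.1, 0.1))
})

test_that("AdamW decoupled weight decay shrinks parameters with zero gradient", {
  params <- list(w = matrix(1, 2, 2))
  opt <- sb$adamw_init(params, lr = 0.1, weight_decay = 0.5)
  r <- sb$adamw_step(opt, params, list(w = matrix(0, 2, 2)))
  # pure decay: w <- w - lr * wd * w
  expect_equal(r$params$w, matrix(1 - 0.1 * 0.5, 2, 2))
})
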