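# Two-phase fine-tuning: class weights, the stratified split, the weighted
# cross-entropy, the freeze/unfreeze contracts and the scheduler.

test_that("inverse-frequency weights follow N / (K * n_c)", {
  w <- compute_class_weights(c(429, 394))
  expect_equal(round(w, 4), c(0.9592, 1.0444))
  expect_equal(compute_class_weights(c(50, 50)), c(1, 1))
  expect_equal(compute_class_weights(c(10, 30)), c(2.0, 40 / 60),
               tolerance = 1e-12)
  expect_error(compute_class_weights(c(10, 0)), "positive")
})

test_that("stratified split reproduces the 823-image study partition", {
  labels <- rep(c("DRIL", "NO_DRIL"), c(429, 394))
  s <- stratified_split(labels, 0.2, 0.1, seed = 3)
  expect_equal(length(s$test), 165)
  expect_equal(length(s$val), 66)
  expect_equal(length(s$train), 823 - 165 - 66)
  # disjoint and exhaustive
  all_idx <- c(s$train, s$val, s$test)
  expect_equal(sort(all_idx), 1:823)
  # class proportions preserved to within rounding
  expect_equal(sum(labels[s$test] == "DRIL"), 86)  # round_half_up(429 * .2)
  expect_equal(sum(labels[s$test] == "NO_DRIL"), 79)
  # determinism
  s2 <- stratified_split(labels, 0.2, 0.1, seed = 3)
  expect_identical(s$assignment, s2$assignment)
  s3 <- stratified_split(labels, 0.2, 0.1, seed = 4)
  expect_false(identical(s$train, s3$train))
})

test_that("small and invalid splits behave per the contract", {
  s <- stratified_split(rep(c("a", "b"), each = 5), 0.2, 0.1, seed = 1)
  expect_equal(length(s$test), 2)
  lab <- rep(c("a", "b"), each = 5)
  expect_equal(sort(unique(lab[s$test])), c("a", "b"))
  expect_error(stratified_split(lab, 1.2, 0.1), "fractions")
  expect_error(stratified_split(c("a", "b"), 0.2, 0.1), "at least 2")
})

test_that("weighted cross-entropy with equal weights is the unweighted loss", {
  set.seed(51)
  logits <- matrix(rnorm(12), 6, 2)
  y <- sample(1:2, 6, replace = TRUE)
  w_eq <- sb$weighted_ce(logits, y, c(1, 1))
  unw <- sb$weighted_ce(logits, y, NULL)
  expect_equal(w_eq$loss, unw$loss, tolerance = 1e-12)
  expect_equal(w_eq$glogits, unw$glogits, tolerance = 1e-12)
  # gradient matches finite differences
  fn <- function(l) sb$weighted_ce(matrix(l, 6, 2), y, c(0.9, 1.1))$loss
  ce <- sb$weighted_ce(logits, y, c(0.9, 1.1))
  expect_lt(fd_gradient_check(fn, logits, ce$glogits), 1e-6)
})

test_that("classifier head has the stated structure and trainable budget", {
  enc <- tiny_encoder(seed = 1)
  clf <- build_classifier(enc, hidden = 16L, seed = 2)
  expect_equal(clf$phase, 1L)
  # head: fc(c_s2 -> 16) + bn(16) + fc(16 -> 2)
  expect_equal(trainable_param_count(clf),
               enc$c_s2 * 16 + 16 + 2 * 16 + 16 * 2 + 2)
  # Kaiming init: zero biases on the linear layers
  expect_equal(clf$params$head$fc1$b, rep(0, 16))
  expect_equal(clf$params$head$fc2$b, rep(0, 2))
  clf$phase <- 2L
  expect_equal(trainable_param_count(clf), sb$param_count(clf$params))
})

test_that("phase 1 leaves the encoder bitwise untouched; phase 2 moves it", {
  set.seed(52)
  ph <- phantom_batch(6, phantom_config(size = 64), seed = 61)
  enc <- tiny_encoder(seed = 3)
  clf <- build_classifier(enc, hidden = 8L, seed = 4)
  split <- stratified_split(ph$labels, 0.25, 0.25, seed = 5)
  data <- sb$prepare_finetune_data(ph$images, ph$labels, split,
                                   clf$class_levels)
  cfg <- list(epochs_phase1 = 2, epochs_phase2 = 1, batch = 4, size = 64)

  enc_params0 <- clf$params$encoder
  enc_state0 <- clf$state$encoder
  p1 <- finetune_phase1(clf, data, cfg)
  expect_identical(p1$clf$params$encoder, enc_params0)
  expect_identical(p1$clf$state$encoder, enc_state0)
  # the head did train
  expect_false(identical(p1$clf$params$head, clf$params$head))
  expect_equal(nrow(p1$history), 2)

  p2 <- finetune_phase2(p1$clf, data, cfg)
  expect_false(identical(p2$clf$params$encoder, enc_params0))
  # phase-2 learning rate is 90% below phase 1
  expect_equal(p2$history$lr[1], 1e-3 * 0.1)
})

test_that("reduce-on-plateau halves the rate after patience stagnant epochs", {
  sched <- sb$plateau_init(1e-3, factor = 0.5, patience = 3L)
  sched <- sb$plateau_step(sched, 0.8)   # improvement
  expect_equal(sched$lr, 1e-3)
  for (i in 1:3) sched <- sb$plateau_step(sched, 0.8)  # plateau
  expect_equal(sched$lr, 5e-4)
  # counter resets after the reduction
  sched <- sb$plateau_step(sched, 0.8)
  expect_equal(sched$lr, 5e-4)
})

test_that("phase-1 head reaches perfect training accuracy on separable images", {
  # class fully determined by overall brightness: linearly separable in any
  # nondegenerate pooled feature space; full-batch training so the
  # batch-norm running statistics converge to the population statistics
  set.seed(53)
  n <- 8
  imgs <- array(0, dim = c(64, 64, 3, 2 * n))
  imgs[, , , 1:n] <- array(runif(64 * 64 * 3 * n, 0, 0.25),
                           dim = c(64, 64, 3, n))
  imgs[, , , (n + 1):(2 * n)] <- array(runif(64 * 64 * 3 * n, 0.75, 1),
                                       dim = c(64, 64, 3, n))
  labels <- rep(c("DRIL", "NO_DRIL"), each = n)
  enc <- tiny_encoder(seed = 6)
  clf <- build_classifier(enc, hidden = 16L, seed = 7)
  split <- stratified_split(labels, 0.25, 0.2, seed = 8)
  data <- sb$prepare_finetune_data(imgs, labels, split, clf$class_levels)
  cfg <- list(epochs_phase1 = 100, batch = 16, size = 64)
  p1 <- finetune_phase1(clf, data, cfg)
  expect_equal(max(p1$history$train_acc), 1.0)
  expect_equal(max(p1$history$val_acc), 1.0)
})

test_that("the full pipeline beats the majority baseline on phantoms", {
  ph <- phantom_batch(12, phantom_config(size = 64), seed = 71)
  enc <- tiny_encoder(seed = 9, base_width = 8L)
  model <- build_ssl_model(enc, proj_hidden = 32L, proj_dim = 16L,
                           spatial_mid = 16L, spatial_dim = 8L, seed = 9)
  ft <- finetune_dril(model, ph$images, ph$labels,
                      config = list(epochs_phase1 = 8, epochs_phase2 = 4,
                                    size = 64, hidden = 16, batch = 8),
                      seed = 10)
  expect_s3_class(ft$report, "sbyol_report")
  majority <- max(table(ph$labels)) / length(ph$labels)
  expect_gt(ft$report$accuracy, majority)
  expect_equal(sort(unique(ft$test_pred)) %in% c("DRIL", "NO_DRIL"),
               rep(TRUE, length(unique(ft$test_pred))))
  # tidiers expose the history and headline metrics
  expect_true(all(c("phase", "epoch", "val_acc") %in% names(tidy(ft))))
  expect_equal(glance(ft)$accuracy, ft$report$accuracy)
  # predictions on fresh images have the documented shape
  pr <- predict(ft$classifier, ph$images[, , , 1:3, drop = FALSE], size = 64)
  expect_equal(nrow(pr), 3)
  expect_true(all(abs(rowSums(pr[, c("DRIL", "NO_DRIL")]) - 1) < 1e-8))
})
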