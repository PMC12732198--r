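# Two-phase fine-tuning of a pretrained encoder for binary DRIL
# classification: phase 1 trains only a freshly initialized head on frozen
# encoder features; phase 2 unfreezes everything at a 90%-reduced learning
# rate with reduce-on-plateau scheduling.

#' Inverse-frequency class weights
#'
#' `w_c = N / (K * n_c)` with `N` the total count and `K` the number of
#' classes; the weights multiply the per-class terms of the weighted
#' cross-entropy. Equal counts give all weights 1.
#'
#' @param counts Positive integer per-class counts (named or not).
#' @return A numeric weight vector, named like `counts`.
#' @examples
#' compute_class_weights(c(DRIL = 429, NO_DRIL = 394))
#' @export
compute_class_weights <- function(counts) {
  if (any(counts <= 0)) {
    stop("all class counts must be positive; a class is absent from the training data")
  }
  n <- sum(counts)
  k <- length(counts)
  n / (k * counts)
}

round_half_up <- function(x) floor(x + 0.5)

#' Stratified train/validation/test split
#'
#' Per-class allocation: a `test_frac` share of each class goes to the test
#' set (round half up), then `val_frac_of_train` of the remaining training
#' samples of each class (round half up) go to validation. The three index
#' sets are disjoint and exhaustive and preserve class proportions to
#' within rounding.
#'
#' @param labels A vector of class labels (factor or character).
#' @param test_frac Fraction of each class held out for testing
#'   (default 0.2).
#' @param val_frac_of_train Fraction of the remaining training samples per
#'   class carved out for validation (default 0.1).
#' @param seed Optional integer seed for a reproducible split.
#' @return An object of class `sbyol_split`: list with integer index
#'   vectors `train`, `val`, `test` and a tibble `assignment`
#'   (index, label, split).
#' @examples
#' s <- stratified_split(rep(c("DRIL", "NO_DRIL"), c(429, 394)), seed = 1)
#' length(s$test)  # 165
#' @export
stratified_split <- function(labels, test_frac = 0.2, val_frac_of_train = 0.1,
                             seed = NULL) {
  if (test_frac <= 0 || test_frac >= 1 || val_frac_of_train <= 0 ||
      val_frac_of_train >= 1) {
    stop("split fractions must lie strictly between 0 and 1")
  }
  labels <- as.character(labels)
  if (any(table(labels) < 2)) stop("need at least 2 samples per class")
  if (!is.null(seed)) set.seed(seed)
  train <- val <- test <- integer(0)
  for (cl in sort(unique(labels))) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    n_test <- round_half_up(length(idx) * test_frac)
    test <- c(test, idx[seq_len(n_test)])
    rest <- idx[-seq_len(n_test)]
    n_val <- round_half_up(length(rest) * val_frac_of_train)
    val <- c(val, rest[seq_len(n_val)])
    train <- c(train, rest[-seq_len(n_val)])
  }
  assignment <- tibble::tibble(
    index = c(train, val, test),
    label = labels[c(train, val, test)],
    split = rep(c("train", "val", "test"),
                c(length(train), length(val), length(test))))
  assignment <- dplyr::arrange(assignment, .data$index)
  structure(list(train = sort(train), val = sort(val), test = sort(test),
                 assignment = assignment),
            class = "sbyol_split")
}

#' @export
print.sbyol_split <- function(x, ...) {
  cat(sprintf("<sbyol_split> train %d / val %d / test %d\n",
              length(x$train), length(x$val), length(x$test)))
  invisible(x)
}

# ---- classifier -------------------------------------------------------------

make_head_arch <- function(in_dim, hidden, n_classes, dropout) {
  nn_seq(fc1 = nn_linear(in_dim, hidden), bn = nn_bn1d(hidden),
         relu = nn_relu(), drop = nn_dropout(dropout),
         fc2 = nn_linear(hidden, n_classes))
}

#' Build a DRIL classifier from a pretrained encoder
#'
#' Attaches a classification head — linear (2048 to 1280 by default), batch
#' norm, nonlinearity, dropout 0.5, linear to the class logits — to the
#' online encoder of a pretrained model. Head linear layers are
#' Kaiming-initialized with zero biases. The classifier starts in phase 1
#' (encoder frozen: only head parameters are trainable).
#'
#' @param pretrained An `sbyol_model` (its online encoder is used), an
#'   `sbyol_pretrain` result, or a bare `sbyol_encoder`.
#' @param hidden Head hidden width (default 1280).
#' @param dropout Head dropout probability (default 0.5).
#' @param n_classes Number of classes (default 2).
#' @param class_levels Character vector of class names in index order
#'   (default `c("DRIL", "NO_DRIL")`, the alphabetical manifest order).
#' @param seed Optional seed for head initialization.
#' @return An object of class `sbyol_classifier`.
#' @export
build_classifier <- function(pretrained, hidden = 1280L, dropout = 0.5,
                             n_classes = 2L,
                             class_levels = c("DRIL", "NO_DRIL"),
                             seed = NULL) {
  if (inherits(pretrained, "sbyol_pretrain")) pretrained <- pretrained$model
  if (inherits(pretrained, "sbyol_model")) {
    encoder <- pretrained$encoder
    enc_params <- pretrained$online$params$encoder
    enc_state <- pretrained$online$state$encoder
  } else if (inherits(pretrained, "sbyol_encoder")) {
    encoder <- pretrained
    enc_params <- pretrained$params
    enc_state <- pretrained$state
  } else {
    stop("pretrained must be an sbyol_model, sbyol_pretrain or sbyol_encoder")
  }
  if (!is.null(seed)) set.seed(seed)
  head_arch <- make_head_arch(encoder$c_s2, hidden, n_classes, dropout)
  head <- nn_init(head_arch)
  structure(list(encoder = encoder, head_arch = head_arch,
                 params = list(encoder = enc_params, head = head$params),
                 state = list(encoder = enc_state, head = head$state),
                 phase = 1L, hidden = hidden, n_classes = n_classes,
                 class_levels = class_levels),
            class = "sbyol_classifier")
}

#' @export
print.sbyol_classifier <- function(x, ...) {
  cat(sprintf("<sbyol_classifier> phase %d, classes: %s\n", x$phase,
              paste(x$class_levels, collapse = ", ")))
  cat(sprintf("  encoder parameters: %s%s\n",
              format(param_count(x$params$encoder), big.mark = ","),
              if (x$phase == 1L) " (frozen)" else ""))
  cat(sprintf("  head parameters:    %s\n",
              format(param_count(x$params$head), big.mark = ",")))
  invisible(x)
}

#' Trainable parameter count of a classifier
#'
#' In phase 1 only the head counts; in phase 2 everything does.
#'
#' @param clf An `sbyol_classifier`.
#' @return Number of trainable scalar parameters.
#' @export
trainable_param_count <- function(clf) {
  if (clf$phase == 1L) param_count(clf$params$head)
  else param_count(clf$params)
}

# Forward pass of the classifier on a transformed batch.
classifier_forward <- function(clf, x, training = FALSE, encoder_train = FALSE,
                               keep_cache = FALSE) {
  enc <- encoder_forward(clf$encoder, clf$params$encoder, clf$state$encoder,
                         x, training = encoder_train,
                         keep_cache = keep_cache && encoder_train)
  feats <- global_pool(enc$s2)
  hd <- nn_forward(clf$head_arch, clf$params$head, clf$state$head, feats,
                   training = training)
  list(logits = hd$out, feats = feats, s2dim = dim(enc$s2),
       enc_cache = enc$cache, head_cache = hd$cache,
       state = list(encoder = enc$state, head = hd$state))
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Weighted cross-entropy (weighted-mean convention): returns loss and the
# gradient with respect to the logits.
weighted_ce <- function(logits, y, weights = NULL) {
  n <- nrow(logits)
  k <- ncol(logits)
  if (is.null(weights)) weights <- rep(1, k)
  p <- softmax_rows(logits)
  wy <- weights[y]
  nll <- -log(pmax(p[cbind(seq_len(n), y)], 1e-12))
  loss <- sum(wy * nll) / sum(wy)
  onehot <- matrix(0, n, k)
  onehot[cbind(seq_len(n), y)] <- 1
  glogits <- (p - onehot) * (wy / sum(wy))
  list(loss = loss, glogits = glogits)
}

# One fine-tuning epoch over mini-batches. Returns updated classifier/opt
# and the epoch mean loss/accuracy.
make_batches <- function(idx, batch_size) {
  batches <- split(idx, ceiling(seq_along(idx) / batch_size))
  k <- length(batches)
  # a singleton remainder cannot be batch-normalized; fold it back
  if (k > 1 && length(batches[[k]]) < 2) {
    batches[[k - 1]] <- c(batches[[k - 1]], batches[[k]])
    batches[[k]] <- NULL
  }
  batches
}

finetune_epoch <- function(clf, x, y, opt, cfg, phase) {
  n <- dim(x)[4]
  idx <- sample.int(n)
  batches <- make_batches(idx, cfg$batch)
  tot_loss <- 0; tot_correct <- 0
  for (b in batches) {
    xb <- finetune_transform(x[, , , b, drop = FALSE], train_mode = TRUE,
                             size = cfg$size)
    yb <- y[b]
    fw <- classifier_forward(clf, xb, training = TRUE,
                             encoder_train = (phase == 2L),
                             keep_cache = (phase == 2L))
    ce <- weighted_ce(fw$logits, yb, cfg$class_weights)
    tot_loss <- tot_loss + ce$loss * length(b)
    tot_correct <- tot_correct +
      sum(max.col(fw$logits, ties.method = "first") == yb)

    hb <- nn_backward(clf$head_arch, clf$params$head, fw$head_cache,
                      ce$glogits, need_gx = (phase == 2L))
    grads <- list(head = hb$grads)
    if (phase == 2L) {
      d <- fw$s2dim
      hw <- d[1] * d[2]
      gs2 <- array(rep(as.vector(t(hb$gx / hw)), each = hw), dim = d)
      eb <- encoder_backward(clf$encoder, clf$params$encoder, fw$enc_cache,
                             gs1 = NULL, gs2 = gs2)
      grads <- list(encoder = eb$grads, head = hb$grads)
    }
    grads <- clip_grad_norm(grads, cfg$clip)

    if (phase == 2L) {
      r <- adamw_step(opt, clf$params[c("encoder", "head")], grads)
      clf$params <- r$params
    } else {
      r <- adamw_step(opt, clf$params["head"], grads)
      clf$params$head <- r$params$head
    }
    opt <- r$opt
    # BN state: head always trains; encoder BN stats move only in phase 2
    clf$state$head <- fw$state$head
    if (phase == 2L) clf$state$encoder <- fw$state$encoder
  }
  list(clf = clf, opt = opt, loss = tot_loss / n, acc = tot_correct / n)
}

eval_classifier_batch <- function(clf, x, y, cfg) {
  n <- dim(x)[4]
  batches <- split(seq_len(n), ceiling(seq_len(n) / cfg$batch))
  tot_loss <- 0; pred <- integer(n)
  for (b in batches) {
    xb <- finetune_transform(x[, , , b, drop = FALSE], train_mode = FALSE,
                             size = cfg$size)
    fw <- classifier_forward(clf, xb, training = FALSE, encoder_train = FALSE)
    ce <- weighted_ce(fw$logits, y[b], cfg$class_weights)
    tot_loss <- tot_loss + ce$loss * length(b)
    pred[b] <- max.col(fw$logits, ties.method = "first")
  }
  list(loss = tot_loss / n, acc = mean(pred == y), pred = pred)
}

run_finetune_phase <- function(clf, data, cfg, phase) {
  lr <- if (phase == 1L) cfg$lr_phase1 else cfg$lr_phase1 * 0.1
  trainables <- if (phase == 1L) clf$params["head"]
                else clf$params[c("encoder", "head")]
  opt <- adamw_init(trainables, lr = lr, weight_decay = cfg$weight_decay)
  sched <- plateau_init(lr, factor = cfg$plateau_factor,
                        patience = cfg$plateau_patience)
  epochs <- if (phase == 1L) cfg$epochs_phase1 else cfg$epochs_phase2
  best_acc <- -Inf
  best <- list(params = clf$params, state = clf$state)
  history <- vector("list", epochs)
  for (ep in seq_len(epochs)) {
    r <- finetune_epoch(clf, data$train_x, data$train_y, opt, cfg, phase)
    clf <- r$clf; opt <- r$opt
    ev <- eval_classifier_batch(clf, data$val_x, data$val_y, cfg)
    history[[ep]] <- tibble::tibble(
      phase = phase, epoch = ep, lr = opt$lr,
      train_loss = r$loss, train_acc = r$acc,
      val_loss = ev$loss, val_acc = ev$acc)
    if (ev$acc > best_acc) {
      best_acc <- ev$acc
      best <- list(params = clf$params, state = clf$state)
    }
    if (phase == 2L) {
      sched <- plateau_step(sched, ev$acc)
      opt$lr <- sched$lr
    }
  }
  clf$params <- best$params
  clf$state <- best$state
  list(clf = clf, history = dplyr::bind_rows(history), best_val_acc = best_acc)
}

prepare_finetune_data <- function(images, labels, split, class_levels) {
  y <- match(as.character(labels), class_levels)
  if (anyNA(y)) {
    stop("labels contain classes outside: ", paste(class_levels, collapse = ", "))
  }
  list(train_x = images[, , , split$train, drop = FALSE],
       train_y = y[split$train],
       val_x = images[, , , split$val, drop = FALSE],
       val_y = y[split$val],
       test_x = images[, , , split$test, drop = FALSE],
       test_y = y[split$test])
}

#' Phase-1 fine-tuning: train the head on a frozen encoder
#'
#' Only head parameters receive optimizer updates; the encoder runs in
#' inference mode with frozen batch-norm statistics, so its parameters and
#' state are bitwise unchanged after training. The head with the best
#' validation accuracy is retained.
#'
#' @param clf An `sbyol_classifier` (phase 1).
#' @param data A list with `train_x`, `train_y`, `val_x`, `val_y` (raw
#'   `[0, 1]` image arrays and integer class indices), as produced
#'   internally by [finetune_dril()].
#' @param config Overrides merged over [default_config()]'s `finetune`
#'   section.
#' @return List with the updated classifier, a history tibble and the best
#'   validation accuracy.
#' @export
finetune_phase1 <- function(clf, data, config = list()) {
  cfg <- utils::modifyList(default_config()$finetune, config)
  clf$phase <- 1L
  run_finetune_phase(clf, data, cfg, 1L)
}

#' Phase-2 fine-tuning: end-to-end training
#'
#' Unfreezes the encoder and trains all parameters at a learning rate
#' reduced by 90% relative to phase 1, with reduce-on-plateau halving on
#' stagnating validation accuracy and gradient clipping at norm 1.0.
#'
#' @inheritParams finetune_phase1
#' @return List with the updated classifier, a history tibble and the best
#'   validation accuracy.
#' @export
finetune_phase2 <- function(clf, data, config = list()) {
  cfg <- utils::modifyList(default_config()$finetune, config)
  clf$phase <- 2L
  run_finetune_phase(clf, data, cfg, 2L)
}

#' Full two-phase DRIL fine-tuning pipeline
#'
#' Splits the labeled data (stratified 80/20 with a 10% validation
#' carve-out from the training portion), computes inverse-frequency class
#' weights from the training labels, runs phase 1 (frozen encoder) then
#' phase 2 (end-to-end), and evaluates on the held-out test set.
#'
#' @param pretrained A pretrained `sbyol_model`, `sbyol_pretrain` or
#'   `sbyol_encoder`.
#' @param images A `(H, W, 3, N)` array in `[0, 1]`.
#' @param labels Class labels of length N (e.g. "DRIL"/"NO_DRIL").
#' @param config Overrides merged over [default_config()]'s `finetune`
#'   section (`hidden`, `dropout`, `lr_phase1`, `batch`, `size`,
#'   `epochs_phase1`, `epochs_phase2`, ...).
#' @param seed Seed controlling split, head init and augmentation.
#' @return An object of class `sbyol_finetune`: list with `classifier`,
#'   `history` (both phases), `split`, `report` (test-set
#'   [classification_report()]), and `test_pred`.
#' @export
finetune_dril <- function(pretrained, images, labels, config = list(),
                          seed = 1L) {
  cfg <- utils::modifyList(default_config()$finetune, config)
  class_levels <- sort(unique(as.character(labels)))
  split <- stratified_split(labels, cfg$test_frac, cfg$val_frac, seed = seed)
  data <- prepare_finetune_data(images, labels, split, class_levels)
  counts <- table(factor(class_levels[data$train_y], levels = class_levels))
  cfg$class_weights <- as.numeric(compute_class_weights(as.numeric(counts)))

  clf <- build_classifier(pretrained, hidden = cfg$hidden,
                          dropout = cfg$dropout,
                          n_classes = length(class_levels),
                          class_levels = class_levels, seed = seed)
  p1 <- finetune_phase1(clf, data, cfg)
  p2 <- finetune_phase2(p1$clf, data, cfg)
  ev <- eval_classifier_batch(p2$clf, data$test_x, data$test_y, cfg)
  report <- classification_report(class_levels[data$test_y],
                                  class_levels[ev$pred],
                                  positive = class_levels[1])
  structure(list(classifier = p2$clf,
                 history = dplyr::bind_rows(p1$history, p2$history),
                 split = split, report = report,
                 test_pred = class_levels[ev$pred], config = cfg),
            class = "sbyol_finetune")
}

#' @export
print.sbyol_finetune <- function(x, ...) {
  cat("<sbyol_finetune>\n")
  cat(sprintf("  epochs: %d (phase 1) + %d (phase 2)\n",
              sum(x$history$phase == 1), sum(x$history$phase == 2)))
  cat(sprintf("  test accuracy: %.4f\n", x$report$accuracy))
  invisible(x)
}

#' Predict DRIL classes for new images
#'
#' @param object An `sbyol_classifier`.
#' @param images A `(H, W, 3, N)` array in `[0, 1]`.
#' @param size Input side length fed to the encoder (default 224).
#' @param batch Mini-batch size.
#' @param ... Unused.
#' @return A tibble with predicted class, and one probability column per
#'   class level.
#' @export
predict.sbyol_classifier <- function(object, images, size = 224L,
                                     batch = 32L, ...) {
  n <- dim(images)[4]
  batches <- split(seq_len(n), ceiling(seq_len(n) / batch))
  probs <- matrix(0, n, object$n_classes)
  for (b in batches) {
    xb <- finetune_transform(images[, , , b, drop = FALSE],
                             train_mode = FALSE, size = size)
    fw <- classifier_forward(object, xb, training = FALSE)
    probs[b, ] <- softmax_rows(fw$logits)
  }
  colnames(probs) <- object$class_levels
  tibble::as_tibble(probs) |>
    dplyr::mutate(
      .pred_class = object$class_levels[max.col(probs, ties.method = "first")],
      .before = 1)
}
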