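# Broom-style tidiers and ggplot2 autoplot methods for the package's
# result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a Cohen's kappa result
#'
#' @param x An `sbyol_kappa`.
#' @param ... Unused.
#' @return A one-row tibble with estimate, confidence bounds, observed and
#'   expected agreement, and n.
#' @method tidy sbyol_kappa
#' @export
tidy.sbyol_kappa <- function(x, ...) {
  tibble::tibble(estimate = x$kappa, conf.low = x$ci_low,
                 conf.high = x$ci_high, std.error = x$se,
                 p.observed = x$p_observed, p.expected = x$p_expected,
                 n = x$n)
}

#' @rdname tidy.sbyol_kappa
#' @method glance sbyol_kappa
#' @export
glance.sbyol_kappa <- function(x, ...) tidy.sbyol_kappa(x, ...)

#' Tidy a classification report
#'
#' @param x An `sbyol_report`.
#' @param ... Unused.
#' @return A tibble with one row per metric (`metric`, `value`).
#' @method tidy sbyol_report
#' @export
tidy.sbyol_report <- function(x, ...) {
  tibble::tibble(
    metric = c("accuracy", "sensitivity", "specificity",
               "precision_weighted", "recall_weighted", "f1_weighted"),
    value = c(x$accuracy, x$sensitivity, x$specificity,
              x$precision_weighted, x$recall_weighted, x$f1_weighted))
}

#' @rdname tidy.sbyol_report
#' @method glance sbyol_report
#' @export
glance.sbyol_report <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, sensitivity = x$sensitivity,
                 specificity = x$specificity,
                 precision_weighted = x$precision_weighted,
                 recall_weighted = x$recall_weighted,
                 f1_weighted = x$f1_weighted, n = x$n)
}

#' Tidy pretraining history
#'
#' @param x An `sbyol_pretrain`.
#' @param ... Unused.
#' @return The per-epoch history tibble (epoch, lr, l_global, l_spatial,
#'   l_hybrid).
#' @method tidy sbyol_pretrain
#' @export
tidy.sbyol_pretrain <- function(x, ...) x$history

#' @rdname tidy.sbyol_pretrain
#' @method glance sbyol_pretrain
#' @export
glance.sbyol_pretrain <- function(x, ...) {
  tibble::tibble(epochs_run = nrow(x$history), best_epoch = x$best_epoch,
                 best_hybrid_loss = x$history$l_hybrid[x$best_epoch],
                 final_lr = x$history$lr[nrow(x$history)])
}

#' Tidy fine-tuning history
#'
#' @param x An `sbyol_finetune`.
#' @param ... Unused.
#' @return The per-epoch history tibble across both phases.
#' @method tidy sbyol_finetune
#' @export
tidy.sbyol_finetune <- function(x, ...) x$history

#' @rdname tidy.sbyol_finetune
#' @method glance sbyol_finetune
#' @export
glance.sbyol_finetune <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(epochs_phase1 = sum(x$history$phase == 1),
                   epochs_phase2 = sum(x$history$phase == 2)),
    glance.sbyol_report(x$report))
}

#' Plot pretraining loss curves
#'
#' @param object An `sbyol_pretrain`.
#' @param ... Unused.
#' @return A ggplot of the global, spatial and hybrid losses per epoch.
#' @method autoplot sbyol_pretrain
#' @export
autoplot.sbyol_pretrain <- function(object, ...) {
  df <- tidyr_longer_losses(object$history)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value,
                                   colour = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "loss", colour = NULL,
                  title = "Self-supervised pretraining") +
    ggplot2::theme_minimal()
}

tidyr_longer_losses <- function(history) {
  dplyr::bind_rows(lapply(c("l_global", "l_spatial", "l_hybrid"), function(nm) {
    tibble::tibble(epoch = history$epoch, loss = nm, value = history[[nm]])
  }))
}

#' Plot fine-tuning accuracy curves
#'
#' @param object An `sbyol_finetune`.
#' @param ... Unused.
#' @return A ggplot of train/validation accuracy per epoch, faceted by
#'   phase.
#' @method autoplot sbyol_finetune
#' @export
autoplot.sbyol_finetune <- function(object, ...) {
  h <- object$history
  df <- dplyr::bind_rows(
    tibble::tibble(phase = h$phase, epoch = h$epoch, set = "train",
                   accuracy = h$train_acc),
    tibble::tibble(phase = h$phase, epoch = h$epoch, set = "validation",
                   accuracy = h$val_acc))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$accuracy,
                                   colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~phase, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "epoch", y = "accuracy", colour = NULL,
                  title = "Two-phase DRIL fine-tuning") +
    ggplot2::theme_minimal()
}

#' Plot a confusion matrix
#'
#' @param object An `sbyol_report`.
#' @param ... Unused.
#' @return A ggplot tile chart of the 2x2 confusion counts.
#' @method autoplot sbyol_report
#' @export
autoplot.sbyol_report <- function(object, ...) {
  cm <- object$confusion
  df <- tibble::tibble(
    truth = rep(c(object$positive, object$negative), each = 2),
    prediction = rep(c(object$positive, object$negative), 2),
    count = c(cm["tp"], cm["fn"], cm["fp"], cm["tn"]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$prediction, y = .data$truth,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), colour = "white") +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(title = sprintf("Accuracy %.2f%%", 100 * object$accuracy)) +
    ggplot2::theme_minimal()
}

#' Four-panel inter-observer agreement figure
#'
#' Panels: (A) the 2x2 observer table, (B) agreement distribution, (C)
#' Cohen's kappa against conventional interpretation bands, (D) the
#' discordance pattern. Panels are combined when the patchwork package is
#' installed, otherwise returned as a list.
#'
#' @param object An `sbyol_agreement_table`.
#' @param ... Unused.
#' @return A patchwork object or a list of four ggplots.
#' @method autoplot sbyol_agreement_table
#' @export
autoplot.sbyol_agreement_table <- function(object, ...) {
  k <- cohen_kappa(object)
  s <- agreement_summary(object)
  cells <- tibble::tibble(
    obs1 = rep(c("positive", "negative"), each = 2),
    obs2 = rep(c("positive", "negative"), 2),
    count = c(object$a, object$b, object$c, object$d))
  pA <- ggplot2::ggplot(cells, ggplot2::aes(x = .data$obs2, y = .data$obs1,
                                            fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), colour = "white") +
    ggplot2::labs(title = "A: observer table", x = "observer 2",
                  y = "observer 1") +
    ggplot2::theme_minimal()
  dist <- dplyr::filter(s, .data$quantity %in%
                          c("both_positive", "both_negative", "discordant"))
  pB <- ggplot2::ggplot(dist, ggplot2::aes(x = .data$quantity,
                                           y = .data$fraction)) +
    ggplot2::geom_col() +
    ggplot2::labs(title = "B: agreement distribution", x = NULL,
                  y = "fraction") +
    ggplot2::theme_minimal()
  bands <- tibble::tibble(lo = c(0, 0.2, 0.4, 0.6, 0.8),
                          hi = c(0.2, 0.4, 0.6, 0.8, 1.0),
                          quality = c("poor", "fair", "moderate", "good",
                                      "excellent"))
  pC <- ggplot2::ggplot(bands) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$lo, xmax = .data$hi,
                                    ymin = 0, ymax = 1,
                                    fill = .data$quality), alpha = 0.5) +
    ggplot2::geom_vline(xintercept = k$kappa, linewidth = 1.2) +
    ggplot2::labs(title = sprintf("C: Cohen's kappa = %.3f", k$kappa),
                  x = "kappa", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
  disc <- dplyr::filter(s, .data$quantity %in%
                          c("obs1_pos_of_discordant", "obs2_pos_of_discordant"))
  pD <- ggplot2::ggplot(disc, ggplot2::aes(x = .data$quantity,
                                           y = .data$fraction)) +
    ggplot2::geom_col() +
    ggplot2::labs(title = "D: discordance pattern", x = NULL,
                  y = "fraction of conflicts") +
    ggplot2::theme_minimal()
  if (requireNamespace("patchwork", quietly = TRUE)) {
    (pA + pB) / (pC + pD)
  } else {
    list(pA, pB, pC, pD)
  }
}

#' Plot a Grad-CAM heatmap
#'
#' @param object An `sbyol_heatmap`.
#' @param ... Unused.
#' @return A ggplot raster of the normalized heatmap.
#' @method autoplot sbyol_heatmap
#' @export
autoplot.sbyol_heatmap <- function(object, ...) {
  v <- object$values
  df <- tibble::tibble(
    row = rep(seq_len(nrow(v)), times = ncol(v)),
    col = rep(seq_len(ncol(v)), each = nrow(v)),
    value = as.vector(v))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("Grad-CAM (%s, class %s)",
                                  object$layer_name, object$target_class),
                  x = NULL, y = NULL, fill = "activation") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
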