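# Clinical evaluation statistics: Cohen's kappa inter-observer agreement on
# a 2x2 table, agreement/discordance breakdowns, and confusion-matrix
# classification metrics with support-weighted averaging.

#' Construct a 2x2 observer agreement table
#'
#' Cell counts of two binary raters: `a` both positive, `b` observer 1
#' positive / observer 2 negative, `c` observer 1 negative / observer 2
#' positive, `d` both negative.
#'
#' @param a,b,c,d Nonnegative integer counts.
#' @return An object of class `sbyol_agreement_table`.
#' @examples
#' agreement_table(409, 16, 11, 387)
#' @export
agreement_table <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("agreement table cells must be nonnegative integers")
  }
  if (sum(counts) == 0) stop("agreement table is empty")
  structure(as.list(counts), n = sum(counts), class = "sbyol_agreement_table")
}

#' @export
print.sbyol_agreement_table <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(`observer 1` = c("positive", "negative"),
                              `observer 2` = c("positive", "negative")))
  print(m)
  invisible(x)
}

#' Cohen's kappa for two raters
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)` with
#' `p_o = (a + d) / n` the observed agreement and
#' `p_e = [(a+b)(a+c) + (c+d)(b+d)] / n^2` the marginal chance agreement.
#' The 95% confidence interval uses the simple asymptotic standard error
#' `sqrt(p_o (1 - p_o) / (n (1 - p_e)^2))` and is informational.
#'
#' @param table An `sbyol_agreement_table` (or a list with `a`, `b`, `c`,
#'   `d`).
#' @param conf_level Confidence level (default 0.95).
#' @return An object of class `sbyol_kappa`: list with `kappa`, `ci_low`,
#'   `ci_high`, `p_observed`, `p_expected`, `n`.
#' @examples
#' cohen_kappa(agreement_table(409, 16, 11, 387))$kappa  # 0.9343
#' @export
cohen_kappa <- function(table, conf_level = 0.95) {
  a <- table$a; b <- table$b; cc <- table$c; d <- table$d
  n <- a + b + cc + d
  if (n == 0) stop("empty agreement table")
  p_o <- (a + d) / n
  p_e <- ((a + b) * (a + cc) + (cc + d) * (b + d)) / n^2
  if (p_e >= 1) {
    stop("degenerate marginals (chance agreement 1): kappa is undefined")
  }
  kappa <- (p_o - p_e) / (1 - p_e)
  se <- sqrt(p_o * (1 - p_o) / (n * (1 - p_e)^2))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(list(kappa = kappa, ci_low = kappa - z * se,
                 ci_high = kappa + z * se, se = se,
                 p_observed = p_o, p_expected = p_e, n = n,
                 conf_level = conf_level),
            class = "sbyol_kappa")
}

#' @export
print.sbyol_kappa <- function(x, ...) {
  cat(sprintf("Cohen's kappa = %.4f (%d%% CI %.4f-%.4f), observed agreement %.1f%% (n = %d)\n",
              x$kappa, round(100 * x$conf_level), x$ci_low, x$ci_high,
              100 * x$p_observed, x$n))
  invisible(x)
}

#' Agreement and discordance breakdown of a 2x2 observer table
#'
#' Overall agreement fraction, each cell as a fraction of all ratings, and
#' each discordant cell as a fraction of the discordant subtotal (reported
#' as `NA` when there is no disagreement).
#'
#' @param table An `sbyol_agreement_table`.
#' @return A tibble with columns `quantity`, `count`, `fraction`.
#' @examples
#' agreement_summary(agreement_table(409, 16, 11, 387))
#' @export
agreement_summary <- function(table) {
  n <- attr(table, "n")
  disc <- table$b + table$c
  tibble::tibble(
    quantity = c("overall_agreement", "both_positive", "both_negative",
                 "obs1_pos_obs2_neg", "obs1_neg_obs2_pos",
                 "discordant", "obs1_pos_of_discordant",
                 "obs2_pos_of_discordant"),
    count = c(table$a + table$d, table$a, table$d, table$b, table$c,
              disc, table$b, table$c),
    fraction = c((table$a + table$d) / n, table$a / n, table$d / n,
                 table$b / n, table$c / n, disc / n,
                 if (disc > 0) table$b / disc else NA_real_,
                 if (disc > 0) table$c / disc else NA_real_))
}

#' Confusion-matrix classification report
#'
#' Binary evaluation with DRIL as the positive class: confusion counts,
#' accuracy, sensitivity (positive recall), specificity, and
#' support-weighted precision, recall and F1 (per-class metrics weighted by
#' the true class supports; weighted recall is identically the accuracy).
#'
#' @param y_true,y_pred Label vectors of equal length with exactly two
#'   distinct classes between them.
#' @param positive Name of the positive class (default `"DRIL"`; falls
#'   back to the alphabetically first label if absent).
#' @return An object of class `sbyol_report`: list with `confusion`
#'   (named counts tp, fn, fp, tn), `accuracy`, `sensitivity`,
#'   `specificity`, `precision_weighted`, `recall_weighted`,
#'   `f1_weighted`, `n`, `positive`.
#' @examples
#' # the printed test-set confusion matrix: TP 86, FN 0, FP 1, TN 77
#' y <- rep(c("DRIL", "NO_DRIL"), c(86, 78))
#' p <- c(rep("DRIL", 86), "DRIL", rep("NO_DRIL", 77))
#' classification_report(y, p)
#' @export
classification_report <- function(y_true, y_pred, positive = "DRIL") {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred have different lengths")
  }
  if (length(y_true) == 0) stop("empty label vectors")
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  classes <- sort(unique(c(y_true, y_pred)))
  if (length(classes) > 2) stop("classification_report expects binary labels")
  if (!positive %in% classes) positive <- classes[1]
  negative <- setdiff(classes, positive)
  if (length(negative) == 0) negative <- paste0("not_", positive)

  tp <- sum(y_true == positive & y_pred == positive)
  fn <- sum(y_true == positive & y_pred != positive)
  fp <- sum(y_true != positive & y_pred == positive)
  tn <- sum(y_true != positive & y_pred != positive)
  n <- tp + fn + fp + tn

  prec <- function(correct, predicted) if (predicted > 0) correct / predicted else 0
  rec <- function(correct, support) if (support > 0) correct / support else 0
  f1 <- function(p, r) if (p + r > 0) 2 * p * r / (p + r) else 0

  sup_pos <- tp + fn
  sup_neg <- tn + fp
  p_pos <- prec(tp, tp + fp); r_pos <- rec(tp, sup_pos)
  p_neg <- prec(tn, tn + fn); r_neg <- rec(tn, sup_neg)
  wavg <- function(vp, vn) (sup_pos * vp + sup_neg * vn) / n

  structure(list(
    confusion = c(tp = tp, fn = fn, fp = fp, tn = tn),
    accuracy = (tp + tn) / n,
    sensitivity = r_pos,
    specificity = rec(tn, sup_neg),
    precision_weighted = wavg(p_pos, p_neg),
    recall_weighted = wavg(r_pos, r_neg),
    f1_weighted = wavg(f1(p_pos, r_pos), f1(p_neg, r_neg)),
    n = n, positive = positive, negative = negative),
    class = "sbyol_report")
}

#' @export
print.sbyol_report <- function(x, ...) {
  cm <- x$confusion
  cat(sprintf("Classification report (positive class: %s, n = %d)\n",
              x$positive, x$n))
  cat(sprintf("  confusion: TP %d  FN %d  FP %d  TN %d\n",
              cm["tp"], cm["fn"], cm["fp"], cm["tn"]))
  cat(sprintf("  accuracy %.2f%%  sensitivity %.2f%%  specificity %.2f%%\n",
              100 * x$accuracy, 100 * x$sensitivity, 100 * x$specificity))
  cat(sprintf("  weighted: precision %.2f%%  recall %.2f%%  F1 %.2f%%\n",
              100 * x$precision_weighted, 100 * x$recall_weighted,
              100 * x$f1_weighted))
  invisible(x)
}
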