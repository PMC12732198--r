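# Agreement statistics and confusion-matrix metrics, checked against the
# closed-form definitions and a brute-force oracle.

test_that("kappa reproduces the printed inter-observer analysis", {
  tab <- agreement_table(409, 16, 11, 387)
  k <- cohen_kappa(tab)
  expect_equal(round(k$kappa, 4), 0.9343)
  expect_equal(round(k$p_observed, 4), 0.9672)
  expect_equal(k$p_observed, 796 / 823)
  expect_equal(k$p_expected, (425 * 420 + 398 * 403) / 823^2)
  expect_true(k$ci_low < k$kappa && k$kappa < k$ci_high)
})

test_that("kappa anchors: perfect, chance-level and degenerate tables", {
  expect_equal(cohen_kappa(agreement_table(40, 0, 0, 60))$kappa, 1)
  expect_equal(cohen_kappa(agreement_table(25, 25, 25, 25))$kappa, 0)
  # both raters always positive: p_e = 1, kappa undefined
  expect_error(cohen_kappa(agreement_table(50, 0, 0, 0)), "undefined|degenerate")
  expect_error(agreement_table(-1, 2, 3, 4), "nonnegative")
  expect_error(agreement_table(0, 0, 0, 0), "empty")
})

test_that("kappa is symmetric under observer swap and label relabeling", {
  set.seed(61)
  for (i in 1:25) {
    cts <- sample(0:60, 4, replace = TRUE)
    if (sum(cts) == 0) next
    tab <- agreement_table(cts[1], cts[2], cts[3], cts[4])
    swapped <- agreement_table(cts[1], cts[3], cts[2], cts[4])
    relabeled <- agreement_table(cts[4], cts[3], cts[2], cts[1])
    k <- tryCatch(cohen_kappa(tab)$kappa, error = function(e) NA)
    if (is.na(k)) next
    expect_equal(cohen_kappa(swapped)$kappa, k, tolerance = 1e-12)
    expect_equal(cohen_kappa(relabeled)$kappa, k, tolerance = 1e-12)
    expect_lte(k, 1)
    if (cts[2] + cts[3] > 0) expect_lt(k, 1)
  }
})

test_that("agreement summary reports the printed fractions", {
  s <- agreement_summary(agreement_table(409, 16, 11, 387))
  get <- function(q, col = "fraction") s[[col]][s$quantity == q]
  expect_equal(get("overall_agreement"), 796 / 823)
  expect_equal(round(get("overall_agreement"), 3), 0.967)
  expect_equal(round(get("obs1_pos_of_discordant"), 3), 0.593)  # 16/27
  expect_equal(get("discordant", "count"), 27)
  # no disagreement: discordance fractions reported as absent
  s0 <- agreement_summary(agreement_table(10, 0, 0, 10))
  expect_true(is.na(s0$fraction[s0$quantity == "obs1_pos_of_discordant"]))
})

test_that("classification report reproduces the printed test-set metrics", {
  y_true <- rep(c("DRIL", "NO_DRIL"), c(86, 78))
  y_pred <- c(rep("DRIL", 86), "DRIL", rep("NO_DRIL", 77))
  r <- classification_report(y_true, y_pred)
  expect_equal(r$confusion, c(tp = 86, fn = 0, fp = 1, tn = 77))
  expect_equal(r$accuracy, 163 / 164)
  expect_equal(round(100 * r$accuracy, 2), 99.39)
  expect_equal(r$sensitivity, 1.0)
  expect_equal(r$specificity, 77 / 78)
  expect_equal(round(100 * r$specificity, 2), 98.72)
  expect_equal(round(100 * r$precision_weighted, 2), 99.40)
  expect_equal(r$precision_weighted, (86 * (86 / 87) + 78 * 1) / 164)
})

test_that("degenerate and invalid report inputs are handled", {
  all_right <- classification_report(c("DRIL", "NO_DRIL"), c("DRIL", "NO_DRIL"))
  expect_equal(all_right$accuracy, 1)
  expect_equal(all_right$f1_weighted, 1)
  expect_error(classification_report(c("a", "b"), c("a")), "length")
  expect_error(classification_report(character(0), character(0)), "empty")
  expect_error(classification_report(c("a", "b", "c"), c("a", "b", "c")),
               "binary")
})

test_that("report matches a brute-force oracle on random label pairs", {
  set.seed(62)
  for (i in 1:100) {
    n <- sample(5:40, 1)
    y <- sample(c("DRIL", "NO_DRIL"), n, replace = TRUE)
    p <- sample(c("DRIL", "NO_DRIL"), n, replace = TRUE)
    if (length(unique(y)) < 2) next
    r <- classification_report(y, p)
    # independent elementwise computation
    acc <- mean(y == p)
    expect_equal(r$accuracy, acc)
    # support-weighted recall is identically the accuracy
    expect_equal(r$recall_weighted, acc, tolerance = 1e-12)
    # per-class oracle for weighted precision
    pw <- 0
    for (cl in c("DRIL", "NO_DRIL")) {
      sup <- sum(y == cl)
      prec <- if (sum(p == cl) > 0) sum(y == cl & p == cl) / sum(p == cl) else 0
      pw <- pw + sup * prec
    }
    expect_equal(r$precision_weighted, pw / n, tolerance = 1e-12)
  }
})

test_that("tidiers return the documented tabular forms", {
  k <- cohen_kappa(agreement_table(409, 16, 11, 387))
  tk <- tidy(k)
  expect_s3_class(tk, "tbl_df")
  expect_equal(tk$estimate, k$kappa)
  r <- classification_report(rep(c("DRIL", "NO_DRIL"), c(3, 3)),
                             rep(c("DRIL", "NO_DRIL"), c(3, 3)))
  tr <- tidy(r)
  expect_equal(nrow(tr), 6)
  expect_true(all(tr$value == 1))
  expect_equal(glance(r)$n, 6)
})

test_that("agreement and report figures build without error", {
  tab <- agreement_table(409, 16, 11, 387)
  p <- autoplot(tab)
  expect_true(inherits(p, "ggplot") || is.list(p))
  r <- classification_report(rep(c("DRIL", "NO_DRIL"), c(4, 4)),
                             rep(c("DRIL", "NO_DRIL"), c(4, 4)))
  expect_s3_class(autoplot(r), "ggplot")
})
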