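test_that("confusion construction matches the report built from a matrix", {
  fx <- paper_confusion_fixtures()$design1
  preds <- rep(rownames(fx), rowSums(fx))
  refs <- unlist(lapply(seq_len(nrow(fx)), function(i)
    rep(colnames(fx), fx[i, ])))
  rep1 <- confusion_and_metrics(preds, refs,
                                label_order = c("MFDM", "Control"))
  rep2 <- evaluation_report(fx)
  expect_equal(rep1$confusion, rep2$confusion, ignore_attr = TRUE)
  expect_equal(rep1$accuracy, rep2$accuracy)
  expect_equal(rep1$per_class, rep2$per_class)
  expect_error(confusion_and_metrics(character(0), character(0)), "non-empty")
  expect_error(confusion_and_metrics("A", "B", label_order = "A"), "outside")
})

test_that("perfect predictions give unit accuracy and balanced accuracy", {
  rep <- confusion_and_metrics(rep(c("A", "B", "C"), 5),
                               rep(c("A", "B", "C"), 5))
  expect_equal(rep$accuracy, 1)
  expect_true(all(rep$per_class$balanced_accuracy == 1))
  expect_equal(unname(rep$ci[["upper"]]), 1)
})

test_that("exact binomial interval matches a tail-probability bisection oracle", {
  bisect <- function(f, lo, hi) {
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (f(mid) > 0) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  x <- 13; n <- 16; a <- 0.05
  lower <- bisect(function(p) stats::pbinom(x - 1, n, p) - (1 - a / 2), 0, 1)
  upper <- bisect(function(p) stats::pbinom(x, n, p) - a / 2, 0, 1)
  ci <- exact_binomial_ci(x, n)
  expect_equal(unname(ci[["lower"]]), lower, tolerance = 1e-6)
  expect_equal(unname(ci[["upper"]]), upper, tolerance = 1e-6)
  expect_equal(unname(exact_binomial_ci(32, 32)[["upper"]]), 1)
  expect_equal(unname(exact_binomial_ci(0, 10)[["lower"]]), 0)
  expect_error(exact_binomial_ci(5, 4), "successes")
})

test_that("exact interval covers the truth at least nominally", {
  p <- 0.8; n <- 30
  covered <- 0
  withr::with_seed(101, draws <- stats::rbinom(500, n, p))
  for (x in draws) {
    ci <- exact_binomial_ci(x, n)
    covered <- covered + (ci[["lower"]] <= p && p <= ci[["upper"]])
  }
  expect_gte(covered / 500, 0.95)
})

test_that("the NIR test is calibrated and matches direct summation", {
  refs <- rep(c("A", "B"), c(60, 40))
  center <- nir_test(60, 100, refs)
  expect_gt(center$p.value, 0.4)
  small <- nir_test(4, 5, rep(c("A", "B"), c(3, 2)))
  expect_equal(small$nir, 0.6)
  expect_equal(small$p.value, sum(stats::dbinom(4:5, 5, 0.6)),
               tolerance = 1e-12)
})

test_that("rank AUC handles perfect, random, tied and absent classes", {
  n <- 2000
  withr::with_seed(102, {
    refs <- sample(c("A", "B"), n, replace = TRUE)
    s_perfect <- cbind(A = as.numeric(refs == "A"),
                       B = as.numeric(refs == "B"))
    s_random <- cbind(A = stats::runif(n), B = stats::runif(n))
  })
  expect_equal(unname(roc_auc_one_vs_all(s_perfect, refs)$auc), c(1, 1))
  auc_r <- roc_auc_one_vs_all(s_random, refs)$auc
  expect_lt(max(abs(auc_r - 0.5)), 0.03)
  s_const <- cbind(A = rep(0.5, 10), B = rep(0.5, 10))
  expect_equal(unname(roc_auc_one_vs_all(s_const,
                                         rep(c("A", "B"), 5))$auc), c(0.5, 0.5))
  w <- capture_warnings(
    out <- roc_auc_one_vs_all(cbind(A = stats::runif(5), C = stats::runif(5)),
                              rep("A", 5)))
  expect_match(w, "absent|undefined", all = TRUE)
  expect_true(is.na(out$auc[["C"]]))
  expect_true(is.na(out$auc[["A"]]))   # no negatives for A either
})

test_that("AUC is invariant under strictly monotone score transforms", {
  withr::with_seed(103, {
    refs <- sample(c("A", "B"), 300, replace = TRUE)
    s <- stats::rnorm(300) + (refs == "A")
  })
  m1 <- roc_auc_one_vs_all(cbind(A = s, B = -s), refs)$auc
  m2 <- roc_auc_one_vs_all(cbind(A = exp(2 * s), B = -exp(2 * s)), refs)$auc
  expect_equal(m1, m2, tolerance = 1e-12)
})

test_that("rank AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(104, {
    refs <- sample(c("A", "B"), 150, replace = TRUE)
    s <- stats::rnorm(150) + 0.8 * (refs == "A")
  })
  ours <- roc_auc_one_vs_all(cbind(A = s, B = -s), refs)$auc[["A"]]
  theirs <- as.numeric(pROC::auc(pROC::roc(
    response = refs, predictor = s, levels = c("B", "A"),
    direction = "<", quiet = TRUE)))
  expect_equal(ours, theirs, tolerance = 1e-12)
})

test_that("ICC(2,1) matches hand-computed ANOVA mean squares", {
  m <- cbind(r1 = c(9, 6, 8, 7, 10, 6), r2 = c(2, 1, 4, 1, 5, 2))
  # two-way ANOVA by hand
  n <- 6; k <- 2; grand <- mean(m)
  ss_rows <- k * sum((rowMeans(m) - grand)^2)
  ss_cols <- n * sum((colMeans(m) - grand)^2)
  ss_err <- sum((m - grand)^2) - ss_rows - ss_cols
  ms_r <- ss_rows / (n - 1)
  ms_c <- ss_cols / (k - 1)
  ms_e <- ss_err / ((n - 1) * (k - 1))
  expected <- (ms_r - ms_e) / (ms_r + ms_e + 2 * (ms_c - ms_e) / n)
  out <- icc_two_raters(m)
  expect_equal(out$icc, expected, tolerance = 1e-12)
  expect_equal(out$ms_rows, ms_r)
})

test_that("ICC is one for identical raters and near zero for independent ones", {
  withr::with_seed(105, x <- stats::rnorm(50, 10, 2))
  expect_equal(icc_two_raters(cbind(x, x))$icc, 1, tolerance = 1e-12)
  withr::with_seed(106, {
    a <- stats::rnorm(500); b <- stats::rnorm(500)
  })
  expect_lt(abs(icc_two_raters(cbind(a, b))$icc), 0.1)
  expect_true(icc_two_raters(cbind(rep(1, 5), rep(1, 5)))$degenerate)
})

test_that("half-up rounding matches the display convention", {
  expect_equal(round_half_up(0.8125, 3), 0.813)
  expect_equal(round_half_up(0.0025404, 3), 0.003)
  expect_equal(round_half_up(-0.8125, 3), -0.813)
})
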