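# Evaluation engine: confusion matrices and every derived metric, exact
# binomial intervals, the no-information-rate test, one-vs-all ROC/AUC, and
# the two-rater ICC.

#' Half-up rounding for report display
#'
#' Rounds halves away from zero (`0.8125 -> 0.813` at 3 digits), the
#' convention used for displayed metric tables, unlike base `round()`'s
#' round-half-to-even.
#'
#' @param x numeric vector.
#' @param digits decimal places (default 3).
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 3) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Bounds from Beta quantiles: lower = BetaInv(alpha/2; x, n-x+1) (0 when
#' x = 0), upper = BetaInv(1-alpha/2; x+1, n-x) (1 when x = n).
#'
#' @param successes,trials non-negative counts, `successes <= trials`.
#' @param confidence confidence level (default 0.95).
#' @return Named numeric vector `c(lower, upper)`.
#' @export
exact_binomial_ci <- function(successes, trials, confidence = 0.95) {
  if (trials < 1 || successes < 0 || successes > trials)
    stop("need 0 <= successes <= trials, trials >= 1.", call. = FALSE)
  a <- 1 - confidence
  lower <- if (successes == 0) 0 else
    stats::qbeta(a / 2, successes, trials - successes + 1)
  upper <- if (successes == trials) 1 else
    stats::qbeta(1 - a / 2, successes + 1, trials - successes)
  c(lower = lower, upper = upper)
}

#' One-sided no-information-rate test
#'
#' The no-information rate (NIR) is the accuracy achieved by always
#' predicting the most frequent reference class. The test p-value is
#' `P(X >= successes)` for `X ~ Binomial(trials, NIR)`, one-sided.
#'
#' @param successes,trials accuracy counts.
#' @param references reference label vector (defines the NIR).
#' @return List with `nir` and `p.value`.
#' @export
nir_test <- function(successes, trials, references) {
  if (trials < 1 || successes < 0 || successes > trials)
    stop("need 0 <= successes <= trials, trials >= 1.", call. = FALSE)
  nir <- max(table(references)) / length(references)
  p <- stats::pbinom(successes - 1, trials, nir, lower.tail = FALSE)
  list(nir = nir, p.value = p)
}

#' Confusion matrix and all derived classification metrics
#'
#' Builds the confusion matrix with prediction rows and reference columns and
#' derives overall accuracy with its exact 95% interval and NIR test, and the
#' per-class one-vs-all sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`,
#' balanced accuracy `(Se+Sp)/2`, precision, recall and F1. For binary
#' problems the headline sensitivity/specificity pair is reported for the
#' positive class taken as the alphabetically first label — so in an
#' MFDM-vs-control design the positive class is "control", the reverse of
#' clinical intuition but the convention under which the published binary
#' table reads Se = 1.000 / Sp = 0.909. When per-class probability `scores`
#' are supplied, one-vs-all ROC curves and AUCs are attached.
#'
#' @param predictions,references equal-length label vectors, values within
#'   `label_order`.
#' @param label_order label order for the matrix rows/columns (defaults to
#'   the sorted union).
#' @param scores optional n x K matrix of per-class probabilities (columns
#'   named by class) for ROC/AUC.
#' @param confidence confidence level of the accuracy interval.
#' @return An object of class `evaluation_report`.
#' @export
confusion_and_metrics <- function(predictions, references, label_order = NULL,
                                  scores = NULL, confidence = 0.95) {
  predictions <- as.character(predictions)
  references <- as.character(references)
  if (length(predictions) == 0 || length(predictions) != length(references))
    stop("predictions and references must be non-empty and equal length.",
         call. = FALSE)
  if (is.null(label_order))
    label_order <- sort(unique(c(predictions, references)))
  if (!all(c(predictions, references) %in% label_order))
    stop("labels outside `label_order`.", call. = FALSE)
  cm <- table(factor(predictions, levels = label_order),
              factor(references, levels = label_order))
  names(dimnames(cm)) <- c("prediction", "reference")
  evaluation_report(as.matrix(unclass(cm)), scores = scores,
                    references = references, confidence = confidence)
}

#' Build an evaluation report from a confusion matrix
#'
#' Same derivations as [confusion_and_metrics()], starting from an already
#' tabulated prediction x reference matrix (e.g. a published one).
#'
#' @param cm square integer matrix, prediction rows x reference columns,
#'   with dimnames.
#' @param scores,references optional, for ROC/AUC (as in
#'   [confusion_and_metrics()]; `references` defaults to the matrix column
#'   expansion).
#' @param confidence confidence level of the accuracy interval.
#' @return An object of class `evaluation_report`: list with `confusion`,
#'   `labels`, `accuracy`, `ci`, `nir`, `nir_p`, `per_class` (tibble),
#'   `positive_class` (binary only), `auc`, `roc` (when scores given).
#' @export
evaluation_report <- function(cm, scores = NULL, references = NULL,
                              confidence = 0.95) {
  cm <- as.matrix(cm)
  if (nrow(cm) != ncol(cm) || any(cm < 0))
    stop("`cm` must be a square non-negative matrix.", call. = FALSE)
  labels <- colnames(cm)
  total <- sum(cm)
  correct <- sum(diag(cm))
  accuracy <- correct / total
  ci <- exact_binomial_ci(correct, total, confidence)
  if (is.null(references)) references <- rep(labels, colSums(cm))
  nt <- nir_test(correct, total, references)

  per_class <- purrr::map_dfr(seq_along(labels), function(j) {
    tp <- cm[j, j]
    fn <- sum(cm[, j]) - tp
    fp <- sum(cm[j, ]) - tp
    tn <- total - tp - fn - fp
    se <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    sp <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
    prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    f1 <- if (!is.na(prec) && !is.na(se) && prec + se > 0)
      2 * prec * se / (prec + se) else NA_real_
    tibble::tibble(class = labels[j], sensitivity = se, specificity = sp,
                   balanced_accuracy = (se + sp) / 2, precision = prec,
                   recall = se, f1 = f1)
  })

  positive_class <- if (length(labels) == 2L) sort(labels)[1] else NA_character_

  out <- structure(
    list(confusion = cm, labels = labels, accuracy = accuracy,
         ci = ci, nir = nt$nir, nir_p = nt$p.value, per_class = per_class,
         positive_class = positive_class, confidence = confidence,
         auc = NULL, roc = NULL),
    class = "evaluation_report"
  )
  if (!is.null(scores)) {
    ra <- roc_auc_one_vs_all(scores, references)
    out$auc <- ra$auc
    out$roc <- ra$roc
  }
  out
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>\n")
  print(x$confusion)
  cat(sprintf("accuracy %.3f [%.3f-%.3f], NIR %.3f (p = %.3g)\n",
              x$accuracy, x$ci[["lower"]], x$ci[["upper"]], x$nir, x$nir_p))
  if (!is.na(x$positive_class)) {
    pc <- x$per_class[x$per_class$class == x$positive_class, ]
    cat(sprintf("binary (positive class %s): Se %.3f, Sp %.3f, balanced accuracy %.3f\n",
                x$positive_class, pc$sensitivity, pc$specificity,
                pc$balanced_accuracy))
  }
  print(as.data.frame(x$per_class), digits = 3)
  if (!is.null(x$auc)) {
    cat("one-vs-all AUC:",
        paste(sprintf("%s=%.3f", names(x$auc), x$auc), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
tidy.evaluation_report <- function(x, ...) {
  out <- x$per_class
  if (!is.null(x$auc)) out$auc <- unname(x$auc[out$class])
  out
}

#' @export
glance.evaluation_report <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, ci_lower = x$ci[["lower"]],
                 ci_upper = x$ci[["upper"]], nir = x$nir, nir_p = x$nir_p,
                 n = sum(x$confusion), n_classes = length(x$labels))
}

#' One-vs-all ROC curves and AUC
#'
#' For each class, ranks the class's probability column against the
#' indicator "reference == class" and computes the empirical ROC and the
#' rank-based (Mann-Whitney) AUC with ties counted one half. Classes absent
#' from the references get `NA` AUC with a warning.
#'
#' @param scores n x K probability (or score) matrix, columns named by class.
#' @param references reference label vector of length n.
#' @return List with `auc` (named vector) and `roc` (tibble: `class`, `fpr`,
#'   `tpr`, `threshold`).
#' @export
roc_auc_one_vs_all <- function(scores, references) {
  scores <- as.matrix(scores)
  references <- as.character(references)
  if (nrow(scores) != length(references))
    stop("probability rows must align with references.", call. = FALSE)
  if (is.null(colnames(scores)))
    stop("`scores` must have class-named columns.", call. = FALSE)
  classes <- colnames(scores)
  auc <- stats::setNames(rep(NA_real_, length(classes)), classes)
  roc_rows <- list()
  for (cl in classes) {
    pos <- references == cl
    n1 <- sum(pos); n0 <- sum(!pos)
    if (n1 == 0 || n0 == 0) {
      warning("class '", cl, "' absent from references (or no negatives); ",
              "AUC undefined.", call. = FALSE)
      next
    }
    s <- scores[, cl]
    r <- rank(s, ties.method = "average")
    auc[cl] <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    th <- c(Inf, sort(unique(s), decreasing = TRUE))
    pts <- purrr::map_dfr(th, function(t) {
      tibble::tibble(class = cl, threshold = t,
                     fpr = sum(s[!pos] >= t) / n0,
                     tpr = sum(s[pos] >= t) / n1)
    })
    roc_rows[[cl]] <- pts
  }
  list(auc = auc, roc = dplyr::bind_rows(roc_rows))
}

#' Two-way random-effects intraclass correlation, ICC(2,1)
#'
#' Single-rater, absolute-agreement ICC from the two-way ANOVA
#' decomposition: `(MS_R - MS_E) / (MS_R + MS_E + 2 (MS_C - MS_E) / n)` for
#' two raters, where MS_R, MS_C, MS_E are the row (item), column (rater) and
#' error mean squares.
#'
#' @param measurements numeric n x 2 matrix: one row per item, one column per
#'   rater, no missing cells.
#' @return List with `icc`, the mean squares, and `degenerate` (`TRUE` when
#'   the total variance is zero).
#' @export
icc_two_raters <- function(measurements) {
  m <- as.matrix(measurements)
  if (ncol(m) != 2L || nrow(m) < 2L || !all(is.finite(m)))
    stop("`measurements` must be a complete n x 2 numeric matrix, n >= 2.",
         call. = FALSE)
  n <- nrow(m); k <- 2L
  grand <- mean(m)
  if (stats::var(as.vector(m)) < .Machine$double.eps)
    return(list(icc = NA_real_, ms_rows = 0, ms_cols = 0, ms_error = 0,
                degenerate = TRUE))
  row_means <- rowMeans(m)
  col_means <- colMeans(m)
  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  ss_total <- sum((m - grand)^2)
  ss_error <- ss_total - ss_rows - ss_cols
  ms_r <- ss_rows / (n - 1)
  ms_c <- ss_cols / (k - 1)
  ms_e <- ss_error / ((n - 1) * (k - 1))
  icc <- (ms_r - ms_e) / (ms_r + ms_e + 2 * (ms_c - ms_e) / n)
  list(icc = icc, ms_rows = ms_r, ms_cols = ms_c, ms_error = ms_e,
       degenerate = FALSE)
}
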