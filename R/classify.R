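# Feature assembly and the gradient-boosted classifier for the four study
# designs.

#' Classification design specification
#'
#' The four designs: 1 — MFDM vs control (binary, shape residuals only);
#' 2.1 — MFDM vs control and the differential diagnoses (five classes);
#' 2.2 — MFDM vs the differential diagnoses (no controls); 3 — genotype
#' classes within MFDM. Designs 2.1 and 2.2 include the patient-level
#' severity and asymmetry scores by default, design 1 and 3 do not (the
#' configurations with the best reported performance).
#'
#' @param id one of `"1"`, `"2.1"`, `"2.2"`, `"3"`.
#' @param include_scores override the design's default.
#' @return An object of class `design_spec`: list with `id`, `labels`,
#'   `label_var` (`"group"` or `"genotype_class"`), `include_scores`.
#' @export
design_spec <- function(id = c("1", "2.1", "2.2", "3"), include_scores = NULL) {
  id <- match.arg(as.character(id), c("1", "2.1", "2.2", "3"))
  spec <- switch(id,
    "1" = list(labels = c("MFDM", "control"), label_var = "group",
               include_scores = FALSE),
    "2.1" = list(labels = c("MFDM", "control", "CHARGE", "TC", "NAFD"),
                 label_var = "group", include_scores = TRUE),
    "2.2" = list(labels = c("MFDM", "CHARGE", "TC", "NAFD"),
                 label_var = "group", include_scores = TRUE),
    "3" = list(labels = c("splice", "frameshift", "nonsense", "deletion"),
               label_var = "genotype_class", include_scores = FALSE)
  )
  if (!is.null(include_scores)) spec$include_scores <- isTRUE(include_scores)
  structure(c(list(id = id), spec), class = "design_spec")
}

#' @export
print.design_spec <- function(x, ...) {
  cat(sprintf("<design_spec %s> labels: %s; scores %sincluded\n", x$id,
              paste(x$labels, collapse = "/"),
              if (x$include_scores) "" else "not "))
  invisible(x)
}

#' Assemble the classifier's feature table for a design
#'
#' One row per ear: the k mixed-model residual columns, plus the patient's
#' severity and asymmetry scores when the design includes them (patient
#' scores are broadcast to the patient's ear rows). Rows outside the design's
#' label set, and rows missing a required feature (e.g. a patient whose
#' contralateral ear was never observed, so no scores exist), are dropped
#' with a message. Design 3 is restricted to MFDM ears and labelled by
#' genotype class.
#'
#' @param residuals tibble of residual columns `PC1..PCk` (one row per ear).
#' @param meta tibble aligned with `residuals`: `patient_id`, `group`,
#'   `genotype_class`.
#' @param scores [patient_scores()] table (required if the design includes
#'   scores).
#' @param design a [design_spec()].
#' @return An object of class `design_features`: list with `features`
#'   (numeric matrix), `labels` (factor with the design's levels), `meta`
#'   (tibble of retained rows), `design`.
#' @export
assemble_features <- function(residuals, meta, scores = NULL,
                              design = design_spec("1")) {
  stopifnot(inherits(design, "design_spec"))
  if (nrow(residuals) != nrow(meta))
    stop("`residuals` and `meta` must align row-wise.", call. = FALSE)
  lab <- meta[[design$label_var]]
  if (design$id == "3") {
    keep <- meta$group == "MFDM" & lab %in% design$labels
    if (!any(keep))
      stop("design 3 requires MFDM ears with genotype labels.", call. = FALSE)
  } else {
    keep <- lab %in% design$labels
  }
  feat <- as.matrix(residuals)
  if (design$include_scores) {
    if (is.null(scores))
      stop("this design includes scores: pass `scores`.", call. = FALSE)
    m <- match(meta$patient_id, scores$patient_id)
    feat <- cbind(feat, severity = scores$severity[m],
                  asymmetry = scores$asymmetry[m])
  }
  ok <- keep & stats::complete.cases(feat)
  dropped <- sum(keep) - sum(ok)
  if (dropped > 0)
    message(dropped, " row(s) dropped for missing required features.")
  if (!any(ok)) stop("no usable rows for this design.", call. = FALSE)
  structure(
    list(features = feat[ok, , drop = FALSE],
         labels = factor(lab[ok], levels = design$labels),
         meta = meta[ok, , drop = FALSE],
         design = design),
    class = "design_features"
  )
}

make_stratified_folds <- function(labels, n_folds, seed) {
  withr::with_seed(seed, {
    folds <- vector("list", n_folds)
    for (lev in levels(labels)) {
      idx <- sample(which(labels == lev))
      assign_to <- rep_len(sample(n_folds), length(idx))
      for (f in seq_len(n_folds))
        folds[[f]] <- c(folds[[f]], idx[assign_to == f])
    }
    lapply(folds, sort)
  })
}

#' Train the gradient-boosted syndrome classifier
#'
#' XGBoost with multinomial log-loss (softprob), learning rate 0.3, gamma 0,
#' maximum tree depth 6. Stratified k-fold cross-validation (seeded fold
#' construction) evaluates the log-loss at every boosting round up to
#' `max_rounds`; the final model is refit on all rows at the round minimizing
#' the mean CV log-loss. If some class has fewer members than `n_folds`, the
#' fold count is reduced with a warning. Fully reproducible given the seed.
#'
#' @param features a [assemble_features()] result, or a numeric matrix (then
#'   pass `labels`).
#' @param labels factor of class labels (ignored when `features` is a
#'   `design_features`).
#' @param n_folds CV folds (default 5).
#' @param seed integer seed for folds and tree construction.
#' @param learning_rate,gamma,max_depth,max_rounds boosting hyperparameters.
#' @return An object of class `ear_classifier`: the fitted booster, the
#'   chosen iteration, the CV log-loss curve, feature names, label levels,
#'   the design (if any) and the seed.
#' @export
train_classifier <- function(features, labels = NULL, n_folds = 5L, seed = 0L,
                             learning_rate = 0.3, gamma = 0, max_depth = 6L,
                             max_rounds = 500L) {
  design <- NULL
  if (inherits(features, "design_features")) {
    design <- features$design
    labels <- features$labels
    features <- features$features
  }
  labels <- droplevels(factor(labels))
  lev <- levels(labels)
  if (length(lev) < 2L)
    stop("need at least two classes to train.", call. = FALSE)
  class_n <- table(labels)
  if (min(class_n) < n_folds) {
    n_folds <- max(2L, as.integer(min(class_n)))
    warning("smallest class has ", min(class_n),
            " rows; reducing to ", n_folds, " folds.", call. = FALSE)
  }
  x <- as.matrix(features)
  y <- as.integer(labels) - 1L
  params <- list(objective = "multi:softprob", num_class = length(lev),
                 eta = learning_rate, gamma = gamma, max_depth = max_depth,
                 eval_metric = "mlogloss", nthread = 1L, seed = seed)
  folds <- make_stratified_folds(labels, n_folds, seed)
  dtrain <- xgboost::xgb.DMatrix(x, label = y)
  withr::with_seed(seed, {
    cv <- xgboost::xgb.cv(params = params, data = dtrain, nrounds = max_rounds,
                          folds = folds, verbose = 0,
                          early_stopping_rounds = 25L)
    curve <- cv$evaluation_log$test_mlogloss_mean
    best_iter <- which.min(curve)
    model <- xgboost::xgb.train(params = params, data = dtrain,
                                nrounds = best_iter, verbose = 0)
  })
  structure(
    list(model = model, best_iteration = best_iter, cv_logloss = curve,
         feature_names = colnames(x), levels = lev, design = design,
         seed = seed, n_folds = n_folds,
         hyperparameters = list(learning_rate = learning_rate, gamma = gamma,
                                max_depth = max_depth,
                                max_rounds = max_rounds)),
    class = "ear_classifier"
  )
}

#' @export
print.ear_classifier <- function(x, ...) {
  cat(sprintf("<ear_classifier>%s %d classes (%s), %d features\n",
              if (is.null(x$design)) "" else sprintf(" design %s:", x$design$id),
              length(x$levels), paste(x$levels, collapse = "/"),
              length(x$feature_names)))
  cat(sprintf("  chosen iteration %d (CV logloss %.4f, %d-fold), seed %d\n",
              x$best_iteration, min(x$cv_logloss), x$n_folds, x$seed))
  invisible(x)
}

#' @export
tidy.ear_classifier <- function(x, ...) {
  tibble::tibble(iteration = seq_along(x$cv_logloss),
                 cv_logloss = x$cv_logloss,
                 chosen = seq_along(x$cv_logloss) == x$best_iteration)
}

#' @export
glance.ear_classifier <- function(x, ...) {
  tibble::tibble(design = if (is.null(x$design)) NA_character_ else x$design$id,
                 n_classes = length(x$levels),
                 n_features = length(x$feature_names),
                 best_iteration = x$best_iteration,
                 cv_logloss = min(x$cv_logloss),
                 seed = x$seed)
}

check_features <- function(bundle, features) {
  if (inherits(features, "design_features")) features <- features$features
  features <- as.matrix(features)
  if (is.null(colnames(features)) ||
      !identical(colnames(features), bundle$feature_names))
    stop("feature columns do not match the trained model (expected: ",
         paste(bundle$feature_names, collapse = ", "), ").", call. = FALSE)
  features
}

#' Per-class predicted probabilities
#'
#' @param bundle an [train_classifier()] result.
#' @param features matrix (or `design_features`) with the same columns the
#'   model was trained on.
#' @return n x K matrix of probabilities; rows sum to 1.
#' @export
predict_proba <- function(bundle, features) {
  stopifnot(inherits(bundle, "ear_classifier"))
  x <- check_features(bundle, features)
  p <- stats::predict(bundle$model, xgboost::xgb.DMatrix(x))
  p <- matrix(p, nrow = nrow(x), ncol = length(bundle$levels), byrow = FALSE)
  colnames(p) <- bundle$levels
  p
}

#' Predicted class labels
#'
#' Argmax of [predict_proba()]; ties broken in favour of the earlier label in
#' the model's level order.
#'
#' @inheritParams predict_proba
#' @return Factor with the model's levels.
#' @export
predict_label <- function(bundle, features) {
  p <- predict_proba(bundle, features)
  factor(bundle$levels[apply(p, 1, which.max)], levels = bundle$levels)
}
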