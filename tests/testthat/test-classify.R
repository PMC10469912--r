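make_residual_fixture <- function(seed, n_per_class = 40, k = 4,
                                  classes = c("MFDM", "control"),
                                  separation = 3) {
  withr::with_seed(seed, {
    n <- n_per_class * length(classes)
    lab <- rep(classes, each = n_per_class)
    x <- matrix(stats::rnorm(n * k), n, k,
                dimnames = list(NULL, paste0("PC", seq_len(k))))
    for (i in seq_along(classes)) {
      x[lab == classes[i], 1] <- x[lab == classes[i], 1] + separation * (i - 1)
      x[lab == classes[i], 2] <- x[lab == classes[i], 2] +
        separation * ((i - 1) %% 2)
    }
    meta <- tibble::tibble(
      patient_id = sprintf("p%04d", seq_len(n)),
      group = lab,
      genotype_class = ifelse(lab == "MFDM",
                              sample(c("splice", "frameshift"), n, TRUE),
                              "none"))
    list(residuals = tibble::as_tibble(x), meta = meta, labels = lab)
  })
}

test_that("design specifications carry the study's label sets and defaults", {
  d1 <- design_spec("1")
  expect_equal(d1$labels, c("MFDM", "control"))
  expect_false(d1$include_scores)
  d21 <- design_spec("2.1")
  expect_length(d21$labels, 5)
  expect_true(d21$include_scores)
  d22 <- design_spec("2.2")
  expect_false("control" %in% d22$labels)
  d3 <- design_spec("3")
  expect_equal(d3$label_var, "genotype_class")
  expect_true(design_spec("1", include_scores = TRUE)$include_scores)
})

test_that("feature assembly yields k columns, or k+2 with scores", {
  fx <- make_residual_fixture(91, k = 8)
  f1 <- assemble_features(fx$residuals, fx$meta, design = design_spec("1"))
  expect_equal(ncol(f1$features), 8)
  scores <- tibble::tibble(patient_id = fx$meta$patient_id,
                           severity = stats::rpois(nrow(fx$meta), 1),
                           asymmetry = stats::runif(nrow(fx$meta)))
  f2 <- assemble_features(fx$residuals, fx$meta, scores,
                          design_spec("1", include_scores = TRUE))
  expect_equal(ncol(f2$features), 10)
  expect_equal(colnames(f2$features)[9:10], c("severity", "asymmetry"))
})

test_that("rows with missing required scores are dropped with a message", {
  fx <- make_residual_fixture(92)
  scores <- tibble::tibble(patient_id = fx$meta$patient_id,
                           severity = 1, asymmetry = 0.5)
  scores$severity[1:3] <- NA          # e.g. unobserved contralateral ear
  expect_message(
    f <- assemble_features(fx$residuals, fx$meta, scores,
                           design_spec("1", include_scores = TRUE)),
    "3 row")
  expect_equal(nrow(f$features), nrow(fx$meta) - 3)
})

test_that("design 3 restricts to MFDM ears and needs genotype labels", {
  fx <- make_residual_fixture(93)
  f <- assemble_features(fx$residuals, fx$meta, design = design_spec("3"))
  expect_true(all(f$meta$group == "MFDM"))
  expect_true(all(levels(f$labels) %in%
                    c("splice", "frameshift", "nonsense", "deletion")))
  no_geno <- fx$meta
  no_geno$genotype_class <- "none"
  expect_error(assemble_features(fx$residuals, no_geno,
                                 design = design_spec("3")),
               "genotype")
})

test_that("separable classes give a falling-then-flat CV curve and high accuracy", {
  fx <- make_residual_fixture(94, n_per_class = 60, separation = 4)
  train_idx <- c(1:40, 61:100)
  test_idx <- setdiff(seq_len(120), train_idx)
  clf <- train_classifier(as.matrix(fx$residuals)[train_idx, ],
                          fx$labels[train_idx], seed = 1, max_rounds = 120)
  expect_lt(min(clf$cv_logloss), clf$cv_logloss[1])
  expect_equal(clf$best_iteration, which.min(clf$cv_logloss))
  pred <- predict_label(clf, as.matrix(fx$residuals)[test_idx, ])
  expect_gt(mean(as.character(pred) == fx$labels[test_idx]), 0.95)
})

test_that("pure-noise features classify at chance", {
  fx <- make_residual_fixture(95, n_per_class = 100, separation = 0)
  train_idx <- c(1:50, 101:150)
  test_idx <- setdiff(seq_len(200), train_idx)
  clf <- suppressWarnings(
    train_classifier(as.matrix(fx$residuals)[train_idx, ],
                     fx$labels[train_idx], seed = 2, max_rounds = 80))
  acc <- mean(as.character(predict_label(clf,
                                         as.matrix(fx$residuals)[test_idx, ])) ==
                fx$labels[test_idx])
  band <- qbinom(c(0.025, 0.975), length(test_idx), 0.5) / length(test_idx)
  expect_gte(acc, band[1])
  expect_lte(acc, band[2])
})

test_that("training is deterministic given the seed", {
  fx <- make_residual_fixture(96)
  x <- as.matrix(fx$residuals)
  c1 <- train_classifier(x, fx$labels, seed = 7, max_rounds = 60)
  c2 <- train_classifier(x, fx$labels, seed = 7, max_rounds = 60)
  expect_equal(c1$best_iteration, c2$best_iteration)
  expect_equal(predict_proba(c1, x), predict_proba(c2, x))
})

test_that("degenerate label sets are rejected or folded down", {
  fx <- make_residual_fixture(97)
  x <- as.matrix(fx$residuals)
  expect_error(train_classifier(x, rep("MFDM", nrow(x))), "two classes")
  small <- c(rep("A", 3), rep("B", 40))
  xs <- x[seq_along(small), ]
  expect_warning(clf <- train_classifier(xs, small, seed = 1, max_rounds = 20),
                 "folds")
  expect_lte(clf$n_folds, 3)
})

test_that("probabilities sum to one and argmax follows label order on ties", {
  fx <- make_residual_fixture(98, classes = c("MFDM", "control", "CHARGE"),
                              n_per_class = 30)
  clf <- train_classifier(as.matrix(fx$residuals), fx$labels, seed = 3,
                          max_rounds = 40)
  p <- predict_proba(clf, as.matrix(fx$residuals))
  expect_true(all(abs(rowSums(p) - 1) < 1e-6))
  expect_error(predict_proba(clf, as.matrix(fx$residuals)[, c(2, 1, 3, 4)]),
               "do not match")
  # argmax convention, as in the case-study probability vector
  probs <- c(CHARGE = 0.84, control = 0.11, MFDM = 0.03, NAFD = 0.02,
             TC = 0.01)
  expect_equal(names(probs)[which.max(probs)], "CHARGE")
})
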