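# End-to-end orchestration: simulate (or load) cohorts, superimpose and slide
# landmarks, adjust for covariates, score patients, train the classifier for
# a design, evaluate on held-out patients, embed.

#' Pipeline configuration
#'
#' Bundles the per-stage settings of [run_pipeline()]. The default validation
#' cohort sizes mirror the held-out set of the study (21 controls, 11 MFDM,
#' 2 NAFD, 6 TC, 8 CHARGE), with exactly one photograph per ear per patient.
#'
#' @param simulation a [simulation_config()] for the training cohort.
#' @param validation a [simulation_config()] with `role = "validation"`; pass
#'   `NULL` to derive one from `simulation` with the default validation group
#'   sizes and `seed + 1`.
#' @param design design id for [design_spec()].
#' @param include_scores override the design default.
#' @param mode semilandmark sliding criterion.
#' @param variance_target PCA retained-variance target.
#' @param slide logical; `FALSE` uses plain GPA without sliding.
#' @param seed seed for fold construction, side selection and embedding.
#' @param n_folds,learning_rate,gamma,max_depth,max_rounds classifier
#'   settings, as in [train_classifier()].
#' @param confidence confidence level for the evaluation report.
#' @param embed compute a UMAP embedding of the training features.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(simulation = simulation_config(),
                            validation = NULL,
                            design = "1", include_scores = NULL,
                            mode = "bending_energy", variance_target = 0.90,
                            slide = TRUE, seed = 0L, n_folds = 5L,
                            learning_rate = 0.3, gamma = 0, max_depth = 6L,
                            max_rounds = 500L, confidence = 0.95,
                            embed = FALSE) {
  stopifnot(inherits(simulation, "sim_config"))
  if (is.null(validation)) {
    validation <- simulation
    validation$group_sizes <- c(control = 21L, MFDM = 11L, NAFD = 2L,
                                TC = 6L, CHARGE = 8L)
    validation$role <- "validation"
    validation$seed <- simulation$seed + 1L
  }
  stopifnot(inherits(validation, "sim_config"),
            validation$role == "validation")
  structure(
    list(simulation = simulation, validation = validation,
         design = as.character(design), include_scores = include_scores,
         mode = mode, variance_target = variance_target, slide = slide,
         seed = as.integer(seed), n_folds = n_folds,
         learning_rate = learning_rate, gamma = gamma, max_depth = max_depth,
         max_rounds = max_rounds, confidence = confidence, embed = embed),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' The YAML mirrors the [pipeline_config()] arguments, with `simulation:` and
#' `validation:` blocks holding [simulation_config()] arguments
#' (`group_sizes` as a mapping).
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  build_sim <- function(block, role) {
    if (is.null(block)) return(NULL)
    if (!is.null(block$group_sizes))
      block$group_sizes <- unlist(block$group_sizes)
    if (!is.null(block$grade_probabilities))
      block$grade_probabilities <- lapply(block$grade_probabilities, unlist)
    if (!is.null(block$p_female)) block$p_female <- unlist(block$p_female)
    block$role <- role
    do.call(simulation_config, block)
  }
  args <- y[setdiff(names(y), c("simulation", "validation"))]
  args$simulation <- build_sim(y$simulation, "training")
  if (is.null(args$simulation)) args$simulation <- simulation_config()
  args$validation <- build_sim(y$validation, "validation")
  do.call(pipeline_config, args)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: cohort simulation (training and validation),
#' reflection of left ears, generalized Procrustes superimposition with
#' semilandmark sliding, shape PCA, per-component mixed-model covariate
#' adjustment (marginal residuals on both sides, with fixed effects frozen
#' from training — see the methods vignette), patient severity/asymmetry
#' scoring (FA normalization frozen from the training cohort), feature
#' assembly for the configured design, gradient-boosted training with
#' CV-selected iteration count, and evaluation on one randomly selected ear
#' per validation patient (scores are computed from both ears first, then one
#' side is drawn, seeded). Identical configurations produce identical
#' results. Each stage logs its row counts; when `out_dir` is given the
#' cohort tables, patient scores, evaluation report and log are written
#' there.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory for serialized intermediates.
#' @return An object of class `pipeline_result`: list with `report`
#'   (`evaluation_report`), `classifier`, `shape_space`, `adjusted`
#'   (`residual_set`), `train_scores`, `val_scores`, `embedding` (or `NULL`),
#'   `retained`, `log` (character), and the cohorts.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- character(0)
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log <<- c(log, line)
    message(line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  train <- stage("simulate", simulate_cohort(config$simulation))
  val <- stage("simulate", simulate_cohort(config$validation))
  say("simulate: %d training ears (%d patients), %d validation ears (%d patients)",
      nrow(train), length(unique(train$patient_id)),
      nrow(val), length(unique(val$patient_id)))

  annotated <- !vapply(train$landmarks, is.null, TRUE)
  configs <- lapply(train$landmarks[annotated],
                    function(lm) reflect_to_reference_side(lm)$points)
  slid <- stage("landmarks-process", {
    if (config$slide)
      slide_semilandmarks(configs, mode = config$mode)
    else gpa(configs)
  })
  space <- stage("landmarks-process",
                 shape_pca(slid, variance_target = config$variance_target))
  say("landmarks-process: %d/%d ears aligned, %d components retained",
      sum(annotated), nrow(train), space$retained)

  meta_train <- train[annotated, c("patient_id", "photo_id", "side", "age",
                                   "gender", "group", "genotype_class")]
  # classifier features are marginal residuals on both sides: conditional
  # residuals let the per-individual random slopes absorb group-level shape
  # offsets during training while validation ears (unseen individuals) keep
  # them, which would train and test the classifier on different feature
  # distributions
  adjusted <- stage("adjust",
                    adjust_covariates(space$scores, meta_train,
                                      mode = "marginal"))
  say("adjust: %d mixed models fitted (%d singular)",
      length(adjusted$fits),
      sum(vapply(adjusted$fits, function(f) f$singular, TRUE)))

  train_scores <- stage("score", patient_scores(train))
  fa_max <- attr(train_scores, "fa_reference_max")
  val_scores <- stage("score", patient_scores(val, fa_reference_max = fa_max))
  say("score: %d training / %d validation patients scored (FA max %.4g frozen)",
      sum(!is.na(train_scores$asymmetry)), sum(!is.na(val_scores$asymmetry)),
      fa_max)

  design <- design_spec(config$design, include_scores = config$include_scores)
  feats <- stage("train", assemble_features(adjusted$residuals, meta_train,
                                            scores = train_scores,
                                            design = design))
  clf <- stage("train", train_classifier(
    feats, n_folds = config$n_folds, seed = config$seed,
    learning_rate = config$learning_rate, gamma = config$gamma,
    max_depth = config$max_depth, max_rounds = config$max_rounds))
  say("train: design %s on %d ears, chosen iteration %d",
      design$id, nrow(feats$features), clf$best_iteration)

  # validation: one randomly selected annotated ear per patient (seeded)
  val_ok <- !vapply(val$landmarks, is.null, TRUE)
  val_ann <- val[val_ok, ]
  sel <- withr::with_seed(config$seed, {
    idx <- split(seq_len(nrow(val_ann)), val_ann$patient_id)
    sort(vapply(idx, function(v) if (length(v) == 1L) v else
      v[sample.int(length(v), 1L)], integer(1)))
  })
  val_sel <- val_ann[sel, ]
  val_configs <- lapply(val_sel$landmarks,
                        function(lm) reflect_to_reference_side(lm)$points)
  val_scores_mat <- stage("evaluate", project_shapes(
    space, val_configs,
    template = if (config$slide) default_template() else NULL,
    mode = config$mode))
  val_meta <- val_sel[, c("patient_id", "photo_id", "side", "age", "gender",
                          "group", "genotype_class")]
  val_res <- stage("evaluate",
                   residualize_new(adjusted, val_scores_mat, val_meta))
  val_feats <- stage("evaluate", assemble_features(
    val_res, val_meta, scores = val_scores, design = design))
  probs <- predict_proba(clf, val_feats$features)
  preds <- predict_label(clf, val_feats$features)
  present <- union(levels(droplevels(val_feats$labels)),
                   levels(droplevels(preds)))
  report <- stage("evaluate", confusion_and_metrics(
    as.character(preds), as.character(val_feats$labels),
    label_order = design$labels[design$labels %in% present],
    scores = probs[, design$labels[design$labels %in% present], drop = FALSE],
    confidence = config$confidence))
  say("evaluate: %d validation ears, accuracy %.3f [%.3f-%.3f]",
      sum(report$confusion), report$accuracy, report$ci[["lower"]],
      report$ci[["upper"]])

  embedding <- NULL
  if (isTRUE(config$embed)) {
    embedding <- stage("embed",
                       umap_embed(feats$features, seed = config$seed))
    embedding$label <- as.character(feats$labels)
    say("embed: %d points embedded", nrow(embedding))
  }

  result <- structure(
    list(report = report, classifier = clf, shape_space = space,
         adjusted = adjusted, train_scores = train_scores,
         val_scores = val_scores, embedding = embedding,
         retained = space$retained, config = config, log = log,
         train_cohort = train, validation_cohort = val,
         validation_features = val_feats),
    class = "pipeline_result"
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_cohort(train, file.path(out_dir, "training"))
    write_cohort(val, file.path(out_dir, "validation"))
    readr::write_csv(train_scores, file.path(out_dir, "training_scores.csv"))
    readr::write_csv(val_scores, file.path(out_dir, "validation_scores.csv"))
    jsonlite::write_json(report_to_list(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
    writeLines(log, file.path(out_dir, "pipeline.log"))
  }
  result
}

report_to_list <- function(report) {
  list(
    labels = report$labels,
    confusion = unname(apply(report$confusion, 1, as.list)),
    accuracy = report$accuracy,
    ci = as.list(report$ci),
    nir = report$nir, nir_p = report$nir_p,
    per_class = report$per_class,
    auc = if (is.null(report$auc)) NULL else as.list(report$auc)
  )
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> design", x$config$design, "\n")
  cat(paste0("  ", x$log, collapse = "\n"), "\n")
  invisible(x)
}
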