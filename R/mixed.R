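# Per-component linear mixed models: score ~ intercept + age + gender with a
# per-individual random slope for age, and the residuals that feed the
# classifier.

#' Fit the per-component mixed model
#'
#' REML fit of `y = alpha + beta1 * age + beta2 * gender + b_i * age + eps`
#' with `b_i ~ N(0, sigma_b^2)` a random age slope per individual (single
#' grouping factor: patient) and `eps ~ N(0, sigma_eps^2)`. Gender is coded
#' with female as the reference level, so `beta2` is the male contrast. There
#' is no age-by-gender interaction and, by default, no random intercept (the
#' model is the equation as written; `random_intercept = TRUE` adds one). A
#' singular fit (`sigma_b` estimated at 0) is returned with `singular = TRUE`
#' rather than an error.
#'
#' @param data data frame with columns `score`, `age`, `gender`,
#'   `patient_id`.
#' @param component optional component index carried into the result.
#' @param random_intercept also include a per-individual random intercept.
#' @return An object of class `pc_mixed_fit`: the parameter estimates
#'   (`alpha`, `beta1`, `beta2`, `sigma_b`, `sigma_eps`), their standard
#'   errors, per-individual predicted slopes, the REML log-likelihood, the
#'   singularity flag and the underlying `lme4` fit.
#' @export
fit_pc_mixed_model <- function(data, component = NA_integer_,
                               random_intercept = FALSE) {
  req <- c("score", "age", "gender", "patient_id")
  if (!all(req %in% names(data)))
    stop("`data` must have columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  if (!all(is.finite(data$score)) || !all(is.finite(data$age)))
    stop("non-finite score or age values.", call. = FALSE)
  if (length(unique(data$patient_id)) < 2L)
    stop("at least two patients are required.", call. = FALSE)
  data$gender <- factor(data$gender, levels = c("female", "male"))
  re <- if (random_intercept) "(1 + age | patient_id)" else "(0 + age | patient_id)"
  form <- stats::as.formula(paste("score ~ age + gender +", re))
  fit <- suppressMessages(lme4::lmer(
    form, data = data, REML = TRUE,
    control = lme4::lmerControl(check.conv.singular = "ignore",
                                calc.derivs = FALSE)
  ))
  fe <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  vc <- as.data.frame(lme4::VarCorr(fit))
  sigma_b <- vc$sdcor[vc$grp == "patient_id" & vc$var1 == "age" &
                        is.na(vc$var2)][1]
  ran <- lme4::ranef(fit)$patient_id
  slopes <- stats::setNames(ran[["age"]], rownames(ran))
  structure(
    list(component = component,
         alpha = unname(fe[["(Intercept)"]]),
         beta1 = unname(fe[["age"]]),
         beta2 = unname(fe[["gendermale"]]),
         se = stats::setNames(unname(se), c("alpha", "beta1", "beta2")),
         sigma_b = sigma_b,
         sigma_eps = stats::sigma(fit),
         individual_slopes = slopes,
         log_restricted_likelihood = as.numeric(stats::logLik(fit)),
         singular = lme4::isSingular(fit),
         random_intercept = random_intercept,
         model = fit),
    class = "pc_mixed_fit"
  )
}

#' @export
print.pc_mixed_fit <- function(x, ...) {
  cat(sprintf("<pc_mixed_fit>%s alpha=%.4f beta1(age)=%.4f beta2(male)=%.4f\n",
              if (is.na(x$component)) "" else sprintf(" PC%d:", x$component),
              x$alpha, x$beta1, x$beta2))
  cat(sprintf("  sigma_b=%.4f sigma_eps=%.4f%s, %d individuals\n",
              x$sigma_b, x$sigma_eps,
              if (x$singular) " (singular: random slope at boundary)" else "",
              length(x$individual_slopes)))
  invisible(x)
}

#' @export
tidy.pc_mixed_fit <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", "age", "gendermale"),
    estimate = c(x$alpha, x$beta1, x$beta2),
    std.error = unname(x$se),
    statistic = c(x$alpha, x$beta1, x$beta2) / unname(x$se)
  )
}

#' @export
glance.pc_mixed_fit <- function(x, ...) {
  tibble::tibble(
    component = x$component,
    sigma_b = x$sigma_b,
    sigma_eps = x$sigma_eps,
    logLik_REML = x$log_restricted_likelihood,
    n_individuals = length(x$individual_slopes),
    singular = x$singular
  )
}

#' Residualize component scores against age and gender
#'
#' Conditional mode (training data) subtracts the full individual prediction
#' `alpha + beta1*age + beta2*gender + b_i*age`, using the individual's
#' predicted random slope; marginal mode (new individuals, for whom random
#' effects are inestimable) subtracts the fixed part only. Conditional mode
#' falls back to marginal, with a warning, for patients unseen in training.
#'
#' @param fit a [fit_pc_mixed_model()] result.
#' @param data data frame with `score`, `age`, `gender`, `patient_id`.
#' @param mode `"conditional"` or `"marginal"`.
#' @return Numeric residual vector, one value per row of `data`.
#' @export
residualize <- function(fit, data, mode = c("conditional", "marginal")) {
  mode <- match.arg(mode)
  stopifnot(inherits(fit, "pc_mixed_fit"))
  male <- as.numeric(data$gender == "male")
  pred <- fit$alpha + fit$beta1 * data$age + fit$beta2 * male
  if (mode == "conditional") {
    b <- fit$individual_slopes[as.character(data$patient_id)]
    unseen <- is.na(b)
    if (any(unseen)) {
      warning(sum(unseen), " observation(s) from patients unseen in training; ",
              "using marginal residuals for them.", call. = FALSE)
      b[unseen] <- 0
    }
    if (fit$random_intercept) {
      ri <- lme4::ranef(fit$model)$patient_id[["(Intercept)"]]
      names(ri) <- rownames(lme4::ranef(fit$model)$patient_id)
      r0 <- ri[as.character(data$patient_id)]
      r0[is.na(r0)] <- 0
      pred <- pred + r0
    }
    pred <- pred + unname(b) * data$age
  }
  data$score - pred
}

#' Fit mixed models for all retained components and residualize
#'
#' Convenience wrapper around [fit_pc_mixed_model()] and [residualize()]:
#' one model per retained shape component, returning the residual table that
#' feeds the classifier.
#'
#' @param scores n x k matrix of component scores (training ears).
#' @param metadata data frame aligned with `scores` rows: `age`, `gender`,
#'   `patient_id`.
#' @param mode residual mode, as in [residualize()].
#' @param random_intercept passed to [fit_pc_mixed_model()].
#' @return An object of class `residual_set`: list with `residuals` (tibble,
#'   columns `PC1..PCk`), `fits` (list of `pc_mixed_fit`), `mode`.
#' @export
adjust_covariates <- function(scores, metadata,
                              mode = c("conditional", "marginal"),
                              random_intercept = FALSE) {
  mode <- match.arg(mode)
  scores <- as.matrix(scores)
  if (nrow(scores) != nrow(metadata))
    stop("`scores` and `metadata` must have the same number of rows.",
         call. = FALSE)
  k <- ncol(scores)
  fits <- vector("list", k)
  res <- matrix(NA_real_, nrow(scores), k,
                dimnames = list(NULL, paste0("PC", seq_len(k))))
  for (j in seq_len(k)) {
    d <- data.frame(score = scores[, j], age = metadata$age,
                    gender = metadata$gender,
                    patient_id = metadata$patient_id)
    fits[[j]] <- fit_pc_mixed_model(d, component = j,
                                    random_intercept = random_intercept)
    res[, j] <- residualize(fits[[j]], d, mode = mode)
  }
  structure(list(residuals = tibble::as_tibble(res), fits = fits, mode = mode),
            class = "residual_set")
}

#' Residualize new ears with training-frozen fixed effects
#'
#' @param adjusted an [adjust_covariates()] result (training fits).
#' @param scores n x k score matrix for new ears (same components).
#' @param metadata data frame with `age`, `gender`, `patient_id`.
#' @return Residual tibble (`PC1..PCk`), marginal mode.
#' @export
residualize_new <- function(adjusted, scores, metadata) {
  stopifnot(inherits(adjusted, "residual_set"))
  scores <- as.matrix(scores)
  k <- length(adjusted$fits)
  stopifnot(ncol(scores) == k)
  res <- matrix(NA_real_, nrow(scores), k,
                dimnames = list(NULL, paste0("PC", seq_len(k))))
  for (j in seq_len(k)) {
    d <- data.frame(score = scores[, j], age = metadata$age,
                    gender = metadata$gender,
                    patient_id = metadata$patient_id)
    res[, j] <- residualize(adjusted$fits[[j]], d, mode = "marginal")
  }
  tibble::as_tibble(res)
}

#' @export
print.residual_set <- function(x, ...) {
  cat(sprintf("<residual_set> %d ears x %d components, %s residuals\n",
              nrow(x$residuals), ncol(x$residuals), x$mode))
  invisible(x)
}
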