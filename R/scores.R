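# Patient-level severity and asymmetry scales, and between-group comparisons.

#' Microtia severity score
#'
#' Sum of the two ears' Marx grades (0 = normal, 1-4 = grades I-IV), giving a
#' patient-level severity in 0-8.
#'
#' @param left_grade,right_grade integer grades in 0-4 (vectorized).
#' @return Integer vector.
#' @export
severity_score <- function(left_grade, right_grade) {
  check_grade(left_grade); check_grade(right_grade)
  as.integer(left_grade + right_grade)
}

check_grade <- function(g) {
  if (any(!g %in% 0:4))
    stop("Marx grades must be integers in 0-4.", call. = FALSE)
  invisible(g)
}

#' Mixed asymmetry scale
#'
#' The 0-3 mixed asymmetry scale: when either ear is grade II or worse, the
#' absolute difference of the two Marx grades; when both ears are grade 0-I
#' (and therefore landmarked), the normalized fluctuating-asymmetry index in
#' \[0, 1\]. Two grade-II ears score 0; a grade-III plus a grade-I ear scores
#' 2; two grade-I ears score their FA index.
#'
#' @param left_grade,right_grade integer grades in 0-4 (vectorized).
#' @param fa_index normalized FA index in \[0, 1\]; required exactly when both
#'   grades are <= 1, ignored otherwise (may be `NA` elsewhere).
#' @return Numeric vector in \[0, 3\].
#' @export
asymmetry_score <- function(left_grade, right_grade, fa_index = NA_real_) {
  check_grade(left_grade); check_grade(right_grade)
  n <- max(length(left_grade), length(right_grade))
  left_grade <- rep_len(left_grade, n)
  right_grade <- rep_len(right_grade, n)
  fa_index <- rep_len(fa_index, n)
  needs_fa <- pmax(left_grade, right_grade) <= 1
  if (any(needs_fa & is.na(fa_index)))
    stop("fa_index is required when both ears are grade 0-I.", call. = FALSE)
  if (any(needs_fa & (fa_index < 0 | fa_index > 1), na.rm = TRUE))
    stop("fa_index must lie in [0, 1].", call. = FALSE)
  ifelse(needs_fa, fa_index, abs(left_grade - right_grade))
}

#' Per-patient severity and asymmetry scores for a cohort
#'
#' Determines each patient's per-side Marx grade, computes the
#' fluctuating-asymmetry index from one landmarked photograph per side
#' (mirrored left vs right, see [fluctuating_asymmetry_index()]), normalizes
#' it over the cohort (or against a frozen training maximum) and applies the
#' severity and mixed asymmetry scales. Patients for whom one side was never
#' observed — or whose FA index is required but uncomputable — get `NA`
#' scores and are excluded from score-using designs downstream.
#'
#' @param cohort cohort tibble ([simulate_cohort()] / [read_cohort_table()]).
#' @param fa_reference_max frozen training-cohort maximum raw FA; `NULL`
#'   normalizes within this cohort.
#' @return Tibble with one row per patient: `patient_id`, `group`,
#'   `genotype_class`, `left_grade`, `right_grade`, `severity`, `raw_fa`,
#'   `fa_index`, `asymmetry`; attribute `fa_reference_max` carries the
#'   normalization constant.
#' @export
patient_scores <- function(cohort, fa_reference_max = NULL) {
  by_patient <- split(seq_len(nrow(cohort)), cohort$patient_id)
  rows <- purrr::map(names(by_patient), function(pid) {
    idx <- by_patient[[pid]]
    sub <- cohort[idx, ]
    grade_of <- function(s) {
      g <- unique(sub$marx_grade[sub$side == s])
      if (length(g) == 0) NA_integer_ else as.integer(g[1])
    }
    lg <- grade_of("left"); rg <- grade_of("right")
    pick_lm <- function(s) {
      lms <- sub$landmarks[sub$side == s]
      lms <- lms[!vapply(lms, is.null, TRUE)]
      if (length(lms) == 0) NULL else lms[[1]]
    }
    raw_fa <- NA_real_
    if (!is.na(lg) && !is.na(rg) && max(lg, rg) <= 1) {
      llm <- pick_lm("left"); rlm <- pick_lm("right")
      if (!is.null(llm) && !is.null(rlm))
        raw_fa <- fluctuating_asymmetry_index(llm, rlm)
    }
    tibble::tibble(patient_id = pid, group = sub$group[1],
                   genotype_class = sub$genotype_class[1],
                   left_grade = lg, right_grade = rg, raw_fa = raw_fa)
  })
  out <- dplyr::bind_rows(rows)
  fa_norm <- rep(NA_real_, nrow(out))
  if (any(!is.na(out$raw_fa))) {
    ok <- !is.na(out$raw_fa)
    nf <- normalize_fa(out$raw_fa[ok], reference_max = fa_reference_max)
    fa_norm[ok] <- nf
    fa_reference_max <- attr(nf, "reference_max")
  }
  out$fa_index <- fa_norm
  complete <- !is.na(out$left_grade) & !is.na(out$right_grade)
  scoreable <- complete &
    (pmax(out$left_grade, out$right_grade) >= 2 | !is.na(out$fa_index))
  out$severity <- ifelse(complete,
                         out$left_grade + out$right_grade, NA_integer_)
  out$asymmetry <- NA_real_
  if (any(scoreable))
    out$asymmetry[scoreable] <- asymmetry_score(out$left_grade[scoreable],
                                                out$right_grade[scoreable],
                                                out$fa_index[scoreable])
  attr(out, "fa_reference_max") <- fa_reference_max
  out
}

#' Compare patient scores between diagnostic groups
#'
#' Linear model of a score on group indicators with MFDM as the reference
#' level, so every coefficient is a contrast of that group against MFDM,
#' tested against 0 by a two-sided t test. When the score table carries
#' repeated rows per patient a per-patient random intercept is added
#' (`lmerTest` fit with Satterthwaite degrees of freedom). Groups with fewer
#' than two patients are excluded with a warning; a degenerate (zero
#' variance) score vector is flagged.
#'
#' @param scores data frame with `patient_id`, `group` and the score column.
#' @param score column name to compare (`"severity"` or `"asymmetry"`).
#' @param reference_group reference level (default `"MFDM"`).
#' @return Tibble: `term`, `estimate`, `std.error`, `statistic`, `p.value`,
#'   `significant` (p < 0.05); attribute `degenerate` flags zero variance.
#' @export
compare_scores_between_groups <- function(scores, score = "severity",
                                          reference_group = "MFDM") {
  stopifnot(score %in% names(scores))
  d <- scores[!is.na(scores[[score]]) & !is.na(scores$group), ]
  counts <- tapply(d$patient_id, d$group, function(x) length(unique(x)))
  small <- names(counts)[counts < 2]
  if (length(small) > 0) {
    warning("excluding group(s) with < 2 patients: ",
            paste(small, collapse = ", "), call. = FALSE)
    d <- d[!d$group %in% small, ]
  }
  if (length(unique(d$group)) < 2L)
    stop("need at least two groups with >= 2 patients each.", call. = FALSE)
  lev <- unique(d$group)
  if (!reference_group %in% lev) reference_group <- lev[1]
  d$group <- stats::relevel(factor(d$group), ref = reference_group)
  d$y <- d[[score]]
  degenerate <- stats::sd(d$y) < .Machine$double.eps^0.5
  repeated <- anyDuplicated(d$patient_id) > 0
  if (degenerate) {
    cf <- tibble::tibble(
      term = c("(Intercept)", paste0("group", setdiff(levels(d$group),
                                                      reference_group))),
      estimate = 0, std.error = 0, statistic = NA_real_, p.value = NA_real_
    )
  } else if (repeated) {
    fit <- lmerTest::lmer(y ~ group + (1 | patient_id), data = d)
    sm <- stats::coef(summary(fit))
    cf <- tibble::tibble(term = rownames(sm), estimate = sm[, "Estimate"],
                         std.error = sm[, "Std. Error"],
                         statistic = sm[, "t value"],
                         p.value = sm[, "Pr(>|t|)"])
  } else {
    fit <- stats::lm(y ~ group, data = d)
    sm <- stats::coef(summary(fit))
    cf <- tibble::tibble(term = rownames(sm), estimate = sm[, "Estimate"],
                         std.error = sm[, "Std. Error"],
                         statistic = sm[, "t value"],
                         p.value = sm[, "Pr(>|t|)"])
  }
  cf$significant <- !is.na(cf$p.value) & cf$p.value < 0.05
  attr(cf, "degenerate") <- degenerate
  attr(cf, "reference_group") <- reference_group
  cf
}
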