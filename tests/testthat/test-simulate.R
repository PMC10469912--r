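test_that("simulation is a pure function of its configuration", {
  cfg <- simulation_config(group_sizes = c(control = 5, MFDM = 5), seed = 11)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a, b)
})

test_that("zero noise and zero effects collapse to one shape", {
  cfg <- simulation_config(group_sizes = c(control = 6),
                           effect_scale = 0, beta_age = 0, beta_gender = 0,
                           sigma_slope = 0, da_offset = 0, fa_sd = 0,
                           meas_sd = 0, seed = 3)
  co <- simulate_cohort(cfg)
  center <- function(m) sweep(m, 2, colMeans(m))
  pts <- lapply(co$landmarks[!vapply(co$landmarks, is.null, TRUE)],
                function(l) center(reflect_to_reference_side(l)$points))
  for (p in pts[-1]) expect_equal(unname(p), unname(pts[[1]]), tolerance = 1e-9)
})

test_that("grade distribution matches the configured probabilities at scale", {
  # MFDM pooled grade >= II mass is 8% by configuration
  co <- simulate_cohort(simulation_config(
    group_sizes = c(MFDM = 3400), photos_per_patient = 3, seed = 19))
  frac <- mean(co$marx_grade >= 2)
  expect_gt(nrow(co), 9000)
  expect_lt(abs(frac - 0.08), 0.01)
})

test_that("landmarks exist exactly for grade 0-I ears, genotype only in MFDM", {
  co <- simulate_cohort(simulation_config(
    group_sizes = c(control = 10, MFDM = 10, TC = 10, CHARGE = 5, NAFD = 5),
    seed = 6))
  has_lm <- !vapply(co$landmarks, is.null, TRUE)
  expect_identical(has_lm, co$marx_grade <= 1L)
  expect_true(all(co$genotype_class[co$group != "MFDM"] == "none"))
  expect_true(all(co$genotype_class[co$group == "MFDM"] != "none"))
  expect_false(anyDuplicated(co$photo_id) > 0)
})

test_that("repeated photographs advance age monotonically per patient", {
  co <- simulate_cohort(simulation_config(group_sizes = c(control = 20),
                                          seed = 7))
  for (ages in split(co$age, co$patient_id)) {
    expect_true(all(diff(ages) >= 0))
  }
})

test_that("validation cohorts hold one photograph of each side per patient", {
  co <- simulate_cohort(simulation_config(group_sizes = c(control = 8, MFDM = 6),
                                          role = "validation", seed = 9))
  counts <- table(co$patient_id, co$side)
  expect_true(all(counts == 1))
})

test_that("configured covariate slopes are recoverable from raw landmarks", {
  # the age and gender fields have unit norm, so the projection of raw
  # right-frame landmarks onto them follows the mixed-model equation exactly
  tpl <- default_template()
  fields <- earmorph:::covariate_fields(tpl)
  beta1 <- 0.6; beta2 <- 3
  hits <- 0
  n_seeds <- 10
  for (s in seq_len(n_seeds)) {
    cfg <- simulation_config(group_sizes = c(control = 60),
                             photos_per_patient = 3,
                             beta_age = beta1, beta_gender = beta2,
                             da_offset = 0, seed = 100 + s)
    co <- simulate_cohort(cfg)
    keep <- !vapply(co$landmarks, is.null, TRUE)
    co <- co[keep, ]
    pts <- lapply(co$landmarks,
                  function(l) reflect_to_reference_side(l)$points)
    proj <- function(field) vapply(pts, function(p) sum(p * field), numeric(1))
    d1 <- data.frame(score = proj(fields$age), age = co$age,
                     gender = co$gender, patient_id = co$patient_id)
    f1 <- fit_pc_mixed_model(d1)
    d2 <- data.frame(score = proj(fields$gender), age = co$age,
                     gender = co$gender, patient_id = co$patient_id)
    f2 <- fit_pc_mixed_model(d2)
    ok <- abs(f1$beta1 - beta1) < 3 * f1$se[["beta1"]] &&
      abs(f2$beta2 - beta2) < 3 * f2$se[["beta2"]]
    hits <- hits + ok
  }
  expect_gte(hits, n_seeds - 1)
})

test_that("published confusion fixtures carry the printed counts", {
  fx <- paper_confusion_fixtures()
  expect_equal(fx$design1["MFDM", "MFDM"], 10)
  expect_equal(unname(colSums(fx[["design2.1"]])), c(7, 21, 7, 2))
  expect_equal(sum(fx[["design2.2"]]), 16)
  expect_equal(rownames(fx$design1), c("MFDM", "Control"))
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(group_sizes = c(bogus = 3)), "named")
  expect_error(simulation_config(grade_probabilities = list(
    control = c(0.5, 0.1, 0, 0, 0), MFDM = c(0.32, 0.6, 0.03, 0.05, 0),
    NAFD = c(0.4, 0.6, 0, 0, 0), TC = c(0.2, 0.6, 0.17, 0.03, 0),
    CHARGE = c(0.4, 0.6, 0, 0, 0))), "summing to 1")
  expect_error(simulation_config(meas_sd = -1), ">= 0")
})
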