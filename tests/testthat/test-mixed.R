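sim_scores <- function(seed, n_pat = 100, per = 3, alpha = 1, beta1 = 0.4,
                       beta2 = 1.2, sigma_b = 0.4, sigma_eps = 0.7) {
  withr::with_seed(seed, {
    pid <- rep(seq_len(n_pat), each = per)
    age <- stats::runif(n_pat * per, 0, 20)
    gender <- sample(c("female", "male"), n_pat * per, replace = TRUE)
    b <- stats::rnorm(n_pat, 0, sigma_b)
    y <- alpha + beta1 * age + beta2 * (gender == "male") + b[pid] * age +
      stats::rnorm(n_pat * per, 0, sigma_eps)
    data.frame(score = y, age = age, gender = gender, patient_id = pid)
  })
}

test_that("null data recover null fixed effects", {
  d <- sim_scores(71, beta1 = 0, beta2 = 0, sigma_b = 0)
  f <- fit_pc_mixed_model(d)
  expect_lt(abs(f$beta1), 3 * f$se[["beta1"]])
  expect_lt(abs(f$beta2), 3 * f$se[["beta2"]])
})

test_that("known parameters are recovered within 3 SE across seeds", {
  hits_b1 <- hits_b2 <- 0
  n_seeds <- 12
  for (s in seq_len(n_seeds)) {
    d <- sim_scores(700 + s, n_pat = 200)
    f <- fit_pc_mixed_model(d)
    hits_b1 <- hits_b1 + (abs(f$beta1 - 0.4) < 3 * f$se[["beta1"]])
    hits_b2 <- hits_b2 + (abs(f$beta2 - 1.2) < 3 * f$se[["beta2"]])
  }
  expect_gte(hits_b1, n_seeds - 1)
  expect_gte(hits_b2, n_seeds - 1)
})

test_that("fit agrees with an independent mixed-model implementation", {
  skip_if_not_installed("nlme")
  d <- sim_scores(72, n_pat = 120)
  f <- fit_pc_mixed_model(d)
  g <- nlme::lme(score ~ age + gender, random = ~ 0 + age | patient_id,
                 data = d, method = "REML")
  expect_equal(unname(nlme::fixef(g)),
               c(f$alpha, f$beta1, f$beta2), tolerance = 1e-4)
  vc <- nlme::VarCorr(g)
  expect_equal(as.numeric(vc["age", "StdDev"]), f$sigma_b, tolerance = 1e-3)
  expect_equal(g$sigma, f$sigma_eps, tolerance = 1e-3)
})

test_that("sigma_b at the boundary is flagged, not an error", {
  d <- sim_scores(73, sigma_b = 0, n_pat = 60)
  f <- fit_pc_mixed_model(d)
  expect_true(is.finite(f$sigma_b))
  if (f$singular) expect_lt(f$sigma_b, 1e-6)
})

test_that("conditional and marginal residuals coincide when sigma_b is zero", {
  d <- sim_scores(74, sigma_b = 0, n_pat = 80)
  f <- fit_pc_mixed_model(d)
  f$individual_slopes[] <- 0     # exact degenerate random effect
  expect_equal(residualize(f, d, "conditional"),
               residualize(f, d, "marginal"), tolerance = 1e-12)
})

test_that("training conditional residuals are centered and age-free", {
  d <- sim_scores(75, n_pat = 150, beta1 = 0.8)
  f <- fit_pc_mixed_model(d)
  r <- residualize(f, d, "conditional")
  expect_lt(abs(mean(r)), 1e-6)
  sl <- summary(stats::lm(r ~ d$age))$coefficients
  expect_lt(abs(sl["d$age", "Estimate"]), 3 * sl["d$age", "Std. Error"])
})

test_that("residuals match hand arithmetic on a four-observation example", {
  fit <- structure(
    list(alpha = 2, beta1 = 0.5, beta2 = 1, sigma_b = 0.1, sigma_eps = 1,
         individual_slopes = c(p1 = 0.2, p2 = -0.1),
         random_intercept = FALSE, singular = FALSE),
    class = "pc_mixed_fit")
  d <- data.frame(score = c(10, 12, 8, 9), age = c(4, 6, 2, 3),
                  gender = c("female", "male", "female", "male"),
                  patient_id = c("p1", "p1", "p2", "p2"))
  # by hand: y - (2 + 0.5 age + 1 male + b_i age)
  cond <- c(10 - (2 + 2 + 0 + 0.8), 12 - (2 + 3 + 1 + 1.2),
            8 - (2 + 1 + 0 - 0.2), 9 - (2 + 1.5 + 1 - 0.3))
  marg <- c(10 - 4, 12 - 6, 8 - 3, 9 - 4.5)
  expect_equal(residualize(fit, d, "conditional"), cond)
  expect_equal(residualize(fit, d, "marginal"), marg)
})

test_that("unseen patients fall back to marginal residuals with a warning", {
  d <- sim_scores(76, n_pat = 30)
  f <- fit_pc_mixed_model(d)
  new <- data.frame(score = 5, age = 10, gender = "female",
                    patient_id = "stranger")
  expect_warning(r <- residualize(f, new, "conditional"), "unseen")
  expect_equal(r, residualize(f, new, "marginal"))
})

test_that("adjust_covariates fits one model per component and is deterministic", {
  d <- sim_scores(77, n_pat = 60)
  scores <- cbind(d$score, -2 * d$score + stats::rnorm(nrow(d)))
  a1 <- adjust_covariates(scores, d)
  a2 <- adjust_covariates(scores, d)
  expect_equal(a1$residuals, a2$residuals)
  expect_length(a1$fits, 2)
  expect_named(a1$residuals, c("PC1", "PC2"))
  new <- residualize_new(a1, scores[1:5, ], d[1:5, ])
  expect_equal(nrow(new), 5)
})
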