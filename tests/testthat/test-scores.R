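test_that("severity is the sum of the two Marx grades", {
  expect_equal(severity_score(2, 2), 4L)
  expect_equal(severity_score(0, 0), 0L)
  expect_equal(severity_score(3, 1), 4L)
  expect_equal(severity_score(c(1, 4), c(0, 4)), c(1L, 8L))
  expect_error(severity_score(5, 0), "0-4")
})

test_that("the mixed asymmetry scale follows its three worked examples", {
  expect_equal(asymmetry_score(2, 2), 0)
  expect_equal(asymmetry_score(3, 1), 2)
  expect_equal(asymmetry_score(1, 1, fa_index = 0.42), 0.42)
  expect_error(asymmetry_score(1, 1), "required")
  expect_error(asymmetry_score(0, 1, fa_index = 1.4), "\\[0, 1\\]")
})

test_that("severity and asymmetry are symmetric in their ear arguments", {
  withr::with_seed(81, {
    for (i in 1:20) {
      l <- sample(0:4, 1); r <- sample(0:4, 1)
      fa <- stats::runif(1)
      expect_equal(severity_score(l, r), severity_score(r, l))
      expect_equal(asymmetry_score(l, r, fa), asymmetry_score(r, l, fa))
    }
  })
})

test_that("patient scores reproduce the configured group severity ordering", {
  co <- simulate_cohort(simulation_config(
    group_sizes = c(control = 60, TC = 40), seed = 82))
  sc <- patient_scores(co)
  sev <- tapply(sc$severity, sc$group, mean, na.rm = TRUE)
  expect_gt(sev[["TC"]], sev[["control"]])
  ok <- !is.na(sc$asymmetry)
  expect_true(all(sc$asymmetry[ok] >= 0 & sc$asymmetry[ok] <= 3))
  # patients with an unobserved side carry missing scores
  one_sided <- with(sc, is.na(left_grade) | is.na(right_grade))
  expect_true(all(is.na(sc$severity[one_sided])))
})

test_that("FA normalization can be frozen from a training cohort", {
  tr <- simulate_cohort(simulation_config(group_sizes = c(control = 30),
                                          seed = 83))
  tr_sc <- patient_scores(tr)
  fa_max <- attr(tr_sc, "fa_reference_max")
  expect_equal(max(tr_sc$fa_index, na.rm = TRUE), 1)
  va <- simulate_cohort(simulation_config(group_sizes = c(control = 10),
                                          role = "validation", seed = 84))
  va_sc <- patient_scores(va, fa_reference_max = fa_max)
  expect_equal(attr(va_sc, "fa_reference_max"), fa_max)
  expect_true(all(va_sc$fa_index >= 0 & va_sc$fa_index <= 1, na.rm = TRUE))
})

test_that("group comparisons detect a strong true difference", {
  withr::with_seed(85, {
    d <- data.frame(
      patient_id = sprintf("p%03d", 1:60),
      group = rep(c("MFDM", "TC"), each = 30),
      severity = c(stats::rnorm(30, 1, 0.5), stats::rnorm(30, 3, 0.5)))
  })
  tab <- compare_scores_between_groups(d, "severity")
  expect_equal(attr(tab, "reference_group"), "MFDM")
  row <- tab[tab$term == "groupTC", ]
  expect_lt(row$p.value, 1e-3)
  expect_true(row$significant)
  expect_equal(unname(row$estimate), 2, tolerance = 0.3)
})

test_that("null group comparisons hold their nominal type-I error", {
  n_seeds <- 200
  rej <- 0
  for (s in seq_len(n_seeds)) {
    withr::with_seed(8500 + s, {
      d <- data.frame(patient_id = sprintf("p%02d", 1:80),
                      group = rep(c("MFDM", "control"), each = 40),
                      severity = stats::rnorm(80))
    })
    tab <- compare_scores_between_groups(d, "severity")
    rej <- rej + tab$significant[tab$term == "groupcontrol"]
  }
  # binomial 99% band around 0.05 for 200 draws
  expect_gte(rej, qbinom(0.005, n_seeds, 0.05))
  expect_lte(rej, qbinom(0.995, n_seeds, 0.05))
})

test_that("degenerate and undersized groups are handled gracefully", {
  d <- data.frame(patient_id = sprintf("p%02d", 1:20),
                  group = rep(c("MFDM", "CHARGE"), each = 10),
                  severity = rep(2, 20))
  tab <- compare_scores_between_groups(d, "severity")
  expect_true(attr(tab, "degenerate"))
  expect_true(all(tab$estimate == 0))
  d2 <- rbind(d, data.frame(patient_id = "p99", group = "NAFD", severity = 5))
  d2$severity <- stats::rnorm(21)
  expect_warning(compare_scores_between_groups(d2, "severity"), "NAFD")
})

test_that("repeated rows per patient engage the random intercept", {
  withr::with_seed(86, {
    d <- data.frame(
      patient_id = rep(sprintf("p%02d", 1:40), each = 2),
      group = rep(rep(c("MFDM", "control"), each = 20), each = 2),
      severity = stats::rnorm(80) + rep(stats::rnorm(40), each = 2))
  })
  tab <- compare_scores_between_groups(d, "severity")
  expect_true(all(c("estimate", "p.value") %in% names(tab)))
  expect_equal(nrow(tab), 2)
})
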