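# Regression families, BH correction and the burden-decade reading.

test_that("BH adjustment reproduces hand-computed step-up values", {
  expect_equal(bh_adjust(0.05), 0.05)
  expect_equal(bh_adjust(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(bh_adjust(c(0.03, 0.01, 0.04)), c(0.04, 0.03, 0.04))
  expect_equal(bh_adjust(numeric(0)), numeric(0))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  p <- c(0.001, 0.2, 0.04, 0.9)
  expect_true(all(bh_adjust(p) >= p))
})

test_that("exactly linear outcomes are recovered without error", {
  d <- exact_linear_cohort(n = 24, beta_x = 2, exposure = "hemoglobin")
  res <- fit_family(regression_spec("hemoglobin"), d)
  expect_equal(res$coefficient, c(2, 2), tolerance = 1e-8)
  expect_equal(res$outcome, c("gmv", "wmv"))
  expect_equal(res$coef_age, c(-1.2, 0.8), tolerance = 1e-8)
  expect_equal(res$coef_sex, c(10, 5), tolerance = 1e-8)
  expect_equal(res$coef_icv, c(0.2, 0.15), tolerance = 1e-8)
  expect_true(all(res$bh_p >= res$raw_p))
})

test_that("family fits agree with an independent normal-equations oracle", {
  set.seed(77)
  for (rep in 1:5) {
    n <- 40
    d <- data.frame(group = sample(c("SCD", "control"), n, replace = TRUE),
                    age = runif(n, 7, 32),
                    sex = sample(c("male", "female"), n, replace = TRUE),
                    hemoglobin = rnorm(n, 11, 2),
                    icv = rnorm(n, 1400, 100))
    d$gmv <- rnorm(n, 620, 50)
    d$wmv <- rnorm(n, 440, 50)
    res <- fit_family(regression_spec("hemoglobin"), d)
    X <- cbind(1, d$hemoglobin, d$age, as.numeric(d$sex == "male"), d$icv)
    for (j in 1:2) {
      orc <- ols_normal_equations(X, d[[res$outcome[j]]])
      expect_equal(res$coefficient[j], orc$beta[2], tolerance = 1e-8)
      expect_equal(res$raw_p[j], orc$p[2], tolerance = 1e-8)
      expect_equal(unlist(res[j, c("coef_intercept", "coef_age",
                                   "coef_sex", "coef_icv")], use.names = FALSE),
                   orc$beta[c(1, 3, 4, 5)], tolerance = 1e-8)
    }
  }
})

test_that("log-burden families exclude zero-burden participants and say so", {
  co <- generate_cohort(cohort_spec(n_scd = 60, n_control = 30,
                                    sci_prevalence = 0.5, seed = 14))
  n_zero <- sum(co$group == "SCD" & co$total_burden == 0)
  expect_message(res <- fit_family(regression_spec("log10_burden"), co),
                 sprintf("excluding %d zero-burden", n_zero))
  expect_equal(unique(res$n), sum(co$group == "SCD" & co$total_burden > 0))
  expect_match(unique(res$group), "SCD w/ SCI")
})

test_that("degenerate designs fail with informative errors", {
  d <- exact_linear_cohort(n = 24)
  d$icv <- 2 * d$age + 1            # collinear with age
  expect_error(fit_family(regression_spec("hemoglobin"), d), "collinear")
  d2 <- exact_linear_cohort(n = 5)
  expect_error(fit_family(regression_spec("hemoglobin"), d2), "usable rows")
  d3 <- exact_linear_cohort(n = 24)
  d3$total_burden <- 0
  expect_error(suppressMessages(
    fit_family(regression_spec("log10_burden"), d3)), "cohort_filter")
})

test_that("adjusted p-values in one family ignore other families entirely", {
  co <- generate_cohort(cohort_spec(seed = 19))
  alone <- fit_family(regression_spec("hemoglobin"), co)
  # fitting other exposures' families must not perturb this family
  invisible(fit_family(regression_spec("scd_status"), co))
  invisible(fit_family(regression_spec("cao2"), co))
  again <- fit_family(regression_spec("hemoglobin"), co)
  expect_identical(alone, again)
})

test_that("the burden-decade reading follows the fitted coefficient", {
  d1 <- decade_deficit(-30.2, 0.1, 1.0)
  expect_equal(d1$predicted_change, -30.2)
  expect_equal(d1$ratio, 30.2 / 0.9, tolerance = 1e-12)
  d2 <- decade_deficit(-30.2, 1.0, 10.0)
  expect_equal(d2$predicted_change, -30.2)
  expect_equal(d2$ratio, 30.2 / 9, tolerance = 1e-12)
  # decade invariance of the predicted change
  for (x in c(0.05, 0.3, 2)) {
    expect_equal(decade_deficit(-7.7, x, 10 * x)$predicted_change, -7.7)
  }
  expect_error(decade_deficit(-30.2, 0, 1), "burden_from")
  expect_error(decade_deficit(-30.2, 1, 0.5), "burden_from")
})

test_that("regional analysis flags an injected caudate effect with high power", {
  eff <- list(gm_cbf = c(left_caudate = -0.0053))
  hits <- vapply(1:150, function(s) {
    co <- generate_cohort(cohort_spec(seed = 1000 + s, regional_effects = eff))
    res <- fit_family(regression_spec("gm_cbf", outcomes = default_structures()), co)
    res$bh_p[res$outcome == "left_caudate"] < 0.05
  }, logical(1))
  expect_gt(mean(hits), 0.8)
})

test_that("regional plumbing validates rosters and required columns", {
  co <- generate_cohort(cohort_spec(n_scd = 30, n_control = 20, seed = 6))
  expect_warning(regional_analysis(co, exposures = "hemoglobin",
                                   structures = default_structures()[1:10]),
                 "not 66")
  expect_error(suppressWarnings(
    regional_analysis(co, exposures = "hemoglobin",
                      structures = c("left_thalamus", "no_such_structure"))),
    "no_such_structure")
  expect_error(regional_analysis(co, exposures = "hemoglobin",
                                 structures = default_structures()[1:10],
                                 strict = TRUE),
               "not 66")
  res <- regional_analysis(co, exposures = c("hemoglobin", "scd_status"))
  expect_equal(nrow(res), 2 * 66)
  expect_equal(unique(table(res$exposure)), c(66L))
})
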