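# Synthetic cohort and ASL-study generation: determinism, distributional
# targets and participant invariants.

test_that("identical seeds give bit-identical cohorts", {
  a <- generate_cohort(cohort_spec(n_scd = 30, n_control = 15, seed = 5))
  b <- generate_cohort(cohort_spec(n_scd = 30, n_control = 15, seed = 5))
  expect_identical(a, b)
  c <- generate_cohort(cohort_spec(n_scd = 30, n_control = 15, seed = 6))
  expect_false(identical(a$hemoglobin, c$hemoglobin))
})

test_that("an empty SCD group yields controls only, with no lesions", {
  co <- generate_cohort(cohort_spec(n_scd = 0, n_control = 5, seed = 2))
  expect_equal(nrow(co), 5L)
  expect_true(all(co$group == "control"))
  expect_true(all(co$n_lesions == 0L))
  expect_true(all(lengths(co$lesions) == 0L))
})

test_that("invalid specs are rejected naming the offending field", {
  expect_error(cohort_spec(n_scd = -1), "n_scd")
  expect_error(cohort_spec(sci_prevalence = 1.2), "sci_prevalence")
  expect_error(cohort_spec(burden_scale = 0), "burden_scale")
  expect_error(cohort_spec(residual_sd = -3), "residual_sd")
  expect_error(cohort_spec(volume_model = "nope"), "volume_model")
})

test_that("participant invariants hold across a large generated cohort", {
  co <- generate_cohort(cohort_spec(n_scd = 300, n_control = 200, seed = 9))
  expect_true(all(co$gmv > 0 & co$wmv > 0))
  expect_true(all(co$icv > co$gmv + co$wmv))
  expect_true(all(co$hematocrit > 0.1 & co$hematocrit < 0.6))
  expect_true(all(co$sao2 > 0.5 & co$sao2 <= 1.0))
  # healthy controls with SCI would have been excluded from enrolment
  expect_true(all(lengths(co$lesions[co$group == "control"]) == 0L))
  expect_equal(co$cao2, co$sao2 * co$hemoglobin * 1.37)
  expect_equal(co$hematocrit, 0.03 * co$hemoglobin)
})

test_that("SCI prevalence matches the binomial expectation at scale", {
  co <- generate_cohort(cohort_spec(n_scd = 880, n_control = 490,
                                    sci_prevalence = 0.35, seed = 3))
  phat <- mean(co$sci_present[co$group == "SCD"])
  half_width <- qnorm(0.995) * sqrt(0.35 * 0.65 / 880)  # binomial 99% CI
  expect_lt(abs(phat - 0.35), half_width)
})

test_that("group hemoglobin means land within 3 standard errors of target", {
  co <- generate_cohort(cohort_spec(n_scd = 600, n_control = 600, seed = 4))
  for (g in c("SCD", "control")) {
    p <- default_group_distributions()[[g]]$hemoglobin
    x <- co$hemoglobin[co$group == g]
    expect_lt(abs(mean(x) - p["mean"]), 3 * p["sd"] / sqrt(length(x)))
  }
})

test_that("lesion-positive burdens are exponential-like with the set mean", {
  co <- generate_cohort(cohort_spec(n_scd = 2000, n_control = 0,
                                    sci_prevalence = 1, burden_scale = 0.3,
                                    seed = 8))
  b <- co$total_burden
  expect_true(all(b > 0))
  expect_equal(mean(b), 0.3, tolerance = 0.05)
  # exponential signature: sd ~ mean, median ~ mean * ln 2
  expect_equal(sd(b) / mean(b), 1, tolerance = 0.1)
})

test_that("sub-threshold distractor lesions never count toward burden", {
  co <- generate_cohort(cohort_spec(n_scd = 200, n_control = 0,
                                    sci_prevalence = 1,
                                    subthreshold_rate = 2, seed = 12))
  for (i in seq_len(nrow(co))) {
    kept <- filter_lesions(co$lesions[[i]])
    expect_equal(co$n_lesions[i], length(kept))
    expect_equal(co$total_burden[i], burden_from_lesions(kept)$total_burden)
  }
  # with rate 2 the filter must actually be exercised
  expect_gt(sum(lengths(co$lesions)) - sum(co$n_lesions), 0)
})

test_that("zero-flow studies produce an identically zero difference series", {
  sim <- generate_asl_study(protocol = asl_protocol("adult"),
                            grid = asl_grid(c(4, 4, 2)),
                            cbf_gm = 0, cbf_wm = 0, hct = 0.4, group = "control")
  expect_true(all(sim$study$diff_series == 0))
})

test_that("noisy repeat means concentrate around the noiseless signal", {
  prot <- asl_protocol("pediatric")
  grid <- asl_grid(c(8, 8, 3))
  clean <- generate_asl_study(protocol = prot, grid = grid, cbf_gm = 70,
                              hct = 0.27, group = "SCD")
  noisy <- generate_asl_study(protocol = prot, grid = grid, cbf_gm = 70,
                              hct = 0.27, group = "SCD",
                              noise_sd = 0.5, seed = 21)
  dm_clean <- clean$study$diff_series[, , , 1]
  dm_mean <- apply(noisy$study$diff_series, 1:3, mean)
  # Gaussian standard error: 4 sd / sqrt(averages) covers ~99.99% per voxel
  frac_within <- mean(abs(dm_mean - dm_clean) <= 4 * 0.5 / sqrt(prot$averages))
  expect_gte(frac_within, 0.99)
})

test_that("a linear drift is removed by quantification's detrending", {
  prot <- asl_protocol("pediatric")
  drifty <- generate_asl_study(protocol = prot, grid = asl_grid(c(6, 6, 2)),
                               cbf_gm = 55, hct = 0.27, group = "SCD",
                               drift = 3, seed = 30)
  map <- quantify_cbf(drifty$study, prot, drifty$gm_params, drifty$wm_params)
  expect_equal(map$gm_mean, 55, tolerance = 1e-9)
})

test_that("simulation refuses protocols where no bolus has arrived", {
  slow <- quant_params("WM", "control", hct = 0.4, bat = 4)
  expect_error(
    generate_asl_study(protocol = asl_protocol("adult"), grid = asl_grid(c(4, 4, 2)),
                       cbf_gm = 50, hct = 0.4, group = "control",
                       wm_params = slow),
    "no labeled bolus")
})
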