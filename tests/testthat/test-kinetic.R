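# Hematocrit-corrected single-PLD kinetic model: blood T1, forward
# signal, drift removal and voxelwise quantification.

test_that("blood T1 matches hand evaluation of the relaxivity formula", {
  # 1 / (0.52 * 0.40 + 0.38) and 1 / (0.52 * 0.27 + 0.38)
  expect_equal(blood_t1_from_hct(0.40), 1.7006803, tolerance = 1e-6)
  expect_equal(blood_t1_from_hct(0.27), 1.9215988, tolerance = 1e-6)
  # anemia lengthens blood T1
  expect_gt(blood_t1_from_hct(0.30), blood_t1_from_hct(0.45))
  expect_error(blood_t1_from_hct(40), "fraction")
  expect_error(blood_t1_from_hct(0), "fraction")
})

test_that("protocol dialects carry the printed timing constants", {
  ad <- asl_protocol("adult")
  pe <- asl_protocol("pediatric")
  expect_equal(c(ad$pld, ad$tau), c(1.9, 1.0))
  expect_equal(c(pe$pld, pe$tau), c(1.65, 1.65))
  expect_error(asl_protocol("custom"), "requires")
  expect_error(asl_protocol("custom", pld = -1, tau = 1), "positive")
})

test_that("forward model is zero at zero flow and linear in flow and M0", {
  prot <- asl_protocol("pediatric")
  par <- quant_params("GM", "SCD", hct = 0.27)
  expect_identical(forward_delta_m(0, 1000, prot, par), 0)
  dm1 <- forward_delta_m(50, 1000, prot, par)
  expect_equal(forward_delta_m(100, 1000, prot, par), 2 * dm1)
  expect_equal(forward_delta_m(50, 2000, prot, par), 2 * dm1)
})

test_that("signal decays strictly as PLD grows beyond the arrival time", {
  par <- quant_params("GM", "control", hct = 0.40)
  plds <- seq(par$bat, par$bat + 1.5, by = 0.1)
  dm <- vapply(plds, function(p) {
    forward_delta_m(60, 1000, asl_protocol("custom", pld = p, tau = 1.0), par)
  }, numeric(1))
  expect_true(all(diff(dm) < 0))
})

test_that("during-bolus and post-bolus branches join continuously at PLD = BAT", {
  par <- quant_params("GM", "control", hct = 0.40, bat = 1.2)
  eps <- 1e-9
  lo <- forward_delta_m(60, 1000, asl_protocol("custom", pld = 1.2 - eps, tau = 1), par)
  hi <- forward_delta_m(60, 1000, asl_protocol("custom", pld = 1.2 + eps, tau = 1), par)
  expect_equal(lo, hi, tolerance = 1e-6)
  # no signal at all before any bolus arrives
  expect_error(
    forward_delta_m(60, 1000, asl_protocol("custom", pld = 0.1, tau = 0.2), par),
    "no labeled bolus")
})

test_that("forward-inverse closure holds across dialects, groups and tissues", {
  for (dial in c("adult", "pediatric")) {
    for (grp in c("SCD", "control")) {
      prot <- asl_protocol(dial)
      hct <- if (grp == "SCD") 0.27 else 0.40
      for (tis in c("GM", "WM")) {
        par <- quant_params(tis, grp, hct = hct)
        f_true <- c(5, 50.64, 82.47, 120)
        dm <- forward_delta_m(f_true, 1500, prot, par)
        expect_equal(invert_delta_m(dm / 1500, prot, par), f_true,
                     tolerance = 1e-9)
      }
    }
  }
})

test_that("estimated CBF falls as the assumed blood T1 lengthens", {
  prot <- asl_protocol("adult")
  dm_norm <- 0.005
  f <- vapply(c(1.5, 1.7, 1.9, 2.1), function(t1b) {
    invert_delta_m(dm_norm, prot,
                   quant_params("GM", "control", t1_blood = t1b))
  }, numeric(1))
  expect_true(all(diff(f) < 0))
})

test_that("detrending removes an exact linear drift and preserves means", {
  d <- c(3, 3, 2, 8)
  base <- array(runif(prod(d[1:3]), 1, 2), d[1:3])
  series <- array(rep(base, d[4]), d)
  expect_equal(detrend_series(series), series)   # no-op on trendless data

  tc <- seq_len(d[4]) - (d[4] + 1) / 2
  drift <- array(rep(0.7 * tc, each = prod(d[1:3])), d)
  expect_equal(detrend_series(series + drift), series, tolerance = 1e-12)

  set.seed(11)
  noisy <- array(rnorm(prod(d)), d)
  out <- detrend_series(noisy)
  expect_equal(apply(out, 1:3, mean), apply(noisy, 1:3, mean), tolerance = 1e-12)
  expect_error(detrend_series(noisy[, , , 1:2, drop = FALSE]), "at least 3")
})

test_that("quantification inverts a noiseless study to machine precision", {
  prot <- asl_protocol("pediatric")
  sim <- generate_asl_study(protocol = prot, grid = asl_grid(c(8, 8, 3)),
                            cbf_gm = 50, cbf_wm = 25, hct = 0.27, group = "SCD")
  map <- quantify_cbf(sim$study, prot, sim$gm_params, sim$wm_params)
  expect_equal(map$gm_mean, 50, tolerance = 1e-9)
  expect_equal(map$wm_mean, 25, tolerance = 1e-9)

  # scale invariance: doubling M0 and the difference series changes nothing
  st <- sim$study
  st2 <- asl_study(2 * st$m0, 2 * st$diff_series, st$gm_mask, st$wm_mask)
  map2 <- quantify_cbf(st2, prot, sim$gm_params, sim$wm_params)
  expect_equal(map2$cbf, map$cbf, tolerance = 1e-12)
})

test_that("the M0 floor excludes degenerate voxels from tissue means", {
  prot <- asl_protocol("pediatric")
  sim <- generate_asl_study(protocol = prot, grid = asl_grid(c(6, 6, 2)),
                            cbf_gm = 60, hct = 0.27, group = "SCD")
  st <- sim$study
  st$m0[1, 1, 1] <- 1e-6          # GM voxel with collapsed M0
  map <- quantify_cbf(st, prot, sim$gm_params, sim$wm_params)
  expect_equal(unname(map$n_excluded["GM"]), 1L)
  expect_false(map$valid[1, 1, 1])
  expect_equal(map$gm_mean, 60, tolerance = 1e-9)
})

test_that("empty masks are rejected by name", {
  prot <- asl_protocol("pediatric")
  sim <- generate_asl_study(protocol = prot, grid = asl_grid(c(4, 4, 2)),
                            cbf_gm = 60, hct = 0.27, group = "SCD")
  st <- sim$study
  st$gm_mask[] <- FALSE
  expect_error(quantify_cbf(st, prot, sim$gm_params, sim$wm_params), "gm_mask")
})

test_that("noisy quantification is unbiased over repeated seeds", {
  prot <- asl_protocol("pediatric")
  grid <- asl_grid(c(6, 6, 2))
  means <- vapply(1:120, function(s) {
    sim <- generate_asl_study(protocol = prot, grid = grid, cbf_gm = 60,
                              hct = 0.27, group = "SCD",
                              noise_sd = 1, seed = s)
    quantify_cbf(sim$study, prot, sim$gm_params, sim$wm_params)$gm_mean
  }, numeric(1))
  expect_equal(mean(means), 60, tolerance = 0.005)
})
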