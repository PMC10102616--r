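# Synthetic cohort generation: participants with demographics, blood
# labs, tissue volumes generated from a known linear model, and silent
# infarct lesions, so every downstream stage can be validated against
# ground truth.

#' Default exposure effect table
#'
#' True generating coefficients (mL of tissue volume per unit exposure)
#' used by the synthetic cohort: one (GMV, WMV) pair per exposure of
#' interest. Values are the fitted primary-analysis coefficients from
#' the sickle-cell brain-volume cohort this package models, so
#' recovering them from simulated data is the core validation.
#'
#' @return Named list mapping exposure to `c(gmv =, wmv =)` coefficients.
#' @export
default_effect_table <- function() {
  list(
    scd_status   = c(gmv = -10.4,  wmv = -15.6),
    hemoglobin   = c(gmv = 2.43,   wmv = 3.15),
    gm_cbf       = c(gmv = -0.129, wmv = -0.343),
    cao2         = c(gmv = 1.76,   wmv = 2.27),
    log10_burden = c(gmv = -10.4,  wmv = -30.2)
  )
}

# Exposure reference points used to center the generating linear
# predictor so baseline volumes stay realistic; slopes are unaffected.
.exposure_refs <- c(scd_status = 0, hemoglobin = 13.28, gm_cbf = 50.64,
                    cao2 = 17.38, log10_burden = log10(0.14))

#' Default per-group demographic and physiologic distributions
#'
#' Location/scale parameters emulating the study cohort: SCD
#' participants are anemic (hemoglobin mean 9.04 g/dL vs. 13.28 in
#' controls), mildly desaturated (SaO2 median 0.96 vs. 0.98), younger on
#' average, and hyperperfused (GM CBF mean 82.47 vs. 50.64
#' ml/100 g/min). Median/IQR summaries are mapped to normal
#' location/scale via sd = IQR/1.349. ICV is N(1400, 120) mL for both
#' groups.
#'
#' @return Nested list with `control` and `SCD` entries.
#' @export
default_group_distributions <- function() {
  list(
    control = list(age = c(mean = 23.75, sd = 12.83 / 1.349),
                   hemoglobin = c(mean = 13.28, sd = 1.57),
                   sao2 = c(mean = 0.98, sd = 0.020 / 1.349),
                   icv = c(mean = 1400, sd = 120),
                   gm_cbf = c(mean = 50.64, sd = 8.9),
                   p_male = 0.429),
    SCD = list(age = c(mean = 18.06, sd = 15.42 / 1.349),
               hemoglobin = c(mean = 9.04, sd = 1.37),
               sao2 = c(mean = 0.96, sd = 0.0326 / 1.349),
               icv = c(mean = 1400, sd = 120),
               gm_cbf = c(mean = 82.47, sd = 17.92),
               p_male = 0.489)
  )
}

#' Specification of a synthetic cohort
#'
#' Collects every knob of the cohort generator. Volumes are generated
#' from one designated exposure (`volume_model`) using the matching
#' `effect_table` row plus age/sex/ICV covariate effects and Gaussian
#' residual; infarct burden is exponential among lesion-positive SCD
#' participants; hematocrit follows the clinical rule of three,
#' Hct = 0.03 x Hb.
#'
#' @param n_scd,n_control Group sizes (non-negative integers).
#' @param seed Integer seed; identical seed gives a bit-identical cohort.
#' @param effect_table See [default_effect_table()].
#' @param volume_model Exposure whose effect-table row generates GMV/WMV.
#' @param residual_sd Gaussian residual SD of the volume models, mL.
#' @param sci_prevalence Fraction of SCD participants with silent
#'   infarcts, in `[0, 1]`.
#' @param burden_scale Mean of the exponential total-burden distribution,
#'   mL.
#' @param subthreshold_rate Expected number of additional sub-criterion
#'   lesions per lesion-positive participant (these exercise the
#'   SIT-trial filter and never count toward burden).
#' @param covariate_effects List with `gmv` and `wmv` entries, each
#'   `c(age =, sex =, icv =)` in mL per year / mL for male / mL per mL.
#' @param group_distributions See [default_group_distributions()].
#' @param regional_cv Coefficient of variation of regional structure
#'   volumes about their baselines.
#' @param regional_effects Optional named list mapping exposure name to a
#'   named vector of per-structure true coefficients (mL per unit
#'   exposure), injected additively into regional volumes.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_scd = 88, n_control = 49, seed = 1,
                        effect_table = default_effect_table(),
                        volume_model = "scd_status",
                        residual_sd = 40,
                        sci_prevalence = 0.35,
                        burden_scale = 0.3,
                        subthreshold_rate = 0.5,
                        covariate_effects = list(
                          gmv = c(age = -1.5, sex = 15, icv = 0.25),
                          wmv = c(age = 1.5, sex = 10, icv = 0.25)),
                        group_distributions = default_group_distributions(),
                        regional_cv = 0.08,
                        regional_effects = NULL) {
  bad <- function(field, why) {
    stop(sprintf("invalid cohort spec: `%s` %s", field, why), call. = FALSE)
  }
  if (!is.numeric(n_scd) || n_scd < 0 || n_scd != round(n_scd))
    bad("n_scd", "must be a non-negative integer")
  if (!is.numeric(n_control) || n_control < 0 || n_control != round(n_control))
    bad("n_control", "must be a non-negative integer")
  if (!is.numeric(sci_prevalence) || sci_prevalence < 0 || sci_prevalence > 1)
    bad("sci_prevalence", "must lie in [0, 1]")
  if (!is.numeric(burden_scale) || burden_scale <= 0)
    bad("burden_scale", "must be positive (mL)")
  if (!is.numeric(residual_sd) || residual_sd <= 0)
    bad("residual_sd", "must be positive (mL)")
  if (!volume_model %in% names(effect_table))
    bad("volume_model", paste("must name an effect_table entry; got", volume_model))
  if (!is.numeric(seed) || !is.finite(seed))
    bad("seed", "must be a finite integer")
  structure(list(n_scd = as.integer(n_scd), n_control = as.integer(n_control),
                 seed = as.integer(seed), effect_table = effect_table,
                 volume_model = volume_model, residual_sd = residual_sd,
                 sci_prevalence = sci_prevalence, burden_scale = burden_scale,
                 subthreshold_rate = subthreshold_rate,
                 covariate_effects = covariate_effects,
                 group_distributions = group_distributions,
                 regional_cv = regional_cv,
                 regional_effects = regional_effects),
            class = "cohort_spec")
}

# Draw lesions for one lesion-positive participant: qualifying lesions
# whose traced volumes sum to the drawn burden (dims guarantee the 3 mm
# criterion), plus sub-threshold distractor lesions that the SIT filter
# must remove.
.draw_lesions <- function(total_burden, subthreshold_rate) {
  k <- 1L + stats::rpois(1L, 3L)
  w <- stats::runif(k)
  vols <- total_burden * w / sum(w)
  les <- lapply(vols, function(v) {
    lesion(dims = c(stats::runif(1, 3, 8), stats::runif(2, 1, 5)),
           volume = v, visible_in_second_plane = TRUE)
  })
  n_sub <- stats::rpois(1L, subthreshold_rate)
  if (n_sub > 0) {
    sub <- lapply(seq_len(n_sub), function(i) {
      not_visible <- stats::runif(1) < 0.5
      dims <- if (not_visible) c(stats::runif(1, 3, 6), stats::runif(2, 1, 3))
              else stats::runif(3, 0.5, 2.9)
      lesion(dims = dims, volume = stats::runif(1, 0.001, 0.01),
             visible_in_second_plane = !not_visible)
    })
    les <- c(les, sub)
  }
  les
}

#' Generate a synthetic cohort
#'
#' Draws `n_scd + n_control` participants from the spec's group
#' distributions, assigns silent-infarct lesions to a `sci_prevalence`
#' fraction of the SCD group with exponentially distributed total burden,
#' and generates GMV/WMV from the designated exposure's true coefficients
#' plus covariate effects and Gaussian residual. Burden columns are
#' computed through [filter_lesions()] and [burden_from_lesions()], so
#' sub-threshold distractor lesions never contribute. The output is a
#' pure function of the spec (including its seed).
#'
#' @param spec A [cohort_spec()].
#' @return A `data.frame` (class `scd_cohort`) with one row per
#'   participant: demographics, labs, derived physiology, global and
#'   regional volumes, lesion summaries, and a `lesions` list-column.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_scd + spec$n_control
  if (n == 0L) stop("invalid cohort spec: `n_scd` + `n_control` is zero", call. = FALSE)

  with_preserved_seed(spec$seed, {
    group <- rep(c("SCD", "control"), c(spec$n_scd, spec$n_control))
    draw <- function(field) {
      vapply(group, function(g) {
        p <- spec$group_distributions[[g]][[field]]
        stats::rnorm(1L, p["mean"], p["sd"])
      }, numeric(1), USE.NAMES = FALSE)
    }
    age <- pmin(pmax(draw("age"), 7), 32)
    hemoglobin <- pmax(draw("hemoglobin"), 3)
    sao2 <- pmin(pmax(draw("sao2"), 0.5), 1.0)
    icv <- pmax(draw("icv"), 900)
    true_gm_cbf <- pmax(draw("gm_cbf"), 10)
    p_male <- vapply(group, function(g) spec$group_distributions[[g]]$p_male,
                     numeric(1), USE.NAMES = FALSE)
    sex <- ifelse(stats::runif(n) < p_male, "male", "female")

    hematocrit <- 0.03 * hemoglobin
    cao2 <- compute_cao2(sao2, hemoglobin)

    sci <- group == "SCD" & stats::runif(n) < spec$sci_prevalence
    lesions <- vector("list", n)
    total_burden <- numeric(n)
    n_lesions <- integer(n)
    for (i in seq_len(n)) {
      if (sci[i]) {
        burden_i <- stats::rexp(1L, rate = 1 / spec$burden_scale)
        lesions[[i]] <- .draw_lesions(burden_i, spec$subthreshold_rate)
      } else {
        lesions[[i]] <- list()
      }
      b <- burden_from_lesions(filter_lesions(lesions[[i]]))
      total_burden[i] <- b$total_burden
      n_lesions[i] <- b$n_lesions_counted
    }
    log10_burden <- ifelse(total_burden > 0, log10(total_burden), NA_real_)

    exposures <- data.frame(scd_status = as.numeric(group == "SCD"),
                            hemoglobin = hemoglobin, gm_cbf = true_gm_cbf,
                            cao2 = cao2, log10_burden = log10_burden)
    xc_of <- function(e) {
      x <- exposures[[e]] - .exposure_refs[[e]]
      ifelse(is.na(x), 0, x)   # zero-burden rows carry no burden effect
    }
    xc <- xc_of(spec$volume_model)
    male <- as.numeric(sex == "male")
    coefs <- spec$effect_table[[spec$volume_model]]
    ce <- spec$covariate_effects
    lin <- function(base, slope, cv) {
      base + slope * xc + cv["age"] * (age - 20) + cv["sex"] * male +
        cv["icv"] * (icv - 1400) + stats::rnorm(n, 0, spec$residual_sd)
    }
    gmv <- pmax(lin(619.4, coefs[["gmv"]], ce$gmv), 100)
    wmv <- pmax(lin(441.3, coefs[["wmv"]], ce$wmv), 100)

    ventricle_volume <- pmax(stats::rnorm(n, 15, 4), 2)
    icv <- pmax(icv, gmv + wmv + ventricle_volume + 20)

    bases <- .structure_baselines()
    regional <- matrix(stats::rnorm(n * length(bases),
                                    mean = rep(bases, each = n),
                                    sd = rep(spec$regional_cv * bases, each = n)),
                       nrow = n, dimnames = list(NULL, names(bases)))
    for (e in names(spec$regional_effects)) {
      eff <- spec$regional_effects[[e]]
      xe <- xc_of(e)
      for (s in names(eff)) regional[, s] <- regional[, s] + eff[[s]] * xe
    }
    regional <- pmax(regional, 0.01)

    out <- data.frame(id = sprintf("P%03d", seq_len(n)), group = group,
                      age = age, sex = sex, hemoglobin = hemoglobin,
                      hematocrit = hematocrit, sao2 = sao2, cao2 = cao2,
                      icv = icv, gmv = gmv, wmv = wmv,
                      ventricle_volume = ventricle_volume,
                      true_gm_cbf = true_gm_cbf, sci_present = sci,
                      n_lesions = n_lesions, total_burden = total_burden,
                      log10_burden = log10_burden,
                      stringsAsFactors = FALSE)
    out <- cbind(out, as.data.frame(regional))
    out$lesions <- I(lesions)
    attr(out, "spec") <- spec
    class(out) <- c("scd_cohort", "data.frame")
    out
  })
}
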