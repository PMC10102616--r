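# Per-exposure multivariable regression families: one OLS fit per
# outcome with age, sex and ICV as covariates, Benjamini-Hochberg
# correction applied within each exposure's family only.

.exposures <- c("scd_status", "hemoglobin", "gm_cbf", "cao2", "log10_burden")

#' Specification of one regression family
#'
#' One exposure of interest, its ordered outcome volumes and cohort
#' filter. Covariates are fixed at age, sex and ICV for every model; the
#' log-burden exposure is only defined among SCD participants with
#' silent infarcts, so its filter is forced to `scd_with_sci`.
#'
#' @param exposure One of `"scd_status"`, `"hemoglobin"`, `"gm_cbf"`,
#'   `"cao2"`, `"log10_burden"`.
#' @param outcomes Ordered character vector of outcome volume columns.
#' @param cohort_filter `"all"` or `"scd_with_sci"`; defaults by exposure.
#' @return An object of class `regression_spec`.
#' @export
regression_spec <- function(exposure, outcomes = c("gmv", "wmv"),
                            cohort_filter = NULL) {
  exposure <- match.arg(exposure, .exposures)
  if (is.null(cohort_filter))
    cohort_filter <- if (exposure == "log10_burden") "scd_with_sci" else "all"
  cohort_filter <- match.arg(cohort_filter, c("all", "scd_with_sci"))
  if (exposure == "log10_burden" && cohort_filter != "scd_with_sci")
    stop("log10_burden regressions require cohort_filter = 'scd_with_sci'",
         call. = FALSE)
  if (length(outcomes) < 1L) stop("at least one outcome is required", call. = FALSE)
  structure(list(exposure = exposure, outcomes = outcomes,
                 covariates = c("age", "sex", "icv"),
                 cohort_filter = cohort_filter),
            class = "regression_spec")
}

# Exposure values on the regression scale. gm_cbf prefers a measured
# column (from ASL quantification) over the generator's ground truth.
.exposure_values <- function(cohort, exposure) {
  switch(exposure,
         scd_status = as.numeric(cohort$group == "SCD"),
         hemoglobin = cohort$hemoglobin,
         gm_cbf = if ("gm_cbf" %in% names(cohort)) cohort$gm_cbf
                  else cohort$true_gm_cbf,
         cao2 = if ("cao2" %in% names(cohort)) cohort$cao2
                else compute_cao2(cohort$sao2, cohort$hemoglobin),
         log10_burden = cohort$log10_burden)
}

.group_label <- function(cohort_filter, n) {
  if (cohort_filter == "scd_with_sci") sprintf("SCD w/ SCI (n = %d)", n)
  else sprintf("HC + SCD (n = %d)", n)
}

#' Fit one regression family
#'
#' For each outcome, fits ordinary least squares
#' `outcome ~ exposure + age + sex + icv` (sex coded male = 1,
#' female = 0) on complete cases passing the cohort filter, takes the
#' two-sided t-test p-value of the exposure coefficient (n - 5 residual
#' degrees of freedom), and applies Benjamini-Hochberg correction across
#' this family's outcomes only. Participants with zero infarct burden
#' are necessarily excluded from log-burden families (log10 of 0 is
#' undefined); the exclusion count is reported via `message()`.
#'
#' @param spec A [regression_spec()].
#' @param cohort A cohort data frame ([generate_cohort()] output or a
#'   table read with [read_cohort_tsv()]).
#' @return Data frame with one row per outcome, in `spec$outcomes`
#'   order: `exposure`, `outcome`, `coefficient`, `raw_p`, `bh_p`, `n`,
#'   `group`, plus the full coefficient vector
#'   (`coef_intercept`, `coef_age`, `coef_sex`, `coef_icv`).
#' @export
fit_family <- function(spec, cohort) {
  stopifnot(inherits(spec, "regression_spec"))
  missing_out <- setdiff(spec$outcomes, names(cohort))
  if (length(missing_out))
    stop("cohort lacks outcome column(s): ", paste(missing_out, collapse = ", "),
         call. = FALSE)

  keep <- if (spec$cohort_filter == "scd_with_sci") {
    cohort$group == "SCD" & cohort$total_burden > 0
  } else rep(TRUE, nrow(cohort))
  if (spec$exposure == "log10_burden") {
    n_zero <- sum(cohort$group == "SCD" & !(cohort$total_burden > 0))
    message(sprintf("log10_burden family: excluding %d zero-burden SCD participant(s)",
                    n_zero))
  }
  sub <- cohort[keep, , drop = FALSE]
  if (nrow(sub) == 0L)
    stop("no participants pass cohort_filter '", spec$cohort_filter, "'",
         call. = FALSE)

  x <- .exposure_values(sub, spec$exposure)
  dd <- data.frame(exposure = x, age = sub$age,
                   sex = as.numeric(sub$sex == "male"), icv = sub$icv)
  Y <- as.matrix(sub[, spec$outcomes, drop = FALSE])
  cc <- stats::complete.cases(dd) & stats::complete.cases(Y)
  dd <- dd[cc, , drop = FALSE]
  Y <- Y[cc, , drop = FALSE]
  n <- nrow(dd)
  p <- 5L
  if (n < p + 2L)
    stop(sprintf("family '%s': only %d usable rows; need at least %d",
                 spec$exposure, n, p + 2L), call. = FALSE)

  fit <- stats::lm(Y ~ exposure + age + sex + icv, data = dd)
  qr_ <- fit$qr
  if (qr_$rank < p) {
    aliased <- colnames(qr_$qr)[qr_$pivot[(qr_$rank + 1L):p]]
    stop("rank-deficient design; collinear column(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  est <- as.matrix(stats::coef(fit))
  res <- as.matrix(stats::residuals(fit))
  xtx_inv_diag <- numeric(p)
  xtx_inv_diag[qr_$pivot] <- diag(chol2inv(qr.R(qr_)))
  sigma2 <- colSums(res^2) / (n - p)
  se <- sqrt(outer(xtx_inv_diag, sigma2))
  tval <- est / se
  pval <- 2 * stats::pt(-abs(tval), df = n - p)

  raw_p <- pval["exposure", ]
  out <- data.frame(exposure = spec$exposure, outcome = spec$outcomes,
                    coefficient = est["exposure", ],
                    raw_p = raw_p, bh_p = bh_adjust(raw_p),
                    n = n, group = .group_label(spec$cohort_filter, n),
                    coef_intercept = est["(Intercept)", ],
                    coef_age = est["age", ], coef_sex = est["sex", ],
                    coef_icv = est["icv", ],
                    row.names = NULL, stringsAsFactors = FALSE)
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard BH adjusted p-values: sort ascending, multiply the i-th by
#' m/i, enforce monotonicity from the largest down, cap at 1, return in
#' input order. Applied within one regression family at a time — never
#' across families — matching the per-exposure correction scope.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(pvals) {
  if (length(pvals) == 0L) return(numeric(0))
  if (any(!is.finite(pvals)) || any(pvals < 0) || any(pvals > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(pvals, method = "BH")
}

#' Volume deficit implied by a burden decade
#'
#' Interprets a log10-burden regression coefficient: the predicted
#' volume change when total burden moves from `burden_from` to
#' `burden_to` is `coefficient * log10(to/from)` (so exactly one
#' coefficient's worth per 10-fold increase), and the ratio compares its
#' magnitude to the burden increase itself. A ratio far above 1 means
#' the modeled tissue loss dwarfs the infarcted volume.
#'
#' @param coefficient_log10 Fitted coefficient, mL per decade of burden.
#' @param burden_from,burden_to Burden range, mL, `0 < from < to`.
#' @return List with `predicted_change` (mL) and `ratio`
#'   (|change| / burden increase, dimensionless).
#' @export
decade_deficit <- function(coefficient_log10, burden_from, burden_to) {
  if (!is.finite(burden_from) || !is.finite(burden_to) ||
      burden_from <= 0 || burden_to <= burden_from)
    stop("require 0 < burden_from < burden_to", call. = FALSE)
  change <- coefficient_log10 * (log10(burden_to) - log10(burden_from))
  list(predicted_change = change,
       ratio = abs(change) / (burden_to - burden_from))
}

#' Regional (secondary) regression analysis
#'
#' Fits one family per exposure over the regional structure volumes,
#' with BH correction within each exposure's 66-structure family.
#'
#' @param cohort Cohort data frame containing the structure columns.
#' @param exposures Character vector of exposures of interest.
#' @param structures Structure roster; [default_structures()] by
#'   default. A roster of length other than 66 is accepted with a
#'   warning (`strict = TRUE` upgrades it to an error).
#' @param strict Error instead of warn on a non-66 roster.
#' @return Row-bound [fit_family()] tables over all exposures.
#' @export
regional_analysis <- function(cohort, exposures = .exposures,
                              structures = default_structures(),
                              strict = FALSE) {
  if (length(structures) != 66L) {
    msg <- sprintf("structure roster has %d entries, not 66", length(structures))
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  missing_s <- setdiff(structures, names(cohort))
  if (length(missing_s))
    stop("cohort lacks structure volume(s): ", paste(missing_s, collapse = ", "),
         call. = FALSE)
  do.call(rbind, lapply(exposures, function(e) {
    fit_family(regression_spec(e, outcomes = structures), cohort)
  }))
}
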