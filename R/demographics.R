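# Demographics-table machinery: two-group comparisons with the
# dispatch used in clinical tables — Welch t for normal continuous
# data, Mann-Whitney U otherwise, chi-squared for categorical data with
# Fisher's exact test when expected cell counts are small. All tests
# are two-sided.

.summ_mean_sd <- function(x) sprintf("%.2f (%.2f)", mean(x), stats::sd(x))
.summ_median_iqr <- function(x) sprintf("%.2f (%.2f)", stats::median(x), stats::IQR(x))
.summ_count_pct <- function(x, level) {
  k <- sum(x == level)
  sprintf("%d (%.1f%%)", k, 100 * k / length(x))
}

#' Compare one variable between two groups
#'
#' Continuous variables use Welch's t-test when both groups look normal
#' and the Mann-Whitney U test otherwise; `normal = "auto"` decides by
#' Shapiro-Wilk at alpha 0.05 in each group, and an explicit
#' `TRUE`/`FALSE` pins the choice. Categorical variables use the
#' chi-squared test, falling back to Fisher's exact test for small cell
#' counts (any expected or observed cell below 5). Group summaries follow the test
#' family: mean (SD) for normal, median (IQR) otherwise, count (%) for
#' categorical.
#'
#' @param values_by_group Named list of exactly two vectors, one per
#'   group.
#' @param kind `"continuous"` or `"categorical"`.
#' @param normal `"auto"`, `TRUE` or `FALSE` (continuous only).
#' @param variable Optional variable name carried into the result.
#' @return An object of class `group_comparison`: variable, test used,
#'   statistic, two-sided p-value and per-group summaries.
#' @export
compare_groups <- function(values_by_group, kind = c("continuous", "categorical"),
                           normal = "auto", variable = NULL) {
  kind <- match.arg(kind)
  if (!is.list(values_by_group) || length(values_by_group) != 2L)
    stop("`values_by_group` must be a list of exactly two groups", call. = FALSE)
  g1 <- values_by_group[[1]]
  g2 <- values_by_group[[2]]
  if (length(g1) == 0L || length(g2) == 0L)
    stop("both groups must be nonempty", call. = FALSE)
  gnames <- names(values_by_group)
  if (is.null(gnames)) gnames <- c("group1", "group2")

  if (kind == "continuous") {
    if (identical(normal, "auto")) {
      sw_ok <- function(x) {
        if (length(unique(x)) < 3L || length(x) < 3L) return(FALSE)
        stats::shapiro.test(x)$p.value > 0.05
      }
      normal <- sw_ok(g1) && sw_ok(g2)
    }
    if (isTRUE(normal)) {
      ht <- stats::t.test(g1, g2, alternative = "two.sided", var.equal = FALSE)
      test <- "t"
      summ <- c(.summ_mean_sd(g1), .summ_mean_sd(g2))
    } else {
      ht <- suppressWarnings(
        stats::wilcox.test(g1, g2, alternative = "two.sided"))
      test <- "mann_whitney"
      summ <- c(.summ_median_iqr(g1), .summ_median_iqr(g2))
    }
  } else {
    tab <- table(factor(rep(gnames, c(length(g1), length(g2))), levels = gnames),
                 c(as.character(g1), as.character(g2)))
    expected <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))$expected
    if (any(expected < 5) || any(tab < 5)) {
      ht <- stats::fisher.test(tab, alternative = "two.sided")
      test <- "fisher"
    } else {
      # continuity-corrected for 2x2 (the default), so large-sample p-values
      # track the exact test
      ht <- suppressWarnings(stats::chisq.test(tab))
      test <- "chi2"
    }
    lev <- colnames(tab)[1]
    summ <- c(.summ_count_pct(as.character(g1), lev),
              .summ_count_pct(as.character(g2), lev))
  }
  names(summ) <- gnames
  structure(list(variable = variable, test = test,
                 statistic = unname(if (!is.null(ht$statistic)) ht$statistic else NA_real_),
                 p = unname(ht$p.value), summaries = summ),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: %s vs %s; %s test, p = %.4g\n",
              if (is.null(x$variable)) "comparison" else x$variable,
              x$summaries[1], x$summaries[2], x$test, x$p))
  invisible(x)
}

# Default demographics rows: column, label, kind, normality handling.
# SCD-only rows are summarized without a between-group test.
.demographics_rows <- function() {
  list(
    list(column = "sex", label = "Male sex, n (percent)", kind = "categorical"),
    list(column = "age", label = "Age at MRI, years, median (IQR)",
         kind = "continuous", normal = FALSE),
    list(column = "hemoglobin", label = "Hemoglobin, g/dL, mean (SD)",
         kind = "continuous", normal = TRUE),
    list(column = "sao2", label = "SaO2, fraction, median (IQR)",
         kind = "continuous", normal = FALSE),
    list(column = "cao2", label = "CaO2, mL/dL, mean (SD)",
         kind = "continuous", normal = TRUE),
    list(column = "gmv", label = "Gray matter volume, mL, mean (SD)",
         kind = "continuous", normal = TRUE),
    list(column = "wmv", label = "White matter volume, mL, mean (SD)",
         kind = "continuous", normal = TRUE),
    list(column = "true_gm_cbf", label = "GM CBF, ml/100 g/min, mean (SD)",
         kind = "continuous", normal = TRUE),
    list(column = "sci_present", label = "SCI present, n (percent)",
         kind = "scd_only_count"),
    list(column = "total_burden", label = "Total SCI burden, mL, median (IQR)",
         kind = "scd_only_median")
  )
}

#' Build a demographics comparison table
#'
#' Emits one row per configured variable with control and SCD summaries
#' and a two-sided p-value from [compare_groups()]; SCD-only rows
#' (infarct prevalence and burden) are summarized without a test.
#' Variables absent from the cohort are skipped with a warning.
#'
#' @param cohort Cohort data frame with a two-level `group` column.
#' @param rows Row configuration; see the default for the format.
#' @return Data frame: `variable`, `control`, `scd`, `test`, `p`.
#' @export
build_demographics_table <- function(cohort, rows = .demographics_rows()) {
  if (nrow(cohort) == 0L) stop("cohort is empty", call. = FALSE)
  groups <- unique(cohort$group)
  if (length(groups) != 2L)
    stop("demographics table requires both groups; found: ",
         paste(groups, collapse = ", "), call. = FALSE)
  ctrl <- cohort[cohort$group == "control", , drop = FALSE]
  scd <- cohort[cohort$group == "SCD", , drop = FALSE]

  out <- lapply(rows, function(r) {
    if (!r$column %in% names(cohort)) {
      warning("skipping demographics row for absent variable `", r$column, "`",
              call. = FALSE)
      return(NULL)
    }
    if (r$kind == "scd_only_count") {
      x <- scd[[r$column]]
      data.frame(variable = r$label, control = "n/a",
                 scd = .summ_count_pct(as.character(as.logical(x)), "TRUE"),
                 test = "none", p = NA_real_, stringsAsFactors = FALSE)
    } else if (r$kind == "scd_only_median") {
      x <- scd[[r$column]]
      x <- x[x > 0]
      data.frame(variable = r$label, control = "n/a",
                 scd = if (length(x)) .summ_median_iqr(x) else "n/a",
                 test = "none", p = NA_real_, stringsAsFactors = FALSE)
    } else {
      cmp <- compare_groups(list(control = ctrl[[r$column]], SCD = scd[[r$column]]),
                            kind = r$kind,
                            normal = if (is.null(r$normal)) "auto" else r$normal,
                            variable = r$label)
      data.frame(variable = r$label, control = cmp$summaries[["control"]],
                 scd = cmp$summaries[["SCD"]], test = cmp$test, p = cmp$p,
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, out)
}
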