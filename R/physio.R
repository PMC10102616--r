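#' Arterial oxygen content
#'
#' CaO2 (ml O2 / 100 g blood) from oxygen saturation and hemoglobin:
#' `sao2 * hemoglobin * 1.37`, where 1.37 is the oxygen-binding capacity
#' of hemoglobin in ml O2 per gram. Anemia lowers CaO2 even at normal
#' saturation, which is the physiologic driver of compensatory CBF
#' elevation in sickle cell disease.
#'
#' @param sao2 Oxygen saturation as a fraction in (0, 1]. Values above
#'   1.5 are rejected as likely percent-unit mistakes.
#' @param hemoglobin Hemoglobin concentration, g/dL, strictly positive.
#' @return CaO2 in ml O2 / 100 g blood.
#' @examples
#' compute_cao2(0.96, 9.04)  # anemic: ~11.9
#' compute_cao2(0.98, 13.28) # healthy: ~17.8
#' @export
compute_cao2 <- function(sao2, hemoglobin) {
  if (any(!is.finite(sao2)) || any(sao2 > 1.5))
    stop("`sao2` must be a fraction in (0, 1]; divide percent values by 100.",
         call. = FALSE)
  if (any(sao2 <= 0) || any(sao2 > 1))
    stop("`sao2` must be in (0, 1]", call. = FALSE)
  if (any(!is.finite(hemoglobin)) || any(hemoglobin <= 0))
    stop("`hemoglobin` must be positive (g/dL)", call. = FALSE)
  sao2 * hemoglobin * 1.37
}

#' White matter volume by subtraction
#'
#' WMV is defined as total brain volume excluding ventricles minus gray
#' matter volume, matching how segmentation suites report it.
#'
#' @param total_excl_ventricles Total brain volume excluding ventricles, mL.
#' @param gmv Gray matter volume, mL.
#' @return White matter volume, mL.
#' @export
derive_wmv <- function(total_excl_ventricles, gmv) {
  if (any(total_excl_ventricles <= 0) || any(gmv <= 0))
    stop("volumes must be positive", call. = FALSE)
  if (any(gmv >= total_excl_ventricles))
    stop("`gmv` must be smaller than `total_excl_ventricles`", call. = FALSE)
  total_excl_ventricles - gmv
}

#' Construct a lesion record
#'
#' A traced candidate infarct: its three orthogonal extents in mm, its
#' traced volume in mL, and whether it was confirmed in a second imaging
#' plane (the confirmation itself is a manual radiological judgement and
#' enters here as a flag).
#'
#' @param dims Numeric length-3, extents in mm, all positive.
#' @param volume Traced lesion volume, mL, positive.
#' @param visible_in_second_plane Logical flag.
#' @return A `lesion` object.
#' @export
lesion <- function(dims, volume, visible_in_second_plane = TRUE) {
  if (length(dims) != 3L || any(!is.finite(dims)) || any(dims <= 0))
    stop("`dims` must be three positive extents in mm", call. = FALSE)
  if (!is.finite(volume) || volume <= 0)
    stop("`volume` must be positive (mL)", call. = FALSE)
  structure(list(dims = as.numeric(dims), volume = as.numeric(volume),
                 visible_in_second_plane = isTRUE(visible_in_second_plane)),
            class = "lesion")
}

#' Filter lesions by the SIT-trial silent-infarct criterion
#'
#' Retains lesions measuring at least 3 mm in at least one plane AND
#' visible in a second imaging plane; both conditions are required.
#' Order is preserved and the filter is idempotent.
#'
#' @param lesions List of [lesion()] objects.
#' @param min_dim Minimum extent in mm (default 3, the SIT-trial value).
#' @return The qualifying subset, order preserved.
#' @export
filter_lesions <- function(lesions, min_dim = 3) {
  stopifnot(is.list(lesions))
  keep <- vapply(lesions, function(l) {
    stopifnot(inherits(l, "lesion"))
    max(l$dims) >= min_dim && l$visible_in_second_plane
  }, logical(1))
  lesions[keep]
}

#' Total infarct burden from qualifying lesions
#'
#' Sums per-lesion traced volumes into a total burden and provides its
#' log10 transform, which is only defined for positive burden; zero
#' burden yields an absent (`NA`) log value, and such participants are
#' excluded from log-burden regressions downstream.
#'
#' @param lesions List of [lesion()] objects, already filtered by
#'   [filter_lesions()].
#' @return A list with `total_burden` (mL), `log10_burden` (`NA` when the
#'   burden is zero) and `n_lesions_counted`.
#' @export
burden_from_lesions <- function(lesions) {
  stopifnot(is.list(lesions))
  vols <- vapply(lesions, function(l) {
    stopifnot(inherits(l, "lesion"))
    l$volume
  }, numeric(1))
  if (any(vols < 0)) stop("lesion volumes must be non-negative", call. = FALSE)
  total <- sum(vols)
  list(total_burden = total,
       log10_burden = if (total > 0) log10(total) else NA_real_,
       n_lesions_counted = length(vols))
}
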