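# File interfaces: TSV participant tables, FreeSurfer-style aseg.stats
# region tables, and NIfTI-1 volumes for ASL studies and CBF maps.

#' Write a participant table as TSV
#'
#' Flattens a cohort to tab-separated text. The `lesions` list-column is
#' dropped (its information is carried by the `n_lesions`,
#' `total_burden` and `log10_burden` summary columns).
#'
#' @param cohort Cohort data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort_tsv <- function(cohort, path) {
  df <- as.data.frame(cohort)
  df$lesions <- NULL
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a participant table from TSV
#'
#' Expects the column layout written by [write_cohort_tsv()]; at minimum
#' `group`, `age`, `sex`, `hemoglobin`, `sao2`, `icv`, `gmv`, `wmv`.
#' Real-data tables with measured hematocrit are accepted as-is.
#'
#' @param path TSV file path.
#' @return Data frame of class `scd_cohort`.
#' @export
read_cohort_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("group", "age", "sex", "hemoglobin", "sao2", "icv", "gmv", "wmv")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("participant table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  class(df) <- c("scd_cohort", "data.frame")
  df
}

#' Read a FreeSurfer-style aseg.stats region table
#'
#' Parses the whitespace-delimited body of an `aseg.stats` file
#' (comment lines start with `#`; the column order is taken from the
#' `# ColHeaders` line) and returns structure volumes in mL.
#'
#' @param path Path to the stats file.
#' @return Named numeric vector: structure name -> volume in mL.
#' @export
read_aseg_stats <- function(path) {
  lines <- readLines(path)
  header <- grep("^# ColHeaders", lines, value = TRUE)
  if (length(header) != 1L)
    stop("no `# ColHeaders` line found in ", path, call. = FALSE)
  cols <- strsplit(sub("^# ColHeaders\\s+", "", header), "\\s+")[[1]]
  i_vol <- match("Volume_mm3", cols)
  i_name <- match("StructName", cols)
  if (is.na(i_vol) || is.na(i_name))
    stop("stats file must have Volume_mm3 and StructName columns", call. = FALSE)
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  fields <- strsplit(trimws(body), "\\s+")
  vols <- vapply(fields, function(f) as.numeric(f[i_vol]), numeric(1))
  names(vols) <- vapply(fields, function(f) f[i_name], character(1))
  vols / 1000   # mm^3 -> mL
}

.as_nifti <- function(arr, affine) {
  img <- RNifti::asNifti(arr)
  RNifti::sform(img) <- structure(affine, code = 2L)
  img
}

#' Write an ASL study as NIfTI-1 volumes
#'
#' Writes `m0.nii.gz`, `diff.nii.gz` (4-D), `gm_mask.nii.gz` and
#' `wm_mask.nii.gz` under `dir`, all sharing the study affine.
#'
#' @param study An [asl_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_asl_study <- function(study, dir) {
  stopifnot(inherits(study, "asl_study"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  aff <- study$affine
  RNifti::writeNifti(.as_nifti(study$m0, aff), file.path(dir, "m0.nii.gz"))
  RNifti::writeNifti(.as_nifti(study$diff_series, aff), file.path(dir, "diff.nii.gz"))
  RNifti::writeNifti(.as_nifti(study$gm_mask * 1L, aff), file.path(dir, "gm_mask.nii.gz"))
  RNifti::writeNifti(.as_nifti(study$wm_mask * 1L, aff), file.path(dir, "wm_mask.nii.gz"))
  invisible(dir)
}

#' Read an ASL study from NIfTI-1 volumes
#'
#' Counterpart of [write_asl_study()].
#'
#' @param dir Directory containing `m0`, `diff`, `gm_mask`, `wm_mask`
#'   NIfTI volumes.
#' @return An [asl_study()].
#' @export
read_asl_study <- function(dir) {
  rd <- function(name) {
    f <- file.path(dir, paste0(name, ".nii.gz"))
    if (!file.exists(f)) stop("missing volume: ", f, call. = FALSE)
    as.array(RNifti::readNifti(f))
  }
  m0 <- rd("m0")
  asl_study(m0 = m0, diff_series = rd("diff"),
            gm_mask = rd("gm_mask") > 0.5, wm_mask = rd("wm_mask") > 0.5,
            affine = unclass(RNifti::xform(RNifti::readNifti(file.path(dir, "m0.nii.gz")))))
}

#' Write a CBF map as NIfTI-1
#'
#' @param map A `cbf_map` from [quantify_cbf()].
#' @param path Output `.nii.gz` path.
#' @param affine Voxel-to-world transform.
#' @return `path`, invisibly.
#' @export
write_cbf_map <- function(map, path, affine = diag(c(3, 3, 7.5, 1))) {
  stopifnot(inherits(map, "cbf_map"))
  RNifti::writeNifti(.as_nifti(map$cbf, affine), path)
  invisible(path)
}
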