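#' @name cohort_manifest
#' @title Cohort manifest
#'
#' @description
#' The manifest binds mask files to their role in the study design. One row
#' per (patient, scan, structure, role): `patient_id`, `scan_id` (one of
#' pCT, pMR, MR10, MR20, MR30), `structure`, `role` (ground_truth,
#' propagated_CT_MR, propagated_MR_MR, redelineation_IOV) and `path`.
#' Propagated and re-delineated records are evaluated against the
#' ground-truth record of the same structure on the same scan, which must
#' therefore exist.
NULL

dirqa_scans <- function() c("pCT", "pMR", "MR10", "MR20", "MR30")

dirqa_roles <- function() {
  c("ground_truth", "propagated_CT_MR", "propagated_MR_MR",
    "redelineation_IOV")
}

manifest_columns <- function() {
  c("patient_id", "scan_id", "structure", "role", "path")
}

#' Validate a cohort manifest
#'
#' Checks the manifest invariants and reports every violation with the
#' offending row number(s).
#'
#' @param manifest data frame with the columns of [cohort_manifest].
#' @return The manifest (invisibly) if valid; otherwise an error listing
#'   all violations.
#' @export
validate_manifest <- function(manifest) {
  miss <- setdiff(manifest_columns(), names(manifest))
  if (length(miss))
    stop("manifest is missing columns: ", paste(miss, collapse = ", "))
  probs <- character(0)
  bad_scan <- which(!manifest$scan_id %in% dirqa_scans())
  if (length(bad_scan))
    probs <- c(probs, sprintf("row %d: unknown scan_id '%s'",
                              bad_scan, manifest$scan_id[bad_scan]))
  bad_role <- which(!manifest$role %in% dirqa_roles())
  if (length(bad_role))
    probs <- c(probs, sprintf("row %d: unknown role '%s'",
                              bad_role, manifest$role[bad_role]))
  key <- paste(manifest$patient_id, manifest$scan_id, manifest$structure,
               manifest$role, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup))
    probs <- c(probs, sprintf(
      "row %d: duplicate (patient, scan, structure, role)", dup))
  gt_key <- paste(manifest$patient_id, manifest$scan_id,
                  manifest$structure, sep = "\r")
  has_gt <- gt_key %in% gt_key[manifest$role == "ground_truth"]
  orphan <- which(manifest$role != "ground_truth" & !has_gt)
  if (length(orphan))
    probs <- c(probs, sprintf(
      "row %d: %s record without ground truth on scan %s",
      orphan, manifest$role[orphan], manifest$scan_id[orphan]))
  if (length(probs))
    stop("manifest validation failed:\n  ",
         paste(probs, collapse = "\n  "), call. = FALSE)
  invisible(manifest)
}

#' Load and validate a cohort manifest CSV
#'
#' @param path CSV file with the columns of [cohort_manifest]. Relative
#'   `path` entries are resolved against the directory of the manifest.
#' @return Validated manifest data frame. An empty file (header only)
#'   yields an empty, valid manifest.
#' @export
load_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  man <- as.data.frame(readr::read_csv(path, col_types = readr::cols(
    patient_id = readr::col_character(),
    scan_id = readr::col_character(),
    structure = readr::col_character(),
    role = readr::col_character(),
    path = readr::col_character())))
  validate_manifest(man)
  rel <- !is.na(man$path) & nzchar(man$path) &
    !grepl("^(/|[A-Za-z]:)", man$path)
  man$path[rel] <- file.path(dirname(path), man$path[rel])
  man
}

#' Write a cohort manifest CSV
#' @param manifest validated manifest data frame.
#' @param path destination CSV.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  validate_manifest(manifest)
  readr::write_csv(manifest[, manifest_columns()], path)
  invisible(path)
}
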