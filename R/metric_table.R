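#' Metric record tables
#'
#' One row per evaluated (patient, scan, structure, comparison arm):
#' `dsc` (dimensionless), `msd` and `hd` (mm), `volume_test_cm3` and
#' `volume_ref_cm3`, plus a `status` column ("ok" or a failure tag for
#' empty-mask pairs, kept as findings rather than dropped) and topology
#' tags of the evaluated mask. CSV round trips preserve numeric fields to
#' full double precision.
#'
#' @param records metric record data frame (see [compare_structures()]).
#' @param path CSV destination / source.
#' @return `write_metric_table()` returns `path` invisibly;
#'   `read_metric_table()` the records data frame.
#' @export
write_metric_table <- function(records, path) {
  miss <- setdiff(metric_columns(), names(records))
  if (length(miss))
    stop("records are missing columns: ", paste(miss, collapse = ", "))
  out <- records[, metric_columns()]
  # 17 significant digits guarantee a bit-exact double round trip
  for (cl in c("dsc", "msd", "hd", "volume_test_cm3", "volume_ref_cm3")) {
    v <- sprintf("%.17g", out[[cl]])
    v[is.na(out[[cl]])] <- NA_character_
    out[[cl]] <- v
  }
  readr::write_csv(out, path, na = "NA")
  invisible(path)
}

#' @rdname write_metric_table
#' @export
read_metric_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  spec <- readr::cols(
    patient_id = readr::col_character(),
    scan_id = readr::col_character(),
    structure = readr::col_character(),
    arm = readr::col_character(),
    status = readr::col_character(),
    dsc = readr::col_character(),
    msd = readr::col_character(),
    hd = readr::col_character(),
    volume_test_cm3 = readr::col_character(),
    volume_ref_cm3 = readr::col_character(),
    n_components = readr::col_integer(),
    has_handle = readr::col_logical())
  rec <- readr::read_csv(path, col_types = spec, na = "NA")
  # doubles parsed via R's strtod (correctly rounded) for exact round trips
  for (cl in c("dsc", "msd", "hd", "volume_test_cm3", "volume_ref_cm3"))
    rec[[cl]] <- as.numeric(rec[[cl]])
  pr <- readr::problems(rec)
  if (nrow(pr))
    stop("malformed metric table rows: ",
         paste(unique(pr$row), collapse = ", "))
  miss <- setdiff(metric_columns(), names(rec))
  if (length(miss))
    stop("metric table is missing columns: ", paste(miss, collapse = ", "))
  as.data.frame(rec)
}

metric_columns <- function() {
  c("patient_id", "scan_id", "structure", "arm", "status",
    "dsc", "msd", "hd", "volume_test_cm3", "volume_ref_cm3",
    "n_components", "has_handle")
}
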