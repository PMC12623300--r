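#' Read / write a cohort table
#'
#' Cohorts travel as comma-separated UTF-8 text with a header.  The only
#' required column is `ccv4_label`; recognised optional columns are typed
#' and validated (`patient_id`, `flip_v2`, `flip_v1`, `irp_supine`,
#' `irp_upright`, `tbe_present`, `tbe_h1`, `tbe_h5`, `tbe_tablet`, and any
#' metric columns).  Malformed rows are reported with their row numbers,
#' never silently dropped.
#'
#' @param path File path.
#' @param cohort Data frame to write.
#' @return `read_cohort()`: a validated tibble. `write_cohort()`: the input,
#'   invisibly.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) {
    abort_panometry(sprintf("cohort file not found: %s", path),
                    "panometry_io_error")
  }
  cohort <- readr::read_csv(path, show_col_types = FALSE)
  check_columns(cohort, "ccv4_label", "read_cohort")

  report_bad <- function(ok, what) {
    rows <- which(!(ok %in% TRUE))
    if (length(rows) > 0) {
      abort_panometry(
        sprintf("invalid %s in row(s) %s.", what,
                paste(utils::head(rows, 10), collapse = ", ")),
        "panometry_invalid_cohort")
    }
  }
  report_bad(cohort$ccv4_label %in% ccv4_levels(), "ccv4_label")
  if ("flip_v2" %in% names(cohort)) {
    ok <- is.na(cohort$flip_v2) | cohort$flip_v2 %in% motility_levels_v2()
    report_bad(ok, "flip_v2")
    cohort$flip_v2 <- factor(cohort$flip_v2, levels = motility_levels_v2())
  }
  if ("flip_v1" %in% names(cohort)) {
    ok <- is.na(cohort$flip_v1) | cohort$flip_v1 %in% motility_levels_v1()
    report_bad(ok, "flip_v1")
    cohort$flip_v1 <- factor(cohort$flip_v1, levels = motility_levels_v1())
  }
  if ("tbe_tablet" %in% names(cohort)) {
    # an all-missing column arrives typeless; it is a categorical field
    if (is.logical(cohort$tbe_tablet)) {
      cohort$tbe_tablet <- as.character(cohort$tbe_tablet)
    }
    ok <- is.na(cohort$tbe_tablet) |
      cohort$tbe_tablet %in% c("not_administered", "passed", "impacted")
    report_bad(ok, "tbe_tablet")
  }
  for (col in c("tbe_h1", "tbe_h5", "irp_supine", "irp_upright")) {
    if (col %in% names(cohort)) {
      if (is.logical(cohort[[col]])) cohort[[col]] <- as.numeric(cohort[[col]])
      ok <- is.na(cohort[[col]]) | (is.numeric(cohort[[col]]) & cohort[[col]] >= 0)
      report_bad(ok, col)
    }
  }
  cohort
}

#' @rdname read_cohort
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(tibble::as_tibble(cohort), path, na = "")
  invisible(cohort)
}
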