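#' Classify the contractile response (scheme v2.0)
#'
#' Applies the v2.0 contractile-response (CR) rules to a metrics table
#' (one row per study, columns as produced by [extract_metrics()]), with
#' fixed precedence — spastic dominates everything, then normal, then the
#' diminished/disordered pressure split, then absent:
#'
#' 1. **SPASTIC** if a sustained occluding contraction or a sustained LES
#'    contraction is present;
#' 2. **NORMAL** if more than one (`> 1`) distinct qualifying antegrade
#'    contraction (at least 6 cm, pressure rise above 10 mmHg);
#' 3. otherwise, if any contractility is present: **DIMINISHED** when the
#'    60-mL pressure is at or below 40 mmHg, **DISORDERED** when above;
#' 4. **ABSENT** when no contractile activity is present in the esophageal
#'    body.
#'
#' Boundary behaviour is fixed: pressure exactly 40 mmHg is DIMINISHED
#' (the split is "at or below"); exactly 2 qualifying contractions is
#' NORMAL ("more than 1").
#'
#' @param data Data frame with columns `n_qualifying_antegrade`,
#'   `any_contractility`, `sustained_occluding`, `sustained_les`,
#'   `pressure_60`.
#' @param params A [flip_params()].
#' @return The input as a tibble with a `cr_v2` factor column appended.
#' @export
#' @examples
#' m <- tibble::tibble(n_qualifying_antegrade = 2, any_contractility = TRUE,
#'                     sustained_occluding = FALSE, sustained_les = FALSE,
#'                     pressure_60 = 35)
#' classify_cr_v2(m)$cr_v2
classify_cr_v2 <- function(data, params = flip_params()) {
  check_columns(data, c("n_qualifying_antegrade", "any_contractility",
                        "sustained_occluding", "sustained_les", "pressure_60"),
                "classify_cr_v2")
  out <- dplyr::mutate(
    tibble::as_tibble(data),
    cr_v2 = factor(dplyr::case_when(
      sustained_occluding | sustained_les ~ "SPASTIC",
      n_qualifying_antegrade >= params$min_antegrade ~ "NORMAL",
      any_contractility & pressure_60 <= params$pressure_split ~ "DIMINISHED",
      any_contractility ~ "DISORDERED",
      TRUE ~ "ABSENT"
    ), levels = cr_levels_v2())
  )
  out
}

#' Classify the contractile response (scheme v1.0)
#'
#' The v1.0 CR rules differ from v2.0 only in that diminished and disordered
#' are not split by the 40-mmHg pressure threshold: both fall into a single
#' impaired/disordered pattern.  Spastic features trigger the
#' spastic-reactive pattern (the v1.0 name for the same flags).
#'
#' @inheritParams classify_cr_v2
#' @return The input as a tibble with a `cr_v1` factor column appended.
#' @export
classify_cr_v1 <- function(data, params = flip_params()) {
  check_columns(data, c("n_qualifying_antegrade", "any_contractility",
                        "sustained_occluding", "sustained_les"),
                "classify_cr_v1")
  dplyr::mutate(
    tibble::as_tibble(data),
    cr_v1 = factor(dplyr::case_when(
      sustained_occluding | sustained_les ~ "SPASTIC_REACTIVE",
      n_qualifying_antegrade >= params$min_antegrade ~ "NORMAL",
      any_contractility ~ "IMPAIRED_DISORDERED",
      TRUE ~ "ABSENT"
    ), levels = cr_levels_v1())
  )
}

#' Classify EGJ opening
#'
#' Applies the consensus EGJ-opening thresholds: **NORMAL** when the 60-mL
#' EGJ distensibility index is at least 2.0 mm^2/mmHg *and* the maximum EGJ
#' diameter is at least 16 mm; **REDUCED** when the index is below 2.0 *and*
#' the maximum diameter is below 12 mm; **INCONCLUSIVE** otherwise.  The
#' numeric cut-offs come from the consensus literature and are configurable
#' through [flip_params()].  (v1.0 called the middle class "borderline";
#' criteria are identical.)
#'
#' @param data Data frame with columns `egj_di_60`, `max_egj_diameter`.
#' @param params A [flip_params()].
#' @return The input as a tibble with an `egj_opening` factor column.
#' @export
#' @examples
#' classify_egj_opening(tibble::tibble(egj_di_60 = 1.0, max_egj_diameter = 10))
classify_egj_opening <- function(data, params = flip_params()) {
  check_columns(data, c("egj_di_60", "max_egj_diameter"), "classify_egj_opening")
  if (any(data$egj_di_60 <= 0, na.rm = TRUE) ||
      any(data$max_egj_diameter <= 0, na.rm = TRUE)) {
    abort_panometry("egj_di_60 and max_egj_diameter must be positive.",
                    "panometry_invalid_argument")
  }
  dplyr::mutate(
    tibble::as_tibble(data),
    egj_opening = factor(dplyr::case_when(
      egj_di_60 >= params$egj_di_normal &
        max_egj_diameter >= params$max_diameter_normal ~ "NORMAL",
      egj_di_60 < params$egj_di_normal &
        max_egj_diameter < params$max_diameter_reduced ~ "REDUCED",
      TRUE ~ "INCONCLUSIVE"
    ), levels = egj_opening_levels())
  )
}

#' Assign the motility class from CR pattern and EGJ opening
#'
#' Pure table lookup: the (CR pattern, EGJ opening) pair is mapped to the
#' motility class through a [decision_table()].  Any pair missing from the
#' table raises a table-incomplete error (unreachable for the shipped,
#' validated tables).
#'
#' @param data Data frame holding the CR and EGJ-opening columns.
#' @param table A [decision_table()]; determines the scheme version.
#' @param cr_col,egjo_col,out_col Column names for the CR pattern input, the
#'   EGJ-opening input, and the appended motility class.
#' @return The input as a tibble with the motility-class factor column
#'   appended.
#' @export
#' @examples
#' x <- tibble::tibble(cr_v2 = "ABSENT", egj_opening = "REDUCED")
#' classify_motility(x, decision_table("v2"))$motility_v2
classify_motility <- function(data, table = decision_table("v2"),
                              cr_col = NULL, egjo_col = "egj_opening",
                              out_col = NULL) {
  stopifnot(inherits(table, "decision_table"))
  version <- attr(table, "version")
  cr_col <- cr_col %||% paste0("cr_", version)
  out_col <- out_col %||% paste0("motility_", version)
  check_columns(data, c(cr_col, egjo_col), "classify_motility")

  key <- paste(as.character(data[[cr_col]]), as.character(data[[egjo_col]]))
  lut <- stats::setNames(table$motility, paste(table$cr, table$egj_opening))
  hit <- lut[key]
  bad <- is.na(hit) & !is.na(key) & !(is.na(data[[cr_col]]) | is.na(data[[egjo_col]]))
  if (any(bad)) {
    abort_panometry(
      sprintf("decision table %s has no entry for: %s.", version,
              paste(unique(key[bad]), collapse = "; ")),
      "panometry_table_incomplete")
  }
  out <- tibble::as_tibble(data)
  out[[out_col]] <- factor(unname(hit), levels = motility_levels(version))
  out
}

# internal: motility level set for a scheme version
motility_levels <- function(version) {
  switch(version, v2 = motility_levels_v2(), v1 = motility_levels_v1(),
         abort_panometry(sprintf("unknown scheme version '%s'.", version),
                         "panometry_invalid_argument"))
}

#' One-call FLIP classification
#'
#' Convenience wrapper running [classify_egj_opening()], [classify_cr_v2()]
#' and/or [classify_cr_v1()], and [classify_motility()] on a metrics table,
#' appending `egj_opening`, `cr_v2`/`cr_v1` and `motility_v2`/`motility_v1`
#' columns.
#'
#' @param data Metrics data frame (see [extract_metrics()]).
#' @param scheme `"v2"`, `"v1"`, or `"both"`.
#' @param params A [flip_params()].
#' @return Tibble with the classification columns appended.
#' @export
classify_flip <- function(data, scheme = c("v2", "v1", "both"),
                          params = flip_params()) {
  scheme <- match.arg(scheme)
  out <- classify_egj_opening(data, params)
  if (scheme %in% c("v2", "both")) {
    out <- classify_cr_v2(out, params)
    out <- classify_motility(out, decision_table("v2"))
  }
  if (scheme %in% c("v1", "both")) {
    out <- classify_cr_v1(out, params)
    out <- classify_motility(out, decision_table("v1"))
  }
  out
}
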