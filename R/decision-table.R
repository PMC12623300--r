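#' Motility-classification decision tables
#'
#' The motility class is a total, single-valued mapping from (CR pattern,
#' EGJ opening) pairs.  `decision_table("v2")` ships the v2.0 mapping
#' (15 cells):
#'
#' | EGJ opening | CR pattern | motility class |
#' |---|---|---|
#' | NORMAL | NORMAL | NORMAL |
#' | NORMAL | DIMINISHED, ABSENT | HYPOCONTRACTILITY |
#' | NORMAL, INCONCLUSIVE | DISORDERED, SPASTIC | POSSIBLE_SPASM |
#' | INCONCLUSIVE | NORMAL, DIMINISHED, ABSENT | POSSIBLE_OBSTRUCTION |
#' | REDUCED | ABSENT, DIMINISHED | NON_SPASTIC_OBSTRUCTION |
#' | REDUCED | DISORDERED, SPASTIC | SPASTIC_OBSTRUCTION |
#' | REDUCED | NORMAL | OBSTRUCTION_NORMAL_CR |
#'
#' Each cell carries a provenance note: `"paper-anchored"` for cells fixed by
#' the published criteria, `"consensus-default"` for cells reconstructed from
#' the consensus scheme (all INCONCLUSIVE-opening cells, and the whole v1.0
#' table), `"user-override"` for cells edited via `overrides`.  The mapping
#' of a spastic CR with inconclusive opening to POSSIBLE_SPASM is a
#' documented default, overridable.
#'
#' `decision_table("v1")` reconstructs the v1.0 scheme (12 cells) with its
#' class names: weak, obstruction with weak CR, spastic-reactive,
#' obstruction with normal CR, and borderline/other for the
#' borderline-opening column.
#'
#' @param version `"v2"` or `"v1"`.
#' @param overrides Optional data frame with columns `cr`, `egj_opening`,
#'   `motility` replacing individual cells (marked `"user-override"`).
#' @return A tibble of class `decision_table` with columns `cr`,
#'   `egj_opening`, `motility`, `provenance` and a `version` attribute.
#' @export
#' @examples
#' decision_table("v2")
decision_table <- function(version = c("v2", "v1"), overrides = NULL) {
  version <- match.arg(version)
  tab <- if (version == "v2") decision_cells_v2() else decision_cells_v1()
  if (!is.null(overrides)) {
    check_columns(overrides, c("cr", "egj_opening", "motility"), "decision_table")
    for (i in seq_len(nrow(overrides))) {
      hit <- tab$cr == overrides$cr[i] & tab$egj_opening == overrides$egj_opening[i]
      if (!any(hit)) {
        abort_panometry(
          sprintf("override targets unknown cell (%s, %s).",
                  overrides$cr[i], overrides$egj_opening[i]),
          "panometry_invalid_argument")
      }
      tab$motility[hit] <- overrides$motility[i]
      tab$provenance[hit] <- "user-override"
    }
  }
  structure(tab, version = version, class = c("decision_table", class(tab)))
}

# internal: v2.0 cells
decision_cells_v2 <- function() {
  cell <- function(cr, egjo, mot, prov) {
    tibble::tibble(cr = cr, egj_opening = egjo, motility = mot, provenance = prov)
  }
  dplyr::bind_rows(
    cell("NORMAL", "NORMAL", "NORMAL", "paper-anchored"),
    cell("DIMINISHED", "NORMAL", "HYPOCONTRACTILITY", "paper-anchored"),
    cell("ABSENT", "NORMAL", "HYPOCONTRACTILITY", "paper-anchored"),
    cell("DISORDERED", "NORMAL", "POSSIBLE_SPASM", "paper-anchored"),
    cell("SPASTIC", "NORMAL", "POSSIBLE_SPASM", "paper-anchored"),
    cell("NORMAL", "INCONCLUSIVE", "POSSIBLE_OBSTRUCTION", "consensus-default"),
    cell("DIMINISHED", "INCONCLUSIVE", "POSSIBLE_OBSTRUCTION", "consensus-default"),
    cell("ABSENT", "INCONCLUSIVE", "POSSIBLE_OBSTRUCTION", "consensus-default"),
    cell("DISORDERED", "INCONCLUSIVE", "POSSIBLE_SPASM", "consensus-default"),
    cell("SPASTIC", "INCONCLUSIVE", "POSSIBLE_SPASM", "consensus-default"),
    cell("NORMAL", "REDUCED", "OBSTRUCTION_NORMAL_CR", "paper-anchored"),
    cell("DIMINISHED", "REDUCED", "NON_SPASTIC_OBSTRUCTION", "paper-anchored"),
    cell("ABSENT", "REDUCED", "NON_SPASTIC_OBSTRUCTION", "paper-anchored"),
    cell("DISORDERED", "REDUCED", "SPASTIC_OBSTRUCTION", "paper-anchored"),
    cell("SPASTIC", "REDUCED", "SPASTIC_OBSTRUCTION", "paper-anchored")
  )
}

# internal: v1.0 cells — reconstructed from the published scheme summary;
# every cell is consensus-default
decision_cells_v1 <- function() {
  grid <- tidyr::expand_grid(cr = cr_levels_v1(), egj_opening = egj_opening_levels())
  grid$motility <- dplyr::case_when(
    grid$cr == "SPASTIC_REACTIVE" ~ "SPASTIC_REACTIVE",
    grid$egj_opening == "NORMAL" & grid$cr == "NORMAL" ~ "NORMAL",
    grid$egj_opening == "NORMAL" ~ "WEAK",
    grid$egj_opening == "INCONCLUSIVE" ~ "BORDERLINE_OTHER",
    grid$cr == "NORMAL" ~ "OBSTRUCTION_NORMAL_CR",
    TRUE ~ "OBSTRUCTION_WEAK_CR"
  )
  grid$provenance <- "consensus-default"
  grid
}

#' Validate a decision table
#'
#' Checks totality (every CR-by-EGJ-opening combination of the scheme
#' version mapped: 15 cells for v2.0, 12 for v1.0), single-valuedness (no
#' duplicate cells), that every motility class belongs to the version's
#' class set, and that every cell carries a recognised provenance note.
#'
#' @param table A [decision_table()] (or any data frame shaped like one,
#'   with a `version` attribute or `version` argument).
#' @param version Scheme version; defaults to the table's attribute.
#' @return A list with `valid` (logical) and `violations` (character vector
#'   describing each problem; empty when valid).
#' @export
#' @examples
#' validate_decision_table(decision_table("v2"))$valid
validate_decision_table <- function(table, version = attr(table, "version")) {
  if (is.null(version)) {
    abort_panometry("decision table version is unknown.", "panometry_invalid_argument")
  }
  cr_set <- switch(version, v2 = cr_levels_v2(), v1 = cr_levels_v1())
  violations <- character()

  expected <- tidyr::expand_grid(cr = cr_set, egj_opening = egj_opening_levels())
  key_exp <- paste(expected$cr, expected$egj_opening)
  key_got <- paste(table$cr, table$egj_opening)

  missing <- setdiff(key_exp, key_got)
  if (length(missing) > 0) {
    violations <- c(violations,
                    paste0("missing cell: ", missing))
  }
  dup <- unique(key_got[duplicated(key_got)])
  if (length(dup) > 0) {
    violations <- c(violations, paste0("duplicated cell (not single-valued): ", dup))
  }
  unknown <- setdiff(key_got, key_exp)
  if (length(unknown) > 0) {
    violations <- c(violations, paste0("cell outside the category sets: ", unknown))
  }
  bad_class <- setdiff(unique(table$motility), motility_levels(version))
  if (length(bad_class) > 0) {
    violations <- c(violations, paste0("unknown motility class: ", bad_class))
  }
  prov_ok <- c("paper-anchored", "consensus-default", "user-override")
  if (!"provenance" %in% names(table)) {
    violations <- c(violations, "provenance column missing")
  } else {
    bad_prov <- setdiff(unique(table$provenance), prov_ok)
    if (length(bad_prov) > 0) {
      violations <- c(violations, paste0("unknown provenance note: ", bad_prov))
    }
  }
  list(valid = length(violations) == 0, violations = violations)
}

#' Read / write a decision table as auditable text
#'
#' One cell per line: `version, cr, egj_opening, motility, provenance`
#' (CSV with header).  Reading re-attaches the version attribute and
#' validates the table.
#'
#' @param table A [decision_table()].
#' @param path File path.
#' @return `write_decision_table()` returns `table` invisibly;
#'   `read_decision_table()` returns a validated `decision_table`.
#' @export
write_decision_table <- function(table, path) {
  stopifnot(inherits(table, "decision_table"))
  out <- tibble::as_tibble(table)
  out <- dplyr::mutate(out, version = attr(table, "version"), .before = 1)
  readr::write_csv(out, path)
  invisible(table)
}

#' @rdname write_decision_table
#' @export
read_decision_table <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  check_columns(raw, c("version", "cr", "egj_opening", "motility", "provenance"),
                "read_decision_table")
  version <- unique(raw$version)
  if (length(version) != 1) {
    abort_panometry("a decision table file must hold exactly one scheme version.",
                    "panometry_invalid_argument")
  }
  tab <- structure(raw[, c("cr", "egj_opening", "motility", "provenance")],
                   version = version,
                   class = c("decision_table", class(tibble::tibble())))
  chk <- validate_decision_table(tab)
  if (!chk$valid) {
    abort_panometry(paste0("invalid decision table: ",
                           paste(chk$violations, collapse = "; ")),
                    "panometry_table_incomplete")
  }
  tab
}

#' @export
print.decision_table <- function(x, ...) {
  cat(sprintf("<decision_table> scheme %s, %d cells\n", attr(x, "version"), nrow(x)))
  NextMethod()
}
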