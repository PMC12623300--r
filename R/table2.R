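#' Packaged multicenter cohort contingency counts
#'
#' The package ships, as plain text, the published cross-tabulation of
#' FLIP panometry v2.0 motility classifications (columns) against HRM/CCv4.0
#' diagnoses (rows) for the 805-patient multicenter validation cohort, with
#' row and column labels verbatim.  `cohort_counts()` returns it in long
#' format; `cohort_fixture()` expands it into one record per patient with
#' the package's internal codes and TBE fields consistent with each row's
#' conclusiveness block (conclusive EGJOO rows get an abnormal TBE,
#' inconclusive-EGJOO rows a missing TBE), ready for
#' [adjudicate_diagnosis()] and the concordance operations.
#'
#' Two printed denominators in the source are internally inconsistent with
#' its own table (75 vs 76 conclusive spastic obstruction; 200 vs 199
#' possible obstruction); the fixture stores the table verbatim and derives
#' all proportions from it.
#'
#' @return `cohort_counts()`: tibble with columns `hrm_row`, `block`,
#'   `flip_column`, `n` (verbatim labels) plus internal codes `ccv4_label`
#'   and `flip_v2`.  `cohort_fixture()`: tibble with one row per patient.
#' @export
#' @examples
#' sum(cohort_counts()$n) # 805
cohort_counts <- function() {
  path <- system.file("extdata", "table2_flip_hrm_counts.csv",
                      package = "panometry", mustWork = TRUE)
  wide <- readr::read_csv(path, show_col_types = FALSE)
  long <- tidyr::pivot_longer(wide, cols = -c("hrm_row", "block"),
                              names_to = "flip_column", values_to = "n")
  hrm_map <- c(
    "Normal" = "normal", "IEM" = "IEM", "Absent" = "absent_contractility",
    "DES" = "DES", "Hypercontractile" = "hypercontractile", "EGJOO" = "EGJOO",
    "Type I achalasia" = "achalasia_I", "Type II achalasia" = "achalasia_II",
    "Type III achalasia" = "achalasia_III",
    "Inconclusive EGJOO" = "EGJOO", "Inconclusive" = "inconclusive_other"
  )
  flip_map <- c(
    "Normal" = "NORMAL", "Hypo-contractility" = "HYPOCONTRACTILITY",
    "Non-spastic obstruction" = "NON_SPASTIC_OBSTRUCTION",
    "Spastic obstruction" = "SPASTIC_OBSTRUCTION",
    "Possible spasm" = "POSSIBLE_SPASM",
    "Possible obstruction" = "POSSIBLE_OBSTRUCTION"
  )
  long$ccv4_label <- unname(hrm_map[long$hrm_row])
  long$flip_v2 <- unname(flip_map[long$flip_column])
  long
}

#' @rdname cohort_counts
#' @export
cohort_fixture <- function() {
  counts <- cohort_counts()
  rows <- counts[rep(seq_len(nrow(counts)), counts$n), ]
  conclusive_block <- rows$block == "Conclusive CCv4.0 Diagnosis"
  conclusive_egjoo <- conclusive_block & rows$ccv4_label == "EGJOO"

  # TBE consistent with each block: conclusive EGJOO was confirmed by an
  # abnormal TBE; inconclusive EGJOO lacked one (missing TBE); other labels
  # need none
  tibble::tibble(
    patient_id = sprintf("P%04d", seq_len(nrow(rows))),
    flip_v2 = factor(rows$flip_v2, levels = motility_levels_v2()),
    ccv4_label = rows$ccv4_label,
    tbe_present = conclusive_egjoo,
    tbe_h1 = ifelse(conclusive_egjoo, 10, NA_real_),
    tbe_h5 = ifelse(conclusive_egjoo, 8, NA_real_),
    tbe_tablet = ifelse(conclusive_egjoo, "not_administered", NA_character_)
  )
}
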