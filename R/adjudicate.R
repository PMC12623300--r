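#' Is a median IRP abnormal?
#'
#' Median integrated relaxation pressure (IRP) is abnormal strictly above
#' 15 mmHg for supine swallows and strictly above 12 mmHg for upright
#' swallows; exactly at the threshold is normal.  Exposed as a standalone
#' utility — diagnoses enter the adjudicator as CCv4.0 labels, not raw IRP.
#'
#' @param median_irp Numeric vector of median IRP values (mmHg).
#' @param position `"supine"` or `"upright"` (recycled).
#' @return Logical vector: `TRUE` when abnormal.
#' @export
#' @examples
#' check_irp_abnormal(c(15, 15.1), "supine")
check_irp_abnormal <- function(median_irp, position) {
  if (any(!is.finite(median_irp))) {
    abort_panometry("median_irp must be finite.", "panometry_invalid_argument")
  }
  if (!all(position %in% c("supine", "upright"))) {
    abort_panometry("position must be \"supine\" or \"upright\".",
                    "panometry_invalid_argument")
  }
  limit <- ifelse(position == "supine", 15, 12)
  median_irp > limit
}

#' Classify a timed barium esophagram
#'
#' Applies the published TBE rules to per-patient columns `tbe_present`
#' (logical), `tbe_h1`/`tbe_h5` (barium column heights at 1 and 5 min, cm)
#' and `tbe_tablet` (`"not_administered"`, `"passed"`, `"impacted"`):
#'
#' * **missing** — no TBE performed;
#' * **abnormal** — column height above 5 cm at 5 min, or above 5 cm at
#'   1 min together with tablet impaction;
#' * **inconclusive** — height above 5 cm at 1 min but at or below 5 cm at
#'   5 min with no tablet administered or tablet passage; or height at or
#'   below 5 cm at 1 min with tablet impaction;
#' * **normal** — otherwise.
#'
#' The printed inconclusive clause "with no tablet administration or tablet
#' passage" is grammatically ambiguous; the default parse treats it as
#' (tablet not administered OR tablet passed).  Set
#' `tbe_clause = "passage_only"` for the alternative parse (tablet passage
#' required).  A 2-min image, when recorded, is carried but unused — the
#' published criteria only consult the 1- and 5-min heights.
#'
#' @param data Data frame with the TBE columns above.
#' @param tbe_clause Parse mode for the inconclusive clause.
#' @return The input as a tibble with a `tbe_class` factor column
#'   (`abnormal`, `normal`, `inconclusive`, `missing`).
#' @export
#' @examples
#' classify_tbe(tibble::tibble(tbe_present = TRUE, tbe_h1 = 7, tbe_h5 = 4,
#'                             tbe_tablet = "not_administered"))$tbe_class
classify_tbe <- function(data, tbe_clause = c("either", "passage_only")) {
  tbe_clause <- match.arg(tbe_clause)
  check_columns(data, c("tbe_present", "tbe_h1", "tbe_h5", "tbe_tablet"),
                "classify_tbe")
  present <- data$tbe_present
  if (any(data$tbe_h1[present] < 0, na.rm = TRUE) ||
      any(data$tbe_h5[present] < 0, na.rm = TRUE)) {
    abort_panometry("barium column heights must be non-negative.",
                    "panometry_invalid_argument")
  }
  bad_tab <- present & !(data$tbe_tablet %in% c("not_administered", "passed", "impacted"))
  if (any(bad_tab, na.rm = TRUE)) {
    abort_panometry("tbe_tablet must be not_administered, passed or impacted.",
                    "panometry_invalid_argument")
  }
  h1 <- data$tbe_h1
  h5 <- data$tbe_h5
  tablet <- data$tbe_tablet
  no_tab <- if (tbe_clause == "either") {
    tablet %in% c("not_administered", "passed")
  } else {
    tablet == "passed"
  }
  dplyr::mutate(
    tibble::as_tibble(data),
    tbe_class = factor(dplyr::case_when(
      !present ~ "missing",
      h5 > 5 ~ "abnormal",
      h1 > 5 & tablet == "impacted" ~ "abnormal",
      h1 > 5 & h5 <= 5 & no_tab ~ "inconclusive",
      h1 <= 5 & tablet == "impacted" ~ "inconclusive",
      TRUE ~ "normal"
    ), levels = c("abnormal", "normal", "inconclusive", "missing"))
  )
}

#' Adjudicate CCv4.0 diagnoses against TBE
#'
#' Resolves each patient's CCv4.0 label and timed barium esophagram into an
#' EGJ-outflow status and a conclusiveness flag:
#'
#' * achalasia (any subtype) is a conclusive disorder of EGJ outflow
#'   regardless of TBE;
#' * labels in `pending_labels` (default EGJOO; optionally borderline
#'   absent contractility) are inconclusive at the HRM level and resolved by
#'   TBE — abnormal TBE makes a conclusive outflow disorder, normal TBE
#'   conclusive normal outflow, missing or inconclusive TBE leaves the
#'   diagnosis inconclusive (excluded from primary analyses);
#' * an explicit `inconclusive_other` label stays inconclusive;
#' * every other label is conclusive with normal EGJ outflow.
#'
#' @param data Data frame with a `ccv4_label` column (see [ccv4_levels()])
#'   and the TBE columns of [classify_tbe()] (or an existing `tbe_class`
#'   column).
#' @param pending_labels Labels that are inconclusive at HRM pending TBE.
#' @param tbe_clause Passed to [classify_tbe()] when `tbe_class` is absent.
#' @return The input as a tibble with appended columns `tbe_class` (if
#'   computed), `outflow_status` (factor: `conclusive_outflow_disorder`,
#'   `normal_outflow`, `inconclusive`), `conclusive` (logical) and
#'   `rationale` (which rule fired).
#' @export
adjudicate_diagnosis <- function(data, pending_labels = "EGJOO",
                                 tbe_clause = c("either", "passage_only")) {
  check_columns(data, "ccv4_label", "adjudicate_diagnosis")
  bad <- setdiff(unique(as.character(data$ccv4_label)), ccv4_levels())
  if (length(bad) > 0) {
    abort_panometry(paste0("unknown CCv4.0 label(s): ", paste(bad, collapse = ", ")),
                    "panometry_invalid_argument")
  }
  out <- tibble::as_tibble(data)
  if (!"tbe_class" %in% names(out)) {
    out <- classify_tbe(out, tbe_clause = tbe_clause)
  }
  label <- as.character(out$ccv4_label)
  tbe <- as.character(out$tbe_class)
  achalasia <- label %in% c("achalasia_I", "achalasia_II", "achalasia_III")
  pending <- label %in% pending_labels

  status <- dplyr::case_when(
    achalasia ~ "conclusive_outflow_disorder",
    label == "inconclusive_other" ~ "inconclusive",
    pending & tbe == "abnormal" ~ "conclusive_outflow_disorder",
    pending & tbe == "normal" ~ "normal_outflow",
    pending ~ "inconclusive",
    TRUE ~ "normal_outflow"
  )
  rationale <- dplyr::case_when(
    achalasia ~ "achalasia: conclusive outflow disorder irrespective of TBE",
    label == "inconclusive_other" ~ "inconclusive HRM study",
    pending & tbe == "abnormal" ~ "inconclusive HRM resolved by abnormal TBE: conclusive outflow disorder",
    pending & tbe == "normal" ~ "inconclusive HRM resolved by normal TBE: normal EGJ outflow",
    pending ~ "inconclusive HRM with missing/inconclusive TBE: excluded from primary analysis",
    TRUE ~ "conclusive non-obstructive HRM diagnosis: normal EGJ outflow"
  )
  out$outflow_status <- factor(status, levels = outflow_levels())
  out$conclusive <- status != "inconclusive"
  out$rationale <- rationale
  out
}

#' Is an adjudicated diagnosis a disorder of EGJ outflow?
#'
#' A disorder of EGJ outflow is achalasia (any subtype) or conclusive EGJ
#' outflow obstruction (an outflow-pending label resolved to a conclusive
#' outflow disorder).  Inconclusive records are rejected: the question is
#' only defined for the conclusive cohort.
#'
#' @param data Adjudicated data frame (see [adjudicate_diagnosis()]).
#' @return Logical vector, one value per row.
#' @export
is_outflow_disorder <- function(data) {
  check_columns(data, c("ccv4_label", "outflow_status", "conclusive"),
                "is_outflow_disorder")
  if (any(!data$conclusive)) {
    abort_panometry("is_outflow_disorder() is undefined for inconclusive diagnoses.",
                    "panometry_inconclusive_input")
  }
  data$outflow_status == "conclusive_outflow_disorder"
}
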