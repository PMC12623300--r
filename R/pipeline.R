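#' Concordance report for an adjudicated cohort
#'
#' Runs the full concordance analysis: adjudication (when not already
#' present), the conclusive/excluded partition, the HRM-by-FLIP
#' cross-tabulation, every headline within-class proportion, and the
#' predictive values of the normal and non-spastic-obstruction FLIP classes
#' for disorders of EGJ outflow.
#'
#' @param cohort Data frame with `flip_v2`, `ccv4_label` and (if not yet
#'   adjudicated) the TBE columns.
#' @param percent_digits Digits kept on the percent scale.
#' @return A list of class `concordance_report`: `n_total`,
#'   `n_conclusive`, `n_excluded`, `crosstab` (HRM rows by FLIP columns,
#'   conclusive cohort), `headline` (tibble of named proportions with
#'   counts), `predictive` (PPV/NPV tibble).
#' @export
#' @examples
#' rep <- concordance_report(cohort_fixture())
#' rep$headline
concordance_report <- function(cohort, percent_digits = 0) {
  check_columns(cohort, c("flip_v2", "ccv4_label"), "concordance_report")
  if (!"conclusive" %in% names(cohort)) {
    cohort <- adjudicate_diagnosis(cohort)
  }
  parts <- primary_filter(cohort)
  conclusive <- parts$conclusive

  ct <- build_crosstab(conclusive, "ccv4_label", "flip_v2")
  ct_t <- build_crosstab(conclusive, "flip_v2", "ccv4_label")

  within <- function(quantity, rows, col, table = ct) {
    dplyr::mutate(
      proportion_within(table, rows, col, percent_digits),
      quantity = quantity, .before = 1
    )
  }
  headline <- dplyr::bind_rows(
    within("normal_or_iem_within_normal_flip", c("normal", "IEM"), "NORMAL"),
    within("normal_hrm_within_normal_flip", "normal", "NORMAL"),
    within("absent_or_iem_within_hypocontractility",
           c("absent_contractility", "IEM"), "HYPOCONTRACTILITY"),
    within("type_1_2_achalasia_within_non_spastic_obstruction",
           c("achalasia_I", "achalasia_II"), "NON_SPASTIC_OBSTRUCTION"),
    within("type_3_achalasia_within_non_spastic_obstruction",
           "achalasia_III", "NON_SPASTIC_OBSTRUCTION"),
    within("hyper_or_des_within_possible_spasm",
           c("hypercontractile", "DES"), "POSSIBLE_SPASM"),
    within("normal_hrm_within_possible_spasm", "normal", "POSSIBLE_SPASM"),
    within("type_1_2_achalasia_within_possible_obstruction",
           c("achalasia_I", "achalasia_II"), "POSSIBLE_OBSTRUCTION"),
    within("type_3_achalasia_to_spastic_obstruction",
           "SPASTIC_OBSTRUCTION", "achalasia_III", table = ct_t)
  )
  predictive <- predictive_values(
    conclusive,
    positive = "NON_SPASTIC_OBSTRUCTION",
    negative = "NORMAL",
    percent_digits = percent_digits
  )
  structure(
    list(n_total = nrow(cohort),
         n_conclusive = nrow(conclusive),
         n_excluded = nrow(parts$excluded),
         crosstab = ct, headline = headline, predictive = predictive),
    class = "concordance_report"
  )
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("<concordance_report> %d patients: %d conclusive, %d excluded\n",
              x$n_total, x$n_conclusive, x$n_excluded))
  print(x$headline)
  print(x$predictive[, c("measure", "numerator", "denominator", "percent")])
  invisible(x)
}

#' Run the full analysis pipeline
#'
#' Orchestrates every stage on one configuration: load (or take) a cohort,
#' adjudicate, filter, and compute the concordance report; optionally also
#' draw a synthetic cohort calibrated to the packaged contingency counts,
#' classify it under both scheme versions from its sampled metrics, and
#' build the v1.0-to-v2.0 reclassification table.  Each stage logs its
#' input/output counts (suppress with `quiet = TRUE`).  Identical
#' configuration and inputs give identical output.
#'
#' @param config A [pipeline_config()].
#' @param cohort A cohort data frame, a path readable by [read_cohort()],
#'   or `NULL` to use the packaged fixture cohort.
#' @param synthetic_n Size of the optional synthetic cohort (0 disables).
#' @param quiet Suppress stage logging.
#' @return A list of class `panometry_report` with elements `config`,
#'   `concordance` (a [concordance_report()]), and, when `synthetic_n > 0`,
#'   `synthetic` (list with the sampled cohort, classification columns and
#'   the reclassification table).
#' @export
run_pipeline <- function(config = pipeline_config(), cohort = NULL,
                         synthetic_n = 0, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  log_stage <- function(...) if (!quiet) message(sprintf(...))

  if (is.null(cohort)) {
    cohort <- cohort_fixture()
    log_stage("load: packaged fixture cohort, %d records", nrow(cohort))
  } else if (is.character(cohort)) {
    cohort <- read_cohort(cohort)
    log_stage("load: %d records read", nrow(cohort))
  }
  adjudicated <- adjudicate_diagnosis(cohort, tbe_clause = config$tbe_clause)
  log_stage("adjudicate: %d records in, %d conclusive",
            nrow(adjudicated), sum(adjudicated$conclusive))
  concordance <- concordance_report(adjudicated,
                                    percent_digits = config$percent_digits)
  log_stage("concord: %d conclusive analysed, %d excluded",
            concordance$n_conclusive, concordance$n_excluded)

  out <- list(config = config, concordance = concordance)
  if (synthetic_n > 0) {
    spec <- calibrate_joint_from_counts(cohort_counts())
    syn <- sample_cohort(spec, synthetic_n, seed = config$seed,
                         params = config$params)
    syn <- classify_flip(syn, scheme = "both", params = config$params)
    syn$flip_v1 <- syn$motility_v1
    reclass <- version_reclassification(
      dplyr::mutate(syn, flip_v2 = .data$motility_v2))
    log_stage("simulate: %d synthetic patients drawn and classified", synthetic_n)
    out$synthetic <- list(cohort = syn, reclassification = reclass)
  }
  structure(out, class = "panometry_report")
}

#' Write a pipeline report as JSON
#'
#' Serialises the report (headline proportions, predictive values, counts,
#' and the configuration that produced them) to a JSON file for audit.
#'
#' @param report A [run_pipeline()] result.
#' @param path Output file.
#' @return `report`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "panometry_report"))
  x <- list(
    config = list(seed = report$config$seed,
                  tbe_clause = report$config$tbe_clause,
                  percent_digits = report$config$percent_digits,
                  params = unclass(report$config$params)),
    n_total = report$concordance$n_total,
    n_conclusive = report$concordance$n_conclusive,
    n_excluded = report$concordance$n_excluded,
    headline = report$concordance$headline,
    predictive = report$concordance$predictive,
    crosstab = tidy(report$concordance$crosstab)
  )
  jsonlite::write_json(x, path, digits = NA, auto_unbox = TRUE)
  invisible(report)
}
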