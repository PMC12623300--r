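#' Split an adjudicated cohort into conclusive and excluded subsets
#'
#' The primary analysis uses only patients with a conclusive HRM/CCv4.0
#' diagnosis; inconclusive diagnoses are set aside (secondary description).
#' The partition always conserves counts.
#'
#' @param cohort Adjudicated data frame with a logical `conclusive` column
#'   (see [adjudicate_diagnosis()]).
#' @return Named list of two tibbles, `conclusive` and `excluded`.
#' @export
#' @examples
#' cohort <- adjudicate_diagnosis(cohort_fixture())
#' vapply(primary_filter(cohort), nrow, integer(1)) # 704 and 101
primary_filter <- function(cohort) {
  check_columns(cohort, "conclusive", "primary_filter")
  if (any(is.na(cohort$conclusive))) {
    abort_panometry("primary_filter() needs adjudicated records (no NA conclusiveness).",
                    "panometry_invalid_argument")
  }
  cohort <- tibble::as_tibble(cohort)
  list(conclusive = cohort[cohort$conclusive, ],
       excluded = cohort[!cohort$conclusive, ])
}

#' Cross-tabulate two cohort variables
#'
#' Exact integer counts with deterministic label ordering: factor levels
#' when the column is a factor, otherwise the canonical package order for
#' known category sets, otherwise sorted.  Levels absent from the data keep
#' zero rows/columns, so margins are stable across subsets.
#'
#' @param cohort Data frame.
#' @param row_var,col_var Column names (strings).
#' @return A `contingency_table`: integer matrix with named dimensions,
#'   carrying the variable names as attributes.  `tidy()` gives long
#'   counts; `glance()` the grand total and margins check.
#' @export
build_crosstab <- function(cohort, row_var, col_var) {
  check_columns(cohort, c(row_var, col_var), "build_crosstab")
  f <- function(x) {
    if (is.factor(x)) return(x)
    lv <- canonical_levels(x)
    factor(x, levels = lv)
  }
  r <- f(cohort[[row_var]])
  c_ <- f(cohort[[col_var]])
  counts <- table(r, c_, dnn = c(row_var, col_var))
  structure(unclass(counts), class = "contingency_table",
            row_var = row_var, col_var = col_var)
}

# internal: canonical ordering for known label sets, else sorted unique
canonical_levels <- function(x) {
  u <- unique(as.character(x))
  for (set in list(motility_levels_v2(), motility_levels_v1(), ccv4_levels(),
                   cr_levels_v2(), cr_levels_v1(), egj_opening_levels(),
                   outflow_levels())) {
    if (all(u %in% set)) return(set)
  }
  sort(u)
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("<contingency_table> %s x %s, n = %d\n",
              attr(x, "row_var"), attr(x, "col_var"), sum(x)))
  print(unclass(x))
  invisible(x)
}

#' @export
tidy.contingency_table <- function(x, ...) {
  out <- tibble::as_tibble(as.data.frame(as.table(unclass(x)), responseName = "n",
                                         stringsAsFactors = FALSE))
  names(out)[1:2] <- c(attr(x, "row_var"), attr(x, "col_var"))
  out$n <- as.integer(out$n)
  out
}

#' @export
glance.contingency_table <- function(x, ...) {
  tibble::tibble(
    n = sum(x), n_rows = nrow(x), n_cols = ncol(x),
    margins_consistent = sum(rowSums(x)) == sum(x) && sum(colSums(x)) == sum(x)
  )
}

#' Proportion of a row subset within one column
#'
#' Reports `sum(counts[rows, col]) / sum(counts[, col])` with the raw
#' counts, the exact fraction, and the integer percent rounded half away
#' from zero (the convention of published reports, so 92.7 prints as 93 and
#' 98.5 as 99).  An empty column yields an undefined marker (`NA`), not an
#' error.
#'
#' @param table A [build_crosstab()] result.
#' @param rows Character vector of row labels (the subset of interest).
#' @param col Single column label (the denominator group).
#' @param percent_digits Digits kept on the percent scale.
#' @return One-row tibble: `numerator`, `denominator`, `proportion`,
#'   `percent`.
#' @export
proportion_within <- function(table, rows, col, percent_digits = 0) {
  stopifnot(inherits(table, "contingency_table"))
  bad <- setdiff(rows, rownames(table))
  if (length(bad) > 0 || !(col %in% colnames(table))) {
    abort_panometry("unknown row or column label.", "panometry_invalid_argument")
  }
  den <- sum(table[, col])
  num <- sum(table[rows, col])
  tibble::tibble(
    numerator = as.integer(num), denominator = as.integer(den),
    proportion = if (den > 0) num / den else NA_real_,
    percent = if (den > 0) round_half_away(100 * num / den, percent_digits) else NA_real_
  )
}

#' Predictive values of FLIP classes for a condition
#'
#' Computes, over a conclusive cohort, the positive and negative predictive
#' value of FLIP classification sets for a per-patient condition (by
#' default a disorder of EGJ outflow, via [is_outflow_disorder()]):
#' PPV = P(condition | class in `positive`), NPV = P(no condition | class in
#' `negative`).  Counts are reported alongside the rounded percent.
#'
#' @param cohort Conclusive adjudicated data frame.
#' @param positive,negative Character vectors of FLIP classes forming the
#'   test-positive and test-negative sets.
#' @param class_col Column holding the FLIP class (default `"flip_v2"`).
#' @param condition Logical vector (one per row) or `NULL` to use
#'   [is_outflow_disorder()].
#' @param percent_digits Digits kept on the percent scale.
#' @return Tibble with one row per measure (`ppv`, `npv`): `measure`,
#'   `numerator`, `denominator`, `estimate`, `percent`, `definition`.
#' @export
#' @examples
#' cohort <- primary_filter(adjudicate_diagnosis(cohort_fixture()))$conclusive
#' predictive_values(cohort,
#'                   positive = "NON_SPASTIC_OBSTRUCTION",
#'                   negative = "NORMAL")
predictive_values <- function(cohort, positive, negative,
                              class_col = "flip_v2", condition = NULL,
                              percent_digits = 0) {
  check_columns(cohort, class_col, "predictive_values")
  if (is.null(condition)) condition <- is_outflow_disorder(cohort)
  stopifnot(length(condition) == nrow(cohort))
  cls <- as.character(cohort[[class_col]])

  one <- function(measure, set, hit) {
    in_set <- cls %in% set
    den <- sum(in_set)
    num <- sum(in_set & hit)
    tibble::tibble(
      measure = measure,
      numerator = as.integer(num), denominator = as.integer(den),
      estimate = if (den > 0) num / den else NA_real_,
      percent = if (den > 0) round_half_away(100 * num / den, percent_digits) else NA_real_,
      definition = sprintf("P(%s | %s in {%s})",
                           if (measure == "ppv") "condition" else "no condition",
                           class_col, paste(set, collapse = ", "))
    )
  }
  dplyr::bind_rows(
    one("ppv", positive, condition),
    one("npv", negative, !condition)
  )
}

#' Reclassification table between scheme versions
#'
#' Cross-tabulates each patient's v1.0 class (rows) against their v2.0
#' class (columns); the long form additionally breaks every cell down by
#' the HRM/CCv4.0 label, mirroring the published version-comparison figure.
#' Row and column totals always equal the cohort size.
#'
#' @param cohort Data frame with `flip_v1` and `flip_v2` columns (and
#'   optionally `ccv4_label` for the per-cell breakdown).
#' @return List with `table` (a [build_crosstab()] matrix) and `breakdown`
#'   (long tibble `flip_v1`, `flip_v2`, `ccv4_label`, `n`; `NULL` when no
#'   label column is present).
#' @export
version_reclassification <- function(cohort) {
  check_columns(cohort, c("flip_v1", "flip_v2"), "version_reclassification")
  if (any(is.na(cohort$flip_v1))) {
    abort_panometry("version_reclassification() needs v1.0 labels for every record.",
                    "panometry_invalid_argument")
  }
  tab <- build_crosstab(cohort, "flip_v1", "flip_v2")
  breakdown <- NULL
  if ("ccv4_label" %in% names(cohort)) {
    breakdown <- dplyr::count(tibble::as_tibble(cohort),
                              .data$flip_v1, .data$flip_v2, .data$ccv4_label,
                              name = "n")
  }
  list(table = tab, breakdown = breakdown)
}

#' Between-group comparison tests
#'
#' Standard two-tailed tests comparing a per-patient variable across
#' groups, as used for cohort characteristics: the chi-squared test
#' (uncorrected) for categorical variables; ANOVA or t test for continuous
#' variables under the parametric choice; Kruskal-Wallis or Mann-Whitney U
#' otherwise.  No multiplicity correction is applied.
#'
#' @param cohort Data frame.
#' @param variable Column being compared (string).
#' @param group Grouping column (string).
#' @param parametric For continuous variables: parametric tests (`TRUE`) or
#'   rank tests (`FALSE`).
#' @return One-row tibble: `method`, `statistic`, `df`, `p_value`,
#'   `n_groups`.  Degenerate inputs (a single group, or a constant
#'   variable) return `NA` statistics rather than erroring.
#' @export
#' @examples
#' d <- data.frame(g = rep(c("a", "b"), each = 30),
#'                 x = rep(c("u", "v"), times = c(30, 30))[c(1:10, 31:50, 11:30, 51:60)])
#' group_comparison_tests(d, "x", "g")
group_comparison_tests <- function(cohort, variable, group, parametric = TRUE) {
  check_columns(cohort, c(variable, group), "group_comparison_tests")
  x <- cohort[[variable]]
  g <- factor(cohort[[group]])
  k <- nlevels(droplevels(g))
  na_row <- function(method) {
    tibble::tibble(method = method, statistic = NA_real_, df = NA_real_,
                   p_value = NA_real_, n_groups = k)
  }
  if (k < 2) return(na_row("degenerate (single group)"))

  if (is.numeric(x)) {
    if (stats::var(x, na.rm = TRUE) == 0) {
      # identical groups: no evidence against equality
      return(tibble::tibble(method = "degenerate (constant variable)",
                            statistic = 0, df = NA_real_, p_value = 1,
                            n_groups = k))
    }
    if (parametric && k == 2) {
      fit <- stats::t.test(x ~ g)
      return(tibble::tibble(method = "t test", statistic = unname(fit$statistic),
                            df = unname(fit$parameter), p_value = fit$p.value,
                            n_groups = k))
    }
    if (parametric) {
      fit <- stats::aov(x ~ g)
      s <- summary(fit)[[1]]
      return(tibble::tibble(method = "ANOVA", statistic = s[["F value"]][1],
                            df = s[["Df"]][1], p_value = s[["Pr(>F)"]][1],
                            n_groups = k))
    }
    if (k == 2) {
      fit <- stats::wilcox.test(x ~ g)
      return(tibble::tibble(method = "Mann-Whitney U",
                            statistic = unname(fit$statistic), df = NA_real_,
                            p_value = fit$p.value, n_groups = k))
    }
    fit <- stats::kruskal.test(x ~ g)
    return(tibble::tibble(method = "Kruskal-Wallis",
                          statistic = unname(fit$statistic),
                          df = unname(fit$parameter), p_value = fit$p.value,
                          n_groups = k))
  }

  tab <- table(x, g)
  if (nrow(tab) < 2) return(na_row("degenerate (constant variable)"))
  fit <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  tibble::tibble(method = "chi-squared", statistic = unname(fit$statistic),
                 df = unname(fit$parameter), p_value = fit$p.value,
                 n_groups = k)
}
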