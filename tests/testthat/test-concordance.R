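adjudicated_fixture <- function() adjudicate_diagnosis(cohort_fixture())

test_that("primary filter partitions and conserves counts", {
  parts <- primary_filter(adjudicated_fixture())
  expect_equal(nrow(parts$conclusive), 704)
  expect_equal(nrow(parts$excluded), 101)
  expect_equal(nrow(parts$conclusive) + nrow(parts$excluded), 805)

  all_conclusive <- adjudicate_diagnosis(
    tibble::tibble(ccv4_label = c("normal", "IEM"),
                   tbe_present = FALSE, tbe_h1 = NA_real_, tbe_h5 = NA_real_,
                   tbe_tablet = NA_character_))
  parts <- primary_filter(all_conclusive)
  expect_equal(nrow(parts$excluded), 0)

  empty <- primary_filter(all_conclusive[0, ])
  expect_equal(nrow(empty$conclusive), 0)
  expect_equal(nrow(empty$excluded), 0)

  expect_error(primary_filter(tibble::tibble(x = 1)),
               class = "panometry_missing_column")
})

test_that("cross-tabulation gives exact counts with stable ordering", {
  conclusive <- primary_filter(adjudicated_fixture())$conclusive
  ct <- build_crosstab(conclusive, "ccv4_label", "flip_v2")
  expect_equal(ct["achalasia_II", "NON_SPASTIC_OBSTRUCTION"], 76)
  expect_equal(ct["normal", "NORMAL"], 111)
  expect_equal(sum(ct), 704)
  expect_equal(rownames(ct), ccv4_levels())
  expect_equal(colnames(ct), motility_levels_v2())

  single <- build_crosstab(tibble::tibble(a = "x", b = "y"), "a", "b")
  expect_equal(sum(single), 1)
  expect_error(build_crosstab(conclusive, "ccv4_label", "no_such"),
               class = "panometry_missing_column")
})

test_that("crosstab margins equal independent per-variable tallies", {
  conclusive <- primary_filter(adjudicated_fixture())$conclusive
  ct <- build_crosstab(conclusive, "ccv4_label", "flip_v2")
  row_tally <- table(factor(conclusive$ccv4_label, levels = ccv4_levels()))
  col_tally <- table(factor(conclusive$flip_v2, levels = motility_levels_v2()))
  expect_equal(unname(rowSums(ct)), as.vector(row_tally))
  expect_equal(unname(colSums(ct)), as.vector(col_tally))
  g <- glance(ct)
  expect_true(g$margins_consistent)
  expect_equal(g$n, 704)
})

test_that("within-column proportions use published integer rounding", {
  conclusive <- primary_filter(adjudicated_fixture())$conclusive
  ct <- build_crosstab(conclusive, "ccv4_label", "flip_v2")

  p <- proportion_within(ct, "normal", "NORMAL")
  expect_equal(p$numerator, 111)
  expect_equal(p$denominator, 137)
  expect_equal(p$percent, 81)

  p <- proportion_within(ct, c("absent_contractility", "IEM"), "HYPOCONTRACTILITY")
  expect_equal(c(p$numerator, p$denominator, p$percent), c(56, 78, 72))

  # a column against all rows is always 100%
  p <- proportion_within(ct, ccv4_levels(), "POSSIBLE_SPASM")
  expect_equal(p$percent, 100)

  # empty denominator yields an undefined marker, not an error: no patient
  # was classified obstruction-with-normal-contractility in this cohort
  p <- proportion_within(ct, "normal", "OBSTRUCTION_NORMAL_CR")
  expect_equal(p$denominator, 0)
  expect_true(is.na(p$percent))
  expect_true(is.na(p$proportion))
})

test_that("rounding is half away from zero, as printed reports use", {
  expect_equal(round_half_away(c(92.7, 98.5, 90.8, 7.84)), c(93, 99, 91, 8))
  expect_equal(round_half_away(-2.5), -3)
  expect_equal(round_half_away(2.345, 2), 2.35)
})

test_that("predictive values reproduce the published NPV and PPV", {
  conclusive <- primary_filter(adjudicated_fixture())$conclusive
  pv <- predictive_values(conclusive, positive = "NON_SPASTIC_OBSTRUCTION",
                          negative = "NORMAL")
  npv <- pv[pv$measure == "npv", ]
  expect_equal(c(npv$numerator, npv$denominator, npv$percent), c(135, 137, 99))
  ppv <- pv[pv$measure == "ppv", ]
  expect_equal(c(ppv$numerator, ppv$denominator, ppv$percent), c(148, 163, 91))

  # degenerate cohort in which the condition never occurs
  benign <- conclusive[conclusive$ccv4_label %in% c("normal", "IEM"), ]
  pv <- predictive_values(benign, positive = "NON_SPASTIC_OBSTRUCTION",
                          negative = "NORMAL")
  expect_equal(pv$estimate[pv$measure == "npv"], 1)
})

test_that("version reclassification conserves totals and respects reachability", {
  spec <- calibrate_joint_from_counts(cohort_counts())
  cohort <- sample_cohort(spec, 2000, seed = 31, demographics = FALSE)
  both <- classify_flip(cohort, scheme = "both")
  both$flip_v1 <- both$motility_v1
  both$flip_v2 <- both$motility_v2

  out <- version_reclassification(both)
  expect_equal(sum(out$table), 2000)
  expect_equal(sum(out$breakdown$n), 2000)

  # classes reachable from each v1.0 class under the shared criteria
  reachable <- list(
    NORMAL = "NORMAL",
    WEAK = c("HYPOCONTRACTILITY", "POSSIBLE_SPASM"),
    OBSTRUCTION_WEAK_CR = c("NON_SPASTIC_OBSTRUCTION", "SPASTIC_OBSTRUCTION"),
    SPASTIC_REACTIVE = c("POSSIBLE_SPASM", "SPASTIC_OBSTRUCTION"),
    OBSTRUCTION_NORMAL_CR = "OBSTRUCTION_NORMAL_CR",
    BORDERLINE_OTHER = c("POSSIBLE_OBSTRUCTION", "POSSIBLE_SPASM")
  )
  long <- tidy(out$table)
  long <- long[long$n > 0, ]
  for (i in seq_len(nrow(long))) {
    expect_true(long$flip_v2[i] %in% reachable[[long$flip_v1[i]]],
                info = paste(long$flip_v1[i], "->", long$flip_v2[i]))
  }

  single <- version_reclassification(both[1, ])
  expect_equal(sum(single$table), 1)
  expect_error(version_reclassification(dplyr::mutate(both, flip_v1 = NA)),
               class = "panometry_invalid_argument")
})

test_that("chi-squared on the worked 2x2 table is 6.667 (uncorrected)", {
  d <- tibble::tibble(
    group = rep(c("g1", "g2"), each = 30),
    outcome = c(rep("a", 10), rep("b", 20), rep("a", 20), rep("b", 10))
  )
  res <- group_comparison_tests(d, "outcome", "group")
  expect_equal(res$method, "chi-squared")
  expect_equal(res$statistic, 20 / 3, tolerance = 1e-12)
  expect_equal(res$df, 1)
})

test_that("identical groups give p of about 1; degenerate inputs do not crash", {
  d <- tibble::tibble(g = rep(c("a", "b"), each = 5), x = rep(c(1, 2, 3, 4, 5), 2))
  res <- group_comparison_tests(d, "x", "g")
  expect_equal(res$method, "t test")
  expect_equal(res$p_value, 1, tolerance = 1e-9)

  one_group <- tibble::tibble(g = "a", x = 1:3)
  expect_true(is.na(group_comparison_tests(one_group, "x", "g")$p_value))
  const <- tibble::tibble(g = rep(c("a", "b"), 5), x = 1)
  expect_equal(group_comparison_tests(const, "x", "g")$p_value, 1)
})

test_that("rank tests and ANOVA are dispatched by design", {
  d <- tibble::tibble(g = rep(c("a", "b", "c"), each = 10),
                      x = c(rnorm(10), rnorm(10, 1), rnorm(10, 2)))
  expect_equal(group_comparison_tests(d, "x", "g")$method, "ANOVA")
  expect_equal(group_comparison_tests(d, "x", "g", parametric = FALSE)$method,
               "Kruskal-Wallis")
  d2 <- d[d$g != "c", ]
  expect_equal(group_comparison_tests(d2, "x", "g", parametric = FALSE)$method,
               "Mann-Whitney U")
})

test_that("asymptotic chi-squared p-value agrees with a permutation null", {
  d <- tibble::tibble(
    group = rep(c("g1", "g2"), each = 950),
    outcome = c(rep("a", 500), rep("b", 450), rep("a", 450), rep("b", 500))
  )
  asym <- group_comparison_tests(d, "outcome", "group")$p_value
  tab <- table(d$outcome, d$group)
  mc <- withr::with_seed(17, stats::chisq.test(tab, correct = FALSE,
                                               simulate.p.value = TRUE,
                                               B = 1e5)$p.value)
  se <- sqrt(mc * (1 - mc) / 1e5)
  # asymptotic approximation error at n = 1900 is well under this band
  expect_lt(abs(asym - mc), 4 * se + 0.005)
})
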