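test_that("IRP thresholds are strict and position-specific", {
  expect_false(check_irp_abnormal(15.0, "supine"))
  expect_true(check_irp_abnormal(15.1, "supine"))
  expect_false(check_irp_abnormal(12.0, "upright"))
  expect_true(check_irp_abnormal(12.5, "upright"))
  # vectorised with recycling
  expect_equal(check_irp_abnormal(c(14, 16), "supine"), c(FALSE, TRUE))
  expect_error(check_irp_abnormal(10, "prone"), class = "panometry_invalid_argument")
  expect_error(check_irp_abnormal(NaN, "supine"), class = "panometry_invalid_argument")
})

tbe_case <- function(h1 = 0, h5 = 0, tablet = "passed", present = TRUE, ...) {
  tibble::tibble(tbe_present = present, tbe_h1 = h1, tbe_h5 = h5,
                 tbe_tablet = tablet)
}

test_that("TBE rules classify the worked examples as published", {
  tbe <- function(...) as.character(classify_tbe(tbe_case(...))$tbe_class)
  expect_equal(tbe(h1 = 8, h5 = 6), "abnormal")                      # 5-min column > 5 cm
  expect_equal(tbe(h1 = 7, h5 = 4, tablet = "impacted"), "abnormal") # 1-min > 5 cm + impaction
  expect_equal(tbe(h1 = 7, h5 = 4, tablet = "not_administered"), "inconclusive")
  expect_equal(tbe(h1 = 7, h5 = 4, tablet = "passed"), "inconclusive")
  expect_equal(tbe(h1 = 3, h5 = 1, tablet = "impacted"), "inconclusive")
  expect_equal(tbe(h1 = 3, h5 = 1, tablet = "passed"), "normal")
  expect_equal(tbe(present = FALSE), "missing")
  expect_error(classify_tbe(tbe_case(h1 = -1)), class = "panometry_invalid_argument")
})

test_that("boundary heights: exactly 5 cm does not trigger the > 5 rules", {
  tbe <- function(...) as.character(classify_tbe(tbe_case(...))$tbe_class)
  expect_equal(tbe(h1 = 5, h5 = 5), "normal")
  expect_equal(tbe(h1 = 5.1, h5 = 5, tablet = "passed"), "inconclusive")
  expect_equal(tbe(h1 = 5, h5 = 5.1), "abnormal")
})

test_that("the alternative parse of the inconclusive clause is selectable", {
  x <- tbe_case(h1 = 7, h5 = 4, tablet = "not_administered")
  expect_equal(as.character(classify_tbe(x, tbe_clause = "either")$tbe_class),
               "inconclusive")
  expect_equal(as.character(classify_tbe(x, tbe_clause = "passage_only")$tbe_class),
               "normal")
})

test_that("TBE classification is total over an exhaustive grid", {
  grid <- tidyr::expand_grid(
    tbe_h1 = 0:20, tbe_h5 = 0:20,
    tbe_tablet = c("not_administered", "passed", "impacted"),
    tbe_present = TRUE
  )
  grid <- dplyr::bind_rows(
    grid,
    tibble::tibble(tbe_h1 = NA_real_, tbe_h5 = NA_real_,
                   tbe_tablet = NA_character_, tbe_present = FALSE)
  )
  out <- classify_tbe(grid)
  expect_false(any(is.na(out$tbe_class)))
  expect_true(all(out$tbe_class %in% c("abnormal", "normal", "inconclusive", "missing")))
})

test_that("adjudication resolves labels against TBE as published", {
  adj <- function(label, ...) {
    adjudicate_diagnosis(dplyr::mutate(tbe_case(...), ccv4_label = label))
  }
  x <- adj("EGJOO", h1 = 8, h5 = 7)                    # abnormal TBE
  expect_equal(as.character(x$outflow_status), "conclusive_outflow_disorder")
  expect_true(x$conclusive)

  x <- adj("EGJOO", present = FALSE)                   # missing TBE
  expect_equal(as.character(x$outflow_status), "inconclusive")
  expect_false(x$conclusive)

  x <- adj("EGJOO", h1 = 2, h5 = 1)                    # normal TBE
  expect_equal(as.character(x$outflow_status), "normal_outflow")
  expect_true(x$conclusive)

  x <- adj("achalasia_II", present = FALSE)            # achalasia needs no TBE
  expect_equal(as.character(x$outflow_status), "conclusive_outflow_disorder")
  expect_true(x$conclusive)

  for (tbe_args in list(list(h1 = 8, h5 = 7), list(present = FALSE))) {
    x <- do.call(adj, c(list("normal"), tbe_args))
    expect_equal(as.character(x$outflow_status), "normal_outflow")
    expect_true(x$conclusive)
  }
  expect_error(adj("not_a_label", present = FALSE),
               class = "panometry_invalid_argument")
})

test_that("borderline absent contractility can be marked TBE-pending", {
  x <- dplyr::mutate(tbe_case(present = FALSE), ccv4_label = "absent_contractility")
  default <- adjudicate_diagnosis(x)
  expect_true(default$conclusive) # conclusive label by default
  pending <- adjudicate_diagnosis(
    x, pending_labels = c("EGJOO", "absent_contractility"))
  expect_false(pending$conclusive) # resolved like EGJOO when declared pending
})

test_that("outflow-disorder predicate covers achalasia and conclusive EGJOO only", {
  cohort <- dplyr::bind_rows(
    dplyr::mutate(tbe_case(present = FALSE), ccv4_label = "achalasia_I"),
    dplyr::mutate(tbe_case(present = FALSE), ccv4_label = "IEM"),
    dplyr::mutate(tbe_case(h1 = 8, h5 = 7), ccv4_label = "EGJOO"),
    dplyr::mutate(tbe_case(h1 = 2, h5 = 1), ccv4_label = "EGJOO")
  )
  adj <- adjudicate_diagnosis(cohort)
  expect_equal(is_outflow_disorder(adj), c(TRUE, FALSE, TRUE, FALSE))

  inconclusive <- adjudicate_diagnosis(
    dplyr::mutate(tbe_case(present = FALSE), ccv4_label = "EGJOO"))
  expect_error(is_outflow_disorder(inconclusive),
               class = "panometry_inconclusive_input")
})

test_that("exclusion bookkeeping conserves the cohort", {
  adj <- adjudicate_diagnosis(cohort_fixture())
  expect_equal(sum(adj$conclusive) + sum(!adj$conclusive), nrow(adj))
  expect_equal(sum(!adj$conclusive), 101)
  expect_equal(sum(adj$conclusive), 704)
})
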