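test_that("v2.0 contractile-response rules and precedence", {
  cases <- list(
    list(m = make_metrics(), expect = "ABSENT"),
    list(m = make_metrics(any_contractility = TRUE, sustained_occluding = TRUE,
                          pressure_60 = 55), expect = "SPASTIC"),
    list(m = make_metrics(sustained_les = TRUE), expect = "SPASTIC"),
    list(m = make_metrics(any_contractility = TRUE, n_qualifying_antegrade = 1L,
                          pressure_60 = 30), expect = "DIMINISHED"),
    list(m = make_metrics(any_contractility = TRUE, n_qualifying_antegrade = 1L,
                          pressure_60 = 40.1), expect = "DISORDERED"),
    list(m = make_metrics(any_contractility = TRUE, n_qualifying_antegrade = 2L),
         expect = "NORMAL")
  )
  for (case in cases) {
    expect_equal(as.character(classify_cr_v2(case$m)$cr_v2), case$expect)
  }
})

test_that("boundary behaviour is fixed: 40 mmHg and 2 contractions", {
  at40 <- make_metrics(any_contractility = TRUE, pressure_60 = 40)
  expect_equal(as.character(classify_cr_v2(at40)$cr_v2), "DIMINISHED")
  just_above <- make_metrics(any_contractility = TRUE, pressure_60 = 40.000001)
  expect_equal(as.character(classify_cr_v2(just_above)$cr_v2), "DISORDERED")

  one <- make_metrics(any_contractility = TRUE, n_qualifying_antegrade = 1L)
  expect_false(as.character(classify_cr_v2(one)$cr_v2) == "NORMAL")
  two <- make_metrics(any_contractility = TRUE, n_qualifying_antegrade = 2L)
  expect_equal(as.character(classify_cr_v2(two)$cr_v2), "NORMAL")
})

test_that("v1.0 merges diminished and disordered; pressure is irrelevant", {
  lo <- make_metrics(any_contractility = TRUE, pressure_60 = 30)
  hi <- make_metrics(any_contractility = TRUE, pressure_60 = 80)
  expect_equal(as.character(classify_cr_v1(lo)$cr_v1), "IMPAIRED_DISORDERED")
  expect_equal(as.character(classify_cr_v1(hi)$cr_v1), "IMPAIRED_DISORDERED")
  expect_equal(as.character(classify_cr_v1(make_metrics())$cr_v1), "ABSENT")
  sp <- make_metrics(sustained_occluding = TRUE)
  expect_equal(as.character(classify_cr_v1(sp)$cr_v1), "SPASTIC_REACTIVE")
})

test_that("v1/v2 coherence: merging the v2 split reproduces v1 exactly", {
  n <- 10000
  draws <- withr::with_seed(99, tibble::tibble(
    egj_di_60 = stats::runif(n, 0.2, 8),
    max_egj_diameter = stats::runif(n, 4, 24),
    pressure_60 = stats::runif(n, 5, 90),
    n_qualifying_antegrade = sample(0:4, n, replace = TRUE),
    any_contractility = stats::runif(n) < 0.7,
    sustained_occluding = stats::runif(n) < 0.15,
    sustained_les = stats::runif(n) < 0.15,
    rac_pattern = FALSE
  ))
  # contractility implied by qualifying contractions
  draws$any_contractility <- draws$any_contractility | draws$n_qualifying_antegrade > 0
  v2 <- as.character(classify_cr_v2(draws)$cr_v2)
  v1 <- as.character(classify_cr_v1(draws)$cr_v1)
  merged <- dplyr::case_when(
    v2 %in% c("DIMINISHED", "DISORDERED") ~ "IMPAIRED_DISORDERED",
    v2 == "SPASTIC" ~ "SPASTIC_REACTIVE",
    TRUE ~ v2
  )
  expect_identical(merged, v1)
})

test_that("EGJ-opening thresholds and input validation", {
  egjo <- function(di, maxd) {
    as.character(classify_egj_opening(
      tibble::tibble(egj_di_60 = di, max_egj_diameter = maxd))$egj_opening)
  }
  expect_equal(egjo(3.5, 18), "NORMAL")
  expect_equal(egjo(1.0, 10), "REDUCED")
  expect_equal(egjo(2.5, 13), "INCONCLUSIVE")
  expect_equal(egjo(1.5, 14), "INCONCLUSIVE") # low DI but diameter >= 12
  expect_equal(egjo(2.0, 16), "NORMAL")       # boundary: thresholds inclusive
  expect_error(egjo(0, 14), class = "panometry_invalid_argument")
  expect_error(egjo(2, -1), class = "panometry_invalid_argument")
})

test_that("motility lookup follows the shipped v2.0 table", {
  lookup <- function(cr, egjo) {
    x <- tibble::tibble(cr_v2 = cr, egj_opening = egjo)
    as.character(classify_motility(x, decision_table("v2"))$motility_v2)
  }
  expect_equal(lookup("ABSENT", "REDUCED"), "NON_SPASTIC_OBSTRUCTION")
  expect_equal(lookup("DIMINISHED", "REDUCED"), "NON_SPASTIC_OBSTRUCTION")
  expect_equal(lookup("DISORDERED", "REDUCED"), "SPASTIC_OBSTRUCTION")
  expect_equal(lookup("SPASTIC", "REDUCED"), "SPASTIC_OBSTRUCTION")
  expect_equal(lookup("NORMAL", "NORMAL"), "NORMAL")
  expect_equal(lookup("NORMAL", "REDUCED"), "OBSTRUCTION_NORMAL_CR")
  expect_equal(lookup("DIMINISHED", "NORMAL"), "HYPOCONTRACTILITY")
  expect_equal(lookup("NORMAL", "INCONCLUSIVE"), "POSSIBLE_OBSTRUCTION")
})

test_that("an unmapped combination raises a table-incomplete error", {
  broken <- decision_table("v2")
  broken <- broken[-1, ]
  attr(broken, "version") <- "v2"
  x <- tibble::tibble(cr_v2 = "NORMAL", egj_opening = "NORMAL")
  expect_error(classify_motility(x, structure(broken, class = c("decision_table", "tbl_df", "tbl", "data.frame"))),
               class = "panometry_table_incomplete")
})

test_that("decision-table validation: totality, single-valuedness, provenance", {
  v2 <- decision_table("v2")
  expect_equal(nrow(v2), 15)
  chk <- validate_decision_table(v2)
  expect_true(chk$valid)
  expect_length(chk$violations, 0)

  v1 <- decision_table("v1")
  expect_equal(nrow(v1), 12)
  expect_true(validate_decision_table(v1)$valid)

  missing_cell <- v2[-3, ]
  attr(missing_cell, "version") <- "v2"
  chk <- validate_decision_table(missing_cell)
  expect_false(chk$valid)
  expect_true(any(grepl("missing cell", chk$violations)))

  dup <- dplyr::bind_rows(tibble::as_tibble(v2), tibble::as_tibble(v2)[1, ])
  chk <- validate_decision_table(dup, version = "v2")
  expect_false(chk$valid)
  expect_true(any(grepl("single-valued", chk$violations)))
})

test_that("cell overrides are applied and marked", {
  tab <- decision_table("v2", overrides = tibble::tibble(
    cr = "SPASTIC", egj_opening = "INCONCLUSIVE", motility = "SPASTIC_OBSTRUCTION"))
  hit <- tab[tab$cr == "SPASTIC" & tab$egj_opening == "INCONCLUSIVE", ]
  expect_equal(hit$motility, "SPASTIC_OBSTRUCTION")
  expect_equal(hit$provenance, "user-override")
  expect_true(validate_decision_table(tab)$valid)
})

test_that("decision tables round-trip through auditable text", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_decision_table(decision_table("v2"), path)
  back <- read_decision_table(path)
  expect_equal(attr(back, "version"), "v2")
  expect_equal(tibble::as_tibble(back), tibble::as_tibble(decision_table("v2")))
})

test_that("noise-free simulations map to the decision table for all 15 cells", {
  tab <- decision_table("v2")
  for (cr in names(sim_cr_to_pattern)) {
    for (eg in names(sim_egjo_to_class)) {
      study <- simulate_topography(topography_spec(cr, eg))
      out <- classify_flip(extract_metrics(study), scheme = "v2")
      expect_equal(as.character(out$cr_v2), unname(sim_cr_to_pattern[cr]),
                   info = paste(cr, eg))
      expect_equal(as.character(out$egj_opening), unname(sim_egjo_to_class[eg]),
                   info = paste(cr, eg))
      expected <- tab$motility[tab$cr == sim_cr_to_pattern[cr] &
                                 tab$egj_opening == sim_egjo_to_class[eg]]
      expect_equal(as.character(out$motility_v2), expected, info = paste(cr, eg))
    }
  }
})
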