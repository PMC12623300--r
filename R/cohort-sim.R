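#' Calibrate a joint FLIP-by-HRM distribution from contingency counts
#'
#' Turns a table of non-negative cell counts into the sampling distribution
#' for [sample_cohort()]: cell probabilities are counts divided by the grand
#' total.  Calibrated from [cohort_counts()] the spec reproduces the
#' published cohort's joint distribution of FLIP v2.0 class and HRM/CCv4.0
#' category (conclusive and inconclusive categories kept distinct).
#'
#' @param counts Data frame of cell counts; needs the columns named below.
#' @param flip_col Column with the FLIP v2.0 class (internal codes).
#' @param hrm_col Column with the HRM category label (verbatim row labels
#'   keep conclusive and inconclusive EGJOO distinct).
#' @param label_col Column with the CCv4.0 code for each category.
#' @param n_col Column with the counts.
#' @param demographics Named list of marginal demographic parameters used
#'   as optional decoration when sampling; the defaults restate the
#'   published cohort marginals (age 55 (17), 62% female, dysphagia 75%).
#' @return A list of class `joint_spec`: `cells` (tibble with `flip_v2`,
#'   `hrm_category`, `ccv4_label`, `prob`), `total`, `demographics`.
#' @export
#' @examples
#' spec <- calibrate_joint_from_counts(cohort_counts())
#' sum(spec$cells$prob) # 1
calibrate_joint_from_counts <- function(counts,
                                        flip_col = "flip_v2",
                                        hrm_col = "hrm_row",
                                        label_col = "ccv4_label",
                                        n_col = "n",
                                        demographics = list(
                                          age_mean = 55, age_sd = 17,
                                          p_female = 0.62,
                                          indications = c(dysphagia = 0.75,
                                                          reflux = 0.08,
                                                          chest_pain = 0.043,
                                                          other = 0.127))) {
  check_columns(counts, c(flip_col, hrm_col, label_col, n_col),
                "calibrate_joint_from_counts")
  n <- counts[[n_col]]
  if (any(n < 0) || any(!is.finite(n))) {
    abort_panometry("cell counts must be finite and non-negative.",
                    "panometry_invalid_argument")
  }
  total <- sum(n)
  if (total <= 0) {
    abort_panometry("all-zero counts cannot be calibrated.",
                    "panometry_invalid_argument")
  }
  cells <- tibble::tibble(
    flip_v2 = as.character(counts[[flip_col]]),
    hrm_category = as.character(counts[[hrm_col]]),
    ccv4_label = as.character(counts[[label_col]]),
    prob = n / total
  )
  bad <- setdiff(unique(cells$flip_v2), motility_levels_v2())
  if (length(bad) > 0) {
    abort_panometry(paste0("unknown FLIP class in counts: ",
                           paste(bad, collapse = ", ")),
                    "panometry_invalid_argument")
  }
  structure(list(cells = cells, total = total, demographics = demographics),
            class = "joint_spec")
}

#' @export
print.joint_spec <- function(x, ...) {
  cat(sprintf("<joint_spec> %d cells calibrated from %g records\n",
              nrow(x$cells), x$total))
  invisible(x)
}

#' Sample FLIP metrics consistent with a motility class
#'
#' Draws, for each requested v2.0 motility class, a metric row that the
#' default thresholds classify back to exactly that class.  Each class
#' first picks one of its admissible (CR pattern, EGJ opening) cells, then
#' samples metrics uniformly within documented per-pattern ranges kept
#' clear of the decision boundaries (e.g. non-spastic obstruction draws
#' EGJ-DI in (0.5, 1.8) mm^2/mmHg and maximum diameter in (6, 11.5) mm with
#' an absent or diminished contractile response).  Uniform sampling within
#' the bounds is a deliberate minimal choice: the criteria fix thresholds,
#' not distributions.
#'
#' @param classes Character/factor vector of v2.0 motility classes.
#' @param seed Integer seed (local stream; global RNG untouched).
#' @param params A [flip_params()].
#' @return Tibble with one metric row per element of `classes` (columns of
#'   [extract_metrics()] plus `cr_truth` and `egjo_truth`).
#' @export
#' @examples
#' m <- attach_metrics(c("NORMAL", "SPASTIC_OBSTRUCTION"), seed = 7)
#' classify_flip(m)$motility_v2
attach_metrics <- function(classes, seed = 1L, params = flip_params()) {
  classes <- as.character(classes)
  bad <- setdiff(unique(classes), motility_levels_v2())
  if (length(bad) > 0) {
    abort_panometry(paste0("unknown motility class: ", paste(bad, collapse = ", ")),
                    "panometry_invalid_argument")
  }
  n <- length(classes)
  if (n == 0) return(metrics_skeleton())

  with_local_seed(seed, {
    pairs <- admissible_pairs()
    # one admissible (CR, EGJO) cell per record
    pick <- vapply(classes, function(cl) {
      idx <- which(pairs$class == cl)
      if (length(idx) == 1) idx else sample(idx, 1)
    }, integer(1))
    cr <- pairs$cr[pick]
    egjo <- pairs$egjo[pick]

    p_lo <- c(NORMAL = 20, DIMINISHED = 15, DISORDERED = 40.5,
              ABSENT = 15, SPASTIC = 20)[cr]
    p_hi <- c(NORMAL = 60, DIMINISHED = 39.5, DISORDERED = 80,
              ABSENT = 60, SPASTIC = 80)[cr]
    pressure_60 <- stats::runif(n, p_lo, p_hi)

    n_qual <- integer(n)
    n_qual[cr == "NORMAL"] <- sample(2:4, sum(cr == "NORMAL"), replace = TRUE)
    sub <- cr %in% c("DIMINISHED", "DISORDERED", "SPASTIC")
    n_qual[sub] <- sample(0:1, sum(sub), replace = TRUE)

    u <- stats::runif(n)
    spastic <- cr == "SPASTIC"
    sustained_occluding <- spastic & u < 2 / 3
    sustained_les <- spastic & u > 1 / 3

    coin <- stats::runif(n) < 0.5 # inconclusive opening has two admissible corners
    di_lo <- ifelse(egjo == "NORMAL", 2.5,
                    ifelse(egjo == "REDUCED", 0.5, ifelse(coin, 2.2, 0.5)))
    di_hi <- ifelse(egjo == "NORMAL", 6,
                    ifelse(egjo == "REDUCED", 1.8, ifelse(coin, 6, 1.8)))
    md_lo <- ifelse(egjo == "NORMAL", 16.5,
                    ifelse(egjo == "REDUCED", 6, 12.5))
    md_hi <- ifelse(egjo == "NORMAL", 22,
                    ifelse(egjo == "REDUCED", 11.5, ifelse(coin, 15.5, 20)))

    tibble::tibble(
      egj_di_60 = stats::runif(n, di_lo, di_hi),
      max_egj_diameter = stats::runif(n, md_lo, md_hi),
      pressure_60 = pressure_60,
      n_qualifying_antegrade = n_qual,
      any_contractility = cr != "ABSENT",
      sustained_occluding = sustained_occluding,
      sustained_les = sustained_les,
      rac_pattern = cr == "NORMAL" & n_qual >= 3,
      cr_truth = cr, egjo_truth = egjo
    )
  })
}

# internal: admissible (CR, EGJO) cells per v2.0 motility class, from the
# shipped decision table
admissible_pairs <- function() {
  tab <- decision_table("v2")
  tibble::tibble(class = tab$motility, cr = tab$cr, egjo = tab$egj_opening)
}

# internal: empty metrics tibble with ground-truth columns
metrics_skeleton <- function() {
  tibble::tibble(
    egj_di_60 = numeric(), max_egj_diameter = numeric(), pressure_60 = numeric(),
    n_qualifying_antegrade = integer(), any_contractility = logical(),
    sustained_occluding = logical(), sustained_les = logical(),
    rac_pattern = logical(), cr_truth = character(), egjo_truth = character()
  )
}

#' Sample a synthetic labelled cohort
#'
#' Draws `n` patients i.i.d. from a calibrated joint distribution of FLIP
#' v2.0 class and HRM category, attaches per-patient FLIP metrics that
#' re-classify to the drawn FLIP class ([attach_metrics()]), TBE fields
#' that adjudicate to the drawn conclusiveness category (conclusive EGJOO
#' gets an abnormal TBE; inconclusive EGJOO a missing one), and optional
#' demographic decoration that never feeds classification.
#'
#' @param spec A [calibrate_joint_from_counts()] result.
#' @param n Cohort size (>= 0).
#' @param seed Integer seed.
#' @param params A [flip_params()].
#' @param demographics Attach age/sex/indication columns?
#' @return Tibble with one row per patient: `patient_id`, ground-truth
#'   `flip_v2` and `hrm_category`, `ccv4_label`, metric columns, TBE
#'   columns, and demographics when requested.
#' @export
sample_cohort <- function(spec, n, seed = 1L, params = flip_params(),
                          demographics = TRUE) {
  stopifnot(inherits(spec, "joint_spec"))
  check_scalar(n, "n", function(x) x >= 0 && x == trunc(x), "a non-negative count")
  cells <- spec$cells
  if (n == 0) {
    out <- dplyr::bind_cols(
      tibble::tibble(patient_id = character(),
                     flip_v2 = factor(character(), levels = motility_levels_v2()),
                     hrm_category = character(), ccv4_label = character()),
      metrics_skeleton(),
      tibble::tibble(tbe_present = logical(), tbe_h1 = numeric(),
                     tbe_h5 = numeric(), tbe_tablet = character())
    )
    return(out)
  }

  with_local_seed(seed, {
    draw <- sample.int(nrow(cells), n, replace = TRUE, prob = cells$prob)
    metrics <- attach_metrics(cells$flip_v2[draw],
                              seed = floor(stats::runif(1, 1, 2^30)),
                              params = params)
    inconclusive_egjoo <- grepl("Inconclusive", cells$hrm_category[draw]) &
      cells$ccv4_label[draw] == "EGJOO"
    conclusive_egjoo <- cells$ccv4_label[draw] == "EGJOO" & !inconclusive_egjoo

    out <- dplyr::bind_cols(
      tibble::tibble(
        patient_id = sprintf("S%06d", seq_len(n)),
        flip_v2 = factor(cells$flip_v2[draw], levels = motility_levels_v2()),
        hrm_category = cells$hrm_category[draw],
        ccv4_label = cells$ccv4_label[draw]
      ),
      metrics
    )
    out$tbe_present <- conclusive_egjoo
    out$tbe_h1 <- ifelse(conclusive_egjoo, 10, NA_real_)
    out$tbe_h5 <- ifelse(conclusive_egjoo, 8, NA_real_)
    out$tbe_tablet <- ifelse(conclusive_egjoo, "not_administered", NA_character_)

    if (demographics) {
      dg <- spec$demographics
      out$age <- pmin(pmax(round(stats::rnorm(n, dg$age_mean, dg$age_sd)), 18), 91)
      out$sex <- ifelse(stats::runif(n) < dg$p_female, "female", "male")
      out$indication <- sample(names(dg$indications), n, replace = TRUE,
                               prob = dg$indications)
    }
    out
  })
}
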