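#' Category sets used across the package
#'
#' Canonical, ordered label sets for the two FLIP panometry scheme versions
#' and for Chicago Classification v4.0 (CCv4.0) manometry labels.  The order
#' fixes row/column ordering in every cross-tabulation.
#'
#' @name panometry_levels
NULL

#' @describeIn panometry_levels Contractile-response patterns, scheme v2.0.
#' @export
cr_levels_v2 <- function() {
  c("NORMAL", "DIMINISHED", "DISORDERED", "ABSENT", "SPASTIC")
}

#' @describeIn panometry_levels Contractile-response patterns, scheme v1.0
#'   (diminished and disordered are merged into a single impaired/disordered
#'   pattern; spastic is named spastic-reactive).
#' @export
cr_levels_v1 <- function() {
  c("NORMAL", "IMPAIRED_DISORDERED", "ABSENT", "SPASTIC_REACTIVE")
}

#' @describeIn panometry_levels EGJ-opening classes (v1.0 called the middle
#'   class "borderline"; v2.0 renamed it "inconclusive" — criteria unchanged).
#' @export
egj_opening_levels <- function() {
  c("NORMAL", "INCONCLUSIVE", "REDUCED")
}

#' @describeIn panometry_levels Motility classes, scheme v2.0.
#' @export
motility_levels_v2 <- function() {
  c("NORMAL", "HYPOCONTRACTILITY", "NON_SPASTIC_OBSTRUCTION",
    "SPASTIC_OBSTRUCTION", "POSSIBLE_SPASM", "POSSIBLE_OBSTRUCTION",
    "OBSTRUCTION_NORMAL_CR")
}

#' @describeIn panometry_levels Motility classes, scheme v1.0.
#' @export
motility_levels_v1 <- function() {
  c("NORMAL", "WEAK", "OBSTRUCTION_WEAK_CR", "SPASTIC_REACTIVE",
    "OBSTRUCTION_NORMAL_CR", "BORDERLINE_OTHER")
}

#' @describeIn panometry_levels CCv4.0 manometry labels accepted by the
#'   adjudicator. `inconclusive_other` covers studies inconclusive for
#'   reasons other than EGJ outflow obstruction.
#' @export
ccv4_levels <- function() {
  c("normal", "IEM", "absent_contractility", "DES", "hypercontractile",
    "EGJOO", "achalasia_I", "achalasia_II", "achalasia_III",
    "inconclusive_other")
}

# internal: levels of adjudicated EGJ-outflow status
outflow_levels <- function() {
  c("conclusive_outflow_disorder", "normal_outflow", "inconclusive")
}

# internal: CR phenotype codes accepted by the simulator
sim_cr_levels <- function() c("normal", "diminished", "disordered", "absent", "spastic")

# internal: EGJ-opening phenotype codes accepted by the simulator
sim_egjo_levels <- function() c("normal", "inconclusive", "reduced")
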