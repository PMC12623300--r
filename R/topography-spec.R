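#' Specify a synthetic FLIP topography
#'
#' Builds the specification consumed by [simulate_topography()].  Unset
#' arguments take phenotype-specific defaults that realise the textbook
#' presentation of each contractile-response (CR) pattern and EGJ-opening
#' class:
#'
#' * `normal` CR: 3 antegrade 8-cm contractions, 60-mL pressure 35 mmHg;
#' * `diminished` CR: 2 antegrade contractions of only 4 cm (too short to
#'   qualify as normal), 60-mL pressure 30 mmHg;
#' * `disordered` CR: 2 retrograde 7-cm contractions, 60-mL pressure
#'   55 mmHg;
#' * `absent` CR: no contractions;
#' * `spastic` CR: one sustained (12 s) occluding contraction, or a
#'   sustained lower-esophageal-sphincter (LES) contraction when
#'   `spastic_type = "les"`; 60-mL pressure 50 mmHg.
#'
#' EGJ-opening defaults: `normal` has 60-mL distensibility index (DI)
#' 4.0 mm^2/mmHg and maximum EGJ diameter 18 mm; `inconclusive` 1.5 and
#' 14 mm; `reduced` 1.0 and 10 mm.
#'
#' Contradictory combinations (an absent CR with contractions requested, a
#' normal CR whose contractions could not satisfy the normal criteria, a
#' diminished CR with 60-mL pressure above 40 mmHg, an EGJ whose 60-mL
#' diameter implied by `egj_di_60` and `pressure_60` would exceed
#' `max_egj_diameter`, ...) are rejected at construction.
#'
#' @param cr_phenotype One of `"normal"`, `"diminished"`, `"disordered"`,
#'   `"absent"`, `"spastic"`.
#' @param egj_phenotype One of `"normal"`, `"inconclusive"`, `"reduced"`.
#' @param n_contractions Number of injected contraction bands.
#' @param contraction_extent_cm Axial extent of each band (cm, in (0, 11]:
#'   bands live in the esophageal-body channels).
#' @param contraction_speed_cm_s Signed axial velocity (cm/s); positive is
#'   antegrade (proximal to distal), negative retrograde, 0 stationary.
#' @param occlusion_duration_s Duration of the stationary spastic band (s).
#' @param spastic_type `"occluding"` (body band) or `"les"` (sustained
#'   EGJ-level contraction); only used when `cr_phenotype = "spastic"`.
#' @param pressure_60 Bag pressure during the 60-mL fill step (mmHg).
#' @param pressure_rise Contraction-associated pressure rise (mmHg).
#' @param egj_di_60 Target EGJ distensibility index at 60 mL (mm^2/mmHg).
#' @param max_egj_diameter Target maximum EGJ diameter over 60-70 mL (mm).
#' @param noise_sd Additive diameter noise SD (mm, >= 0).
#' @param seed Integer seed for the study's noise stream.
#' @return A list of class `topography_spec`.
#' @export
#' @examples
#' topography_spec("normal", "normal")
#' topography_spec("spastic", "reduced", spastic_type = "les")
topography_spec <- function(cr_phenotype = c("normal", "diminished", "disordered",
                                             "absent", "spastic"),
                            egj_phenotype = c("normal", "inconclusive", "reduced"),
                            n_contractions = NULL,
                            contraction_extent_cm = NULL,
                            contraction_speed_cm_s = NULL,
                            occlusion_duration_s = 12,
                            spastic_type = c("occluding", "les"),
                            pressure_60 = NULL,
                            pressure_rise = 15,
                            egj_di_60 = NULL,
                            max_egj_diameter = NULL,
                            noise_sd = 0,
                            seed = 1L) {
  cr_phenotype <- match.arg(cr_phenotype)
  egj_phenotype <- match.arg(egj_phenotype)
  spastic_type <- match.arg(spastic_type)

  cr_defaults <- list(
    normal     = list(n = 3L, extent = 8,  speed = 3,  p60 = 35),
    diminished = list(n = 2L, extent = 4,  speed = 3,  p60 = 30),
    disordered = list(n = 2L, extent = 7,  speed = -3, p60 = 55),
    absent     = list(n = 0L, extent = 8,  speed = 3,  p60 = 35),
    spastic    = list(n = 1L, extent = 4,  speed = 0,  p60 = 50)
  )[[cr_phenotype]]
  egj_defaults <- list(
    normal       = list(di = 4.0, maxd = 18),
    inconclusive = list(di = 1.5, maxd = 14),
    reduced      = list(di = 1.0, maxd = 10)
  )[[egj_phenotype]]

  n_contractions <- if (is.null(n_contractions)) cr_defaults$n else as.integer(n_contractions)
  contraction_extent_cm <- contraction_extent_cm %||% cr_defaults$extent
  contraction_speed_cm_s <- contraction_speed_cm_s %||% cr_defaults$speed
  pressure_60 <- pressure_60 %||% cr_defaults$p60
  egj_di_60 <- egj_di_60 %||% egj_defaults$di
  max_egj_diameter <- max_egj_diameter %||% egj_defaults$maxd

  check_scalar(n_contractions, "n_contractions", function(x) x >= 0, "a non-negative count")
  check_scalar(contraction_extent_cm, "contraction_extent_cm",
               function(x) x > 0 && x <= 11,
               "in (0, 11] (bands live in esophageal-body channels 1-12)")
  check_scalar(noise_sd, "noise_sd", function(x) x >= 0, "non-negative")
  check_scalar(pressure_60, "pressure_60", function(x) x > 0, "positive")
  check_scalar(egj_di_60, "egj_di_60", function(x) x > 0, "positive")
  check_scalar(max_egj_diameter, "max_egj_diameter", function(x) x > 0, "positive")
  check_scalar(occlusion_duration_s, "occlusion_duration_s", function(x) x > 0, "positive")

  contradiction <- function(msg) {
    abort_panometry(paste0("contradictory topography spec: ", msg),
                    "panometry_contradictory_spec")
  }
  if (cr_phenotype == "absent" && n_contractions > 0) {
    contradiction("an absent contractile response cannot have contractions.")
  }
  if (cr_phenotype != "absent" && n_contractions < 1) {
    contradiction(sprintf("a %s contractile response needs at least one contraction.",
                          cr_phenotype))
  }
  if (cr_phenotype == "normal" &&
      (n_contractions < 2 || contraction_extent_cm < 6 || contraction_speed_cm_s <= 0)) {
    contradiction("a normal contractile response needs > 1 antegrade contraction of >= 6 cm.")
  }
  if (cr_phenotype %in% c("diminished", "disordered") &&
      n_contractions >= 2 && contraction_speed_cm_s > 0 && contraction_extent_cm >= 6) {
    contradiction(paste0("multiple antegrade contractions of >= 6 cm would satisfy the ",
                         "normal criteria, not a ", cr_phenotype, " pattern."))
  }
  if (cr_phenotype == "diminished" && pressure_60 > 40) {
    contradiction("a diminished contractile response requires 60-mL pressure <= 40 mmHg.")
  }
  if (cr_phenotype == "disordered" && pressure_60 <= 40) {
    contradiction("a disordered contractile response requires 60-mL pressure > 40 mmHg.")
  }
  d60 <- 2 * sqrt(egj_di_60 * pressure_60 / pi)
  if (d60 > max_egj_diameter + 1e-9) {
    contradiction(sprintf(
      "egj_di_60 = %.3g at pressure %.3g mmHg implies a 60-mL EGJ diameter of %.1f mm, exceeding max_egj_diameter = %.3g mm.",
      egj_di_60, pressure_60, d60, max_egj_diameter))
  }

  structure(
    list(cr_phenotype = cr_phenotype, egj_phenotype = egj_phenotype,
         n_contractions = n_contractions,
         contraction_extent_cm = contraction_extent_cm,
         contraction_speed_cm_s = contraction_speed_cm_s,
         occlusion_duration_s = occlusion_duration_s,
         spastic_type = spastic_type,
         pressure_60 = pressure_60, pressure_rise = pressure_rise,
         egj_di_60 = egj_di_60, max_egj_diameter = max_egj_diameter,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "topography_spec"
  )
}

#' @export
print.topography_spec <- function(x, ...) {
  cat(sprintf(
    "<topography_spec> CR %s / EGJ opening %s: %d contraction(s), extent %g cm, speed %g cm/s\n  60-mL pressure %g mmHg, EGJ-DI %g mm^2/mmHg, max EGJ diameter %g mm, noise SD %g mm, seed %d\n",
    x$cr_phenotype, x$egj_phenotype, x$n_contractions,
    x$contraction_extent_cm, x$contraction_speed_cm_s,
    x$pressure_60, x$egj_di_60, x$max_egj_diameter, x$noise_sd, x$seed
  ))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
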