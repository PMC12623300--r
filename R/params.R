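#' Analysis parameters for feature extraction and classification
#'
#' Collects every tunable threshold used by the contraction-event detector,
#' the EGJ-opening metrics, and the contractile-response / EGJ-opening
#' classifiers, with the consensus defaults.  All lengths are in cm or mm as
#' indicated, times in seconds, pressures in mmHg, distensibility in
#' mm^2/mmHg.
#'
#' @param sampling_hz Topography sampling rate used by the simulator (Hz).
#' @param dwell_s Dwell time per fill step (s); the fill protocol holds each
#'   volume for 30-60 s.
#' @param fill_volumes Stepwise fill protocol volumes (mL).
#' @param n_channels Number of impedance sensor channels (1-cm spacing).
#' @param egj_channels Integer vector of channel indices straddling the EGJ.
#' @param rel_threshold Contraction threshold as a fraction of the per-channel
#'   rolling baseline diameter.
#' @param abs_floor_mm Absolute contraction threshold (mm); the effective
#'   threshold at each sample is the stricter (smaller) of the relative and
#'   absolute thresholds.
#' @param baseline_window_s Width of the per-channel rolling-median baseline
#'   window (s); must exceed twice the longest expected occlusion so sustained
#'   contractions do not drag the baseline down.
#' @param occluding_mm Minimum diameter at or below which a contraction is
#'   lumen-occluding (mm).
#' @param sustained_s Minimum duration for a contraction to count as
#'   sustained (s).
#' @param distinct_gap_s,distinct_gap_ch Minimum temporal (s) / axial
#'   (channels) separation for two contraction regions to count as distinct;
#'   closer regions are merged into one event.
#' @param pressure_baseline_s Pre-event window used as the pressure baseline
#'   when measuring the contraction-associated pressure rise (s).
#' @param direction_slope_cm_s Minimum |ridge slope| (cm/s) to call an event
#'   antegrade (positive) or retrograde (negative); slower events are "mixed".
#' @param analysis_min_fill Contractile response is evaluated from this fill
#'   volume onward (mL).
#' @param egj_window_s EGJ-distensibility analysis window: the final
#'   `egj_window_s` seconds of the 60-mL fill step.
#' @param min_extent_cm Minimum axial length for a qualifying antegrade
#'   contraction (cm).
#' @param min_pressure_rise Minimum associated pressure rise for a qualifying
#'   contraction (mmHg).
#' @param min_antegrade Number of distinct qualifying antegrade contractions
#'   that must be exceeded for a normal contractile response ("multiple"
#'   means more than 1, so the default demands at least 2).
#' @param pressure_split 60-mL pressure split between diminished (at or
#'   below) and disordered (above) contractile response (mmHg).
#' @param egj_di_normal EGJ-DI at or above which (with adequate diameter)
#'   EGJ opening is normal (mm^2/mmHg).
#' @param max_diameter_normal Maximum-EGJ-diameter threshold for normal
#'   opening (mm).
#' @param max_diameter_reduced Maximum-EGJ-diameter threshold below which
#'   (with low EGJ-DI) opening is reduced (mm).
#'
#' @return A named list of class `flip_params`.
#' @export
#' @examples
#' p <- flip_params()
#' p$pressure_split
flip_params <- function(sampling_hz = 10,
                        dwell_s = 40,
                        fill_volumes = c(40, 50, 60, 70),
                        n_channels = 16,
                        egj_channels = 13:15,
                        rel_threshold = 0.5,
                        abs_floor_mm = 9,
                        baseline_window_s = 25,
                        occluding_mm = 2,
                        sustained_s = 10,
                        distinct_gap_s = 2,
                        distinct_gap_ch = 2,
                        pressure_baseline_s = 5,
                        direction_slope_cm_s = 0.5,
                        analysis_min_fill = 50,
                        egj_window_s = 10,
                        min_extent_cm = 6,
                        min_pressure_rise = 10,
                        min_antegrade = 2,
                        pressure_split = 40,
                        egj_di_normal = 2.0,
                        max_diameter_normal = 16,
                        max_diameter_reduced = 12) {
  check_scalar(dwell_s, "dwell_s", function(x) x >= 30 && x <= 60,
               "within the 30-60 s protocol dwell")
  check_scalar(rel_threshold, "rel_threshold", function(x) x > 0 && x < 1,
               "in (0, 1)")
  for (nm in c("sampling_hz", "abs_floor_mm", "baseline_window_s", "occluding_mm",
               "sustained_s", "pressure_baseline_s", "egj_window_s",
               "min_extent_cm", "min_pressure_rise", "pressure_split",
               "egj_di_normal", "max_diameter_normal", "max_diameter_reduced")) {
    check_scalar(get(nm), nm, function(x) is.finite(x) && x > 0, "a positive number")
  }
  if (max_diameter_reduced > max_diameter_normal) {
    abort_panometry("`max_diameter_reduced` cannot exceed `max_diameter_normal`.",
                    "panometry_invalid_argument")
  }
  structure(
    list(
      sampling_hz = sampling_hz, dwell_s = dwell_s, fill_volumes = fill_volumes,
      n_channels = n_channels, egj_channels = egj_channels,
      rel_threshold = rel_threshold, abs_floor_mm = abs_floor_mm,
      baseline_window_s = baseline_window_s, occluding_mm = occluding_mm,
      sustained_s = sustained_s, distinct_gap_s = distinct_gap_s,
      distinct_gap_ch = distinct_gap_ch,
      pressure_baseline_s = pressure_baseline_s,
      direction_slope_cm_s = direction_slope_cm_s,
      analysis_min_fill = analysis_min_fill, egj_window_s = egj_window_s,
      min_extent_cm = min_extent_cm, min_pressure_rise = min_pressure_rise,
      min_antegrade = min_antegrade, pressure_split = pressure_split,
      egj_di_normal = egj_di_normal,
      max_diameter_normal = max_diameter_normal,
      max_diameter_reduced = max_diameter_reduced
    ),
    class = "flip_params"
  )
}

#' Pipeline configuration
#'
#' Bundles the analysis parameters with run-level settings: the RNG seed, the
#' rounding policy for reported percentages, and how the grammatically
#' ambiguous inconclusive-TBE clause is parsed (see [classify_tbe()]).
#'
#' @param params A [flip_params()] list.
#' @param seed Integer seed driving every stochastic stage.
#' @param percent_digits Decimal digits kept when rounding percentages
#'   (half away from zero).
#' @param tbe_clause How "no tablet administration or tablet passage" is
#'   parsed: `"either"` (not administered OR passed; default) or
#'   `"passage_only"` (tablet passed only).
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(params = flip_params(),
                            seed = 1L,
                            percent_digits = 0,
                            tbe_clause = c("either", "passage_only")) {
  tbe_clause <- match.arg(tbe_clause)
  stopifnot(inherits(params, "flip_params"))
  structure(
    list(params = params, seed = as.integer(seed),
         percent_digits = percent_digits, tbe_clause = tbe_clause),
    class = "pipeline_config"
  )
}

#' Read / write a pipeline configuration
#'
#' Configurations round-trip losslessly through YAML so every report can
#' embed the exact thresholds that produced it.
#'
#' @param config A [pipeline_config()] object.
#' @param path File path.
#' @return `write_config()` returns `config` invisibly; `read_config()`
#'   returns a `pipeline_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  x <- unclass(config)
  x$params <- unclass(x$params)
  yaml::write_yaml(x, path)
  invisible(config)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  pipeline_config(
    params = do.call(flip_params, x$params),
    seed = x$seed,
    percent_digits = x$percent_digits,
    tbe_clause = x$tbe_clause
  )
}
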