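#' FLIP panometry study container
#'
#' A `flip_study` holds one exam: a uniformly sampled time axis, the stepwise
#' bag fill volume (mL), bag pressure (mmHg), and a time-by-channel grid of
#' luminal diameters (mm) from 16 impedance sensors at 1-cm spacing, channel
#' 1 proximal to channel 16 distal, with the EGJ straddled by a declared
#' channel interval.  Simulated studies additionally carry the clean
#' (pre-noise, pre-contraction) baseline grid and a ground-truth event table.
#'
#' @param time Numeric vector of sample times (s), uniformly spaced.
#' @param fill_volume Numeric vector, mL per sample; non-decreasing step
#'   function over the fill protocol.
#' @param bag_pressure Numeric vector, mmHg per sample.
#' @param diameters Numeric matrix, `length(time)` rows by 16 channels (mm).
#' @param egj_channels Integer vector of channel indices straddling the EGJ.
#' @param events Ground-truth contraction event tibble (simulated studies)
#'   or `NULL`.
#' @param baseline Clean baseline diameter matrix (simulated studies) or
#'   `NULL`.
#' @return An object of class `flip_study`.
#' @export
flip_study <- function(time, fill_volume, bag_pressure, diameters,
                       egj_channels = 13:15, events = NULL, baseline = NULL) {
  study <- structure(
    list(time = as.numeric(time), fill_volume = as.numeric(fill_volume),
         bag_pressure = as.numeric(bag_pressure),
         diameters = as.matrix(diameters),
         egj_channels = as.integer(egj_channels),
         events = events, baseline = baseline),
    class = "flip_study"
  )
  validate_flip_study(study)
  study
}

#' Validate a FLIP study against the protocol invariants
#'
#' Checks that all diameters are positive, the fill volume is a
#' non-decreasing step function whose dwell per step lies within the 30-60 s
#' protocol bound, the channel count is 16, and all traces share one time
#' axis.
#'
#' @param study A [flip_study()].
#' @return `study`, invisibly; errors describe the violated invariant.
#' @export
validate_flip_study <- function(study) {
  stopifnot(inherits(study, "flip_study"))
  n <- length(study$time)
  if (length(study$fill_volume) != n || length(study$bag_pressure) != n ||
      nrow(study$diameters) != n) {
    abort_panometry("time, fill_volume, bag_pressure and diameters must share one time axis.",
                    "panometry_invalid_study")
  }
  if (ncol(study$diameters) != 16) {
    abort_panometry("a FLIP study must have exactly 16 sensor channels.",
                    "panometry_invalid_study")
  }
  if (any(study$diameters <= 0)) {
    abort_panometry("all luminal diameters must be positive.",
                    "panometry_invalid_study")
  }
  if (any(diff(study$fill_volume) < 0)) {
    abort_panometry("fill volume must be non-decreasing over time.",
                    "panometry_invalid_study")
  }
  if (n > 1) {
    dt <- diff(study$time)
    if (max(dt) - min(dt) > 1e-8) {
      abort_panometry("time axis must be uniformly sampled.",
                      "panometry_invalid_study")
    }
    dwell <- rle(study$fill_volume)$lengths * dt[1]
    if (any(dwell < 30 - 1e-9) || any(dwell > 60 + 1e-9)) {
      abort_panometry("each fill step must dwell between 30 and 60 s.",
                      "panometry_invalid_study")
    }
  }
  if (any(study$egj_channels < 1) || any(study$egj_channels > 16)) {
    abort_panometry("egj_channels must index channels 1..16.",
                    "panometry_invalid_study")
  }
  invisible(study)
}

#' @export
print.flip_study <- function(x, ...) {
  fs <- if (length(x$time) > 1) 1 / (x$time[2] - x$time[1]) else NA_real_
  cat(sprintf(
    "<flip_study> %d samples @ %.4g Hz, %d channels, fill %g-%g mL, EGJ channels %s\n",
    length(x$time), fs, ncol(x$diameters),
    min(x$fill_volume), max(x$fill_volume),
    paste(range(x$egj_channels), collapse = "-")
  ))
  if (!is.null(x$events)) {
    cat(sprintf("  ground-truth events: %d\n", nrow(x$events)))
  }
  invisible(x)
}

#' @importFrom tibble as_tibble
#' @export
as_tibble.flip_study <- function(x, ...) {
  n <- length(x$time)
  tibble::tibble(
    time = rep(x$time, times = ncol(x$diameters)),
    channel = rep(seq_len(ncol(x$diameters)), each = n),
    diameter = as.vector(x$diameters),
    fill_volume = rep(x$fill_volume, times = ncol(x$diameters)),
    bag_pressure = rep(x$bag_pressure, times = ncol(x$diameters))
  )
}

#' @importFrom generics tidy
#' @export
tidy.flip_study <- function(x, ...) as_tibble.flip_study(x)

#' @importFrom generics glance
#' @export
glance.flip_study <- function(x, ...) {
  tibble::tibble(
    n_samples = length(x$time),
    n_channels = ncol(x$diameters),
    sampling_hz = if (length(x$time) > 1) 1 / (x$time[2] - x$time[1]) else NA_real_,
    min_fill = min(x$fill_volume),
    max_fill = max(x$fill_volume),
    n_ground_truth_events = if (is.null(x$events)) NA_integer_ else nrow(x$events)
  )
}

#' Write / read a FLIP study as plain text
#'
#' The diameter grid is written as a long-format CSV (time, channel,
#' diameter); pressure, fill volume, the EGJ channel interval and any
#' ground-truth events go to a JSON side-car at `paste0(path, ".json")`.
#'
#' @param study A [flip_study()].
#' @param path Path of the CSV file to write/read.
#' @return `write_flip_study()` returns `study` invisibly;
#'   `read_flip_study()` returns a `flip_study`.
#' @export
write_flip_study <- function(study, path) {
  stopifnot(inherits(study, "flip_study"))
  long <- as_tibble.flip_study(study)[, c("time", "channel", "diameter")]
  readr::write_csv(long, path)
  side <- list(
    fill_volume = study$fill_volume,
    bag_pressure = study$bag_pressure,
    egj_channels = study$egj_channels,
    events = study$events
  )
  jsonlite::write_json(side, paste0(path, ".json"), digits = NA, null = "null")
  invisible(study)
}

#' @rdname write_flip_study
#' @export
read_flip_study <- function(path) {
  long <- readr::read_csv(path, show_col_types = FALSE)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  time <- sort(unique(long$time))
  n_ch <- max(long$channel)
  d <- matrix(NA_real_, length(time), n_ch)
  d[cbind(match(long$time, time), long$channel)] <- long$diameter
  events <- side$events
  if (!is.null(events) && is.data.frame(events)) events <- tibble::as_tibble(events)
  flip_study(
    time = time, fill_volume = side$fill_volume,
    bag_pressure = side$bag_pressure, diameters = d,
    egj_channels = side$egj_channels, events = events
  )
}
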