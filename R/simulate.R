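#' Simulate a FLIP panometry study with known ground truth
#'
#' Generates a complete stepwise-fill FLIP exam (40/50/60/70 mL, each held
#' for `params$dwell_s` seconds at `params$sampling_hz` Hz) whose diameter
#' topography embeds, by construction, the contractile-response and
#' EGJ-opening phenotype requested in `spec`:
#'
#' * the EGJ channels carry a diameter trace whose 60-mL value reproduces
#'   `spec$egj_di_60` at `spec$pressure_60` exactly (circular-lumen
#'   cross-section), and whose 70-mL value equals `spec$max_egj_diameter`;
#' * contraction bands are travelling (or stationary) diameter reductions on
#'   the esophageal-body channels, Gaussian in space, with raised-cosine
#'   onset/offset and a synchronous bag-pressure rise; their axial extent is
#'   the exact channel span driven below the detection threshold;
#' * all bands are placed during the 50- and 60-mL steps (the analysed
#'   period), leaving the final `params$egj_window_s` seconds of the 60-mL
#'   step event-free for the distensibility measurement.
#'
#' The returned study carries the injected events as ground truth
#' (`study$events`) and the clean baseline grid (`study$baseline`).
#' Identical `spec` (including seed) yields a bit-identical study.
#'
#' @param spec A [topography_spec()].
#' @param params A [flip_params()].
#' @return A [flip_study()] with ground-truth `events` tibble.
#' @export
#' @examples
#' study <- simulate_topography(topography_spec("normal", "normal"))
#' study$events
simulate_topography <- function(spec, params = flip_params()) {
  stopifnot(inherits(spec, "topography_spec"))
  stopifnot(inherits(params, "flip_params"))

  study <- baseline_study(spec, params)

  plan <- schedule_events(spec, params)
  for (i in seq_len(nrow(plan))) {
    ev <- plan[i, ]
    if (ev$at_egj) {
      study <- inject_les_contraction(
        study, onset_s = ev$onset, duration_s = ev$duration,
        pressure_rise = spec$pressure_rise, params = params
      )
    } else {
      study <- inject_contraction_band(
        study, onset_s = ev$onset, start_channel = ev$start_channel,
        extent_cm = spec$contraction_extent_cm,
        speed_cm_s = ev$speed,
        duration_s = if (ev$speed == 0) ev$duration else NULL,
        target_min_mm = ev$target_min,
        pressure_rise = spec$pressure_rise, params = params
      )
    }
  }
  if (is.null(study$events)) {
    study$events <- empty_event_table()
  }
  if (spec$noise_sd > 0) {
    study <- add_noise(study, spec$noise_sd, seed = spec$seed)
  }
  validate_flip_study(study)
  study
}

# internal: clean baseline study (no contractions, no noise)
baseline_study <- function(spec, params) {
  fs <- params$sampling_hz
  dwell_n <- round(params$dwell_s * fs)
  vols <- params$fill_volumes
  n <- dwell_n * length(vols)
  time <- (seq_len(n) - 1) / fs
  fill <- rep(vols, each = dwell_n)

  # esophageal-body baseline widens with distension volume
  body_base <- stats::setNames(c(12, 14, 16, 18), c("40", "50", "60", "70"))
  # EGJ diameter: 60-mL value implied by the distensibility target,
  # 70-mL value equals the target maximum; sub-60 steps proportionally tighter
  d60 <- 2 * sqrt(spec$egj_di_60 * spec$pressure_60 / pi)
  egj_base <- stats::setNames(
    c(0.70 * d60, 0.85 * d60, d60, spec$max_egj_diameter), c("40", "50", "60", "70"))
  p_base <- stats::setNames(
    spec$pressure_60 * c(0.5, 0.75, 1, 1.25), c("40", "50", "60", "70"))

  key <- as.character(fill)
  d <- matrix(NA_real_, n, params$n_channels)
  body_ch <- setdiff(seq_len(params$n_channels), c(params$egj_channels, params$n_channels))
  for (ch in body_ch) d[, ch] <- body_base[key]
  for (ch in params$egj_channels) d[, ch] <- egj_base[key]
  d[, params$n_channels] <- 19 # intragastric sensor beyond the EGJ

  flip_study(
    time = time, fill_volume = fill, bag_pressure = unname(p_base[key]),
    diameters = d, egj_channels = params$egj_channels,
    events = empty_event_table(), baseline = d
  )
}

# internal: empty ground-truth/detected event table with the full schema
empty_event_table <- function() {
  tibble::tibble(
    onset_time = numeric(), offset_time = numeric(),
    channel_lo = integer(), channel_hi = integer(),
    axial_extent = numeric(),
    direction = character(),
    occluding = logical(), sustained = logical(), at_egj = logical(),
    pressure_rise = numeric()
  )
}

# internal: lay out the requested contractions in the 50- and 60-mL steps,
# keeping the final EGJ-DI window of the 60-mL step event-free
schedule_events <- function(spec, params) {
  if (spec$n_contractions == 0) {
    return(tibble::tibble(onset = numeric(), duration = numeric(),
                          start_channel = integer(), speed = numeric(),
                          target_min = numeric(), at_egj = logical()))
  }
  dwell <- params$dwell_s
  t50 <- dwell          # start of the 50-mL step
  t60 <- 2 * dwell
  # leading margin keeps the pre-event pressure-baseline window inside the step
  lead <- params$pressure_baseline_s + 1
  windows <- list(
    c(t50 + lead, t50 + dwell - 2),
    c(t60 + lead, t60 + dwell - params$egj_window_s - 2)
  )
  spastic <- spec$cr_phenotype == "spastic"
  at_egj <- spastic && spec$spastic_type == "les"
  stationary <- spastic || spec$contraction_speed_cm_s == 0
  duration <- if (stationary) {
    spec$occlusion_duration_s
  } else {
    (spec$contraction_extent_cm - 1) / abs(spec$contraction_speed_cm_s) + 1
  }
  gap <- max(params$distinct_gap_s + 2, 4)

  onsets <- numeric(0)
  w <- 1
  cursor <- windows[[1]][1]
  for (i in seq_len(spec$n_contractions)) {
    while (cursor + duration > windows[[w]][2]) {
      w <- w + 1
      if (w > length(windows)) {
        abort_panometry(
          sprintf("cannot place %d contraction(s) of %.1f s within the analysed fill steps.",
                  spec$n_contractions, duration),
          "panometry_contradictory_spec")
      }
      cursor <- windows[[w]][1]
    }
    onsets[i] <- cursor
    cursor <- cursor + duration + gap
  }

  tibble::tibble(
    onset = onsets, duration = duration,
    start_channel = if (stationary) 5L else 2L,
    speed = if (stationary) 0 else spec$contraction_speed_cm_s,
    target_min = if (spastic && !at_egj) 1 else 3,
    at_egj = at_egj
  )
}

#' Inject a contraction band into a FLIP study
#'
#' Low-level primitive behind [simulate_topography()], exposed so tests and
#' users can build bespoke topographies (e.g. a band confined to the 40-mL
#' step).  The band is a Gaussian-in-space diameter reduction on the
#' esophageal-body channels whose centre travels at `speed_cm_s`; its spatial
#' width is calibrated so the channel span driven below the default detection
#' threshold equals `extent_cm` exactly.  A synchronous raised-cosine bag
#' pressure rise of `pressure_rise` mmHg accompanies the band.
#'
#' @param study A [flip_study()] carrying its clean `baseline` grid.
#' @param onset_s Event onset time (s).
#' @param start_channel Most proximal channel the band centre visits.
#' @param extent_cm Axial extent (cm = channels).
#' @param speed_cm_s Signed axial velocity; positive antegrade, negative
#'   retrograde, 0 stationary (then `duration_s` is required).
#' @param duration_s Total event duration for stationary bands (s).
#' @param target_min_mm Minimum diameter reached at the band centre (mm);
#'   at or below `params$occluding_mm` the band is lumen-occluding.
#' @param pressure_rise Peak synchronous pressure rise (mmHg).
#' @param ramp_s Raised-cosine onset/offset ramp (s).
#' @param params A [flip_params()].
#' @return The modified study, with the event appended to `study$events`.
#' @export
inject_contraction_band <- function(study, onset_s, start_channel, extent_cm,
                                    speed_cm_s = 3, duration_s = NULL,
                                    target_min_mm = 3, pressure_rise = 15,
                                    ramp_s = 0.5, params = flip_params()) {
  stopifnot(inherits(study, "flip_study"))
  if (is.null(study$baseline)) {
    abort_panometry("inject_contraction_band() needs a study with its clean baseline grid.",
                    "panometry_invalid_study")
  }
  m <- extent_cm - 1
  stationary <- speed_cm_s == 0
  if (stationary && is.null(duration_s)) {
    abort_panometry("stationary bands need `duration_s`.", "panometry_invalid_argument")
  }
  travel <- if (stationary) 0 else m / abs(speed_cm_s)
  dur <- if (stationary) duration_s else travel + 2 * ramp_s
  offset_s <- onset_s + dur

  idx <- which(study$time >= onset_s & study$time <= offset_s)
  if (length(idx) == 0) return(study)
  tt <- study$time[idx]

  # temporal envelope: raised-cosine ramps around a full-depth plateau
  env <- rep(1, length(tt))
  up <- tt < onset_s + ramp_s
  dn <- tt > offset_s - ramp_s
  env[up] <- 0.5 * (1 - cos(pi * (tt[up] - onset_s) / ramp_s))
  env[dn] <- 0.5 * (1 - cos(pi * (offset_s - tt[dn]) / ramp_s))

  # band centre: holds at the endpoints during the ramps, travels in between
  if (stationary) {
    centre <- rep(start_channel + m / 2, length(tt))
    ch_lo <- ceiling(start_channel + m / 2 - extent_cm / 2 + 1e-9)
    ch_hi <- floor(start_channel + m / 2 + extent_cm / 2 - 1e-9)
  } else {
    frac <- pmin(pmax((tt - (onset_s + ramp_s)) / travel, 0), 1)
    if (speed_cm_s > 0) {
      centre <- start_channel + frac * m
    } else {
      centre <- start_channel + m - frac * m
    }
    ch_lo <- start_channel
    ch_hi <- start_channel + as.integer(m)
  }

  body_ch <- setdiff(seq_len(params$n_channels),
                     c(study$egj_channels, params$n_channels))
  if (ch_lo < min(body_ch) || ch_hi > max(body_ch)) {
    abort_panometry("contraction band exceeds the esophageal-body channel range.",
                    "panometry_contradictory_spec")
  }

  # spatial width calibrated against the detection threshold at this fill step
  base_mm <- study$baseline[idx[1], ch_lo]
  thr <- min(params$rel_threshold * base_mm, params$abs_floor_mm)
  depth <- base_mm - target_min_mm
  if (depth <= base_mm - thr) {
    abort_panometry("band too shallow to cross the detection threshold.",
                    "panometry_contradictory_spec")
  }
  half_width <- if (stationary) extent_cm / 2 else 0.75
  sigma <- half_width / sqrt(2 * log(depth / (base_mm - thr)))

  for (ch in body_ch) {
    dip <- depth * env * exp(-((ch - centre)^2) / (2 * sigma^2))
    study$diameters[idx, ch] <- pmax(study$diameters[idx, ch] - dip, 0.3)
  }

  # synchronous pressure rise peaking mid-event
  study$bag_pressure[idx] <- study$bag_pressure[idx] +
    pressure_rise * 0.5 * (1 - cos(2 * pi * (tt - onset_s) / dur))

  direction <- if (stationary) "mixed" else if (speed_cm_s > 0) "antegrade" else "retrograde"
  ev <- tibble::tibble(
    onset_time = onset_s, offset_time = offset_s,
    channel_lo = as.integer(ch_lo), channel_hi = as.integer(ch_hi),
    axial_extent = as.numeric(ch_hi - ch_lo + 1),
    direction = direction,
    occluding = target_min_mm <= params$occluding_mm,
    sustained = dur - ramp_s >= params$sustained_s,
    at_egj = FALSE,
    pressure_rise = pressure_rise
  )
  study$events <- dplyr::bind_rows(study$events, ev)
  study
}

# internal: sustained EGJ-level (LES) contraction — flat diameter reduction
# confined to the EGJ channels
inject_les_contraction <- function(study, onset_s, duration_s,
                                   pressure_rise = 15, ramp_s = 0.5,
                                   params = flip_params()) {
  offset_s <- onset_s + duration_s
  idx <- which(study$time >= onset_s & study$time <= offset_s)
  tt <- study$time[idx]
  env <- rep(1, length(tt))
  up <- tt < onset_s + ramp_s
  dn <- tt > offset_s - ramp_s
  env[up] <- 0.5 * (1 - cos(pi * (tt[up] - onset_s) / ramp_s))
  env[dn] <- 0.5 * (1 - cos(pi * (offset_s - tt[dn]) / ramp_s))

  for (ch in study$egj_channels) {
    base <- study$baseline[idx, ch]
    target <- 0.3 * base # well below the relative detection threshold
    study$diameters[idx, ch] <- pmax(base - (base - target) * env, 0.3)
  }
  study$bag_pressure[idx] <- study$bag_pressure[idx] +
    pressure_rise * 0.5 * (1 - cos(2 * pi * (tt - onset_s) / duration_s))

  ev <- tibble::tibble(
    onset_time = onset_s, offset_time = offset_s,
    channel_lo = min(study$egj_channels), channel_hi = max(study$egj_channels),
    axial_extent = as.numeric(length(study$egj_channels)),
    direction = "mixed",
    occluding = FALSE,
    sustained = duration_s - ramp_s >= params$sustained_s,
    at_egj = TRUE,
    pressure_rise = pressure_rise
  )
  study$events <- dplyr::bind_rows(study$events, ev)
  study
}

#' Add measurement noise to a FLIP study
#'
#' Adds zero-mean Gaussian perturbation to the diameter grid, floored at
#' 0.3 mm so diameters stay positive (the floor only engages at occluded
#' lumens).  Pressure and fill volume are untouched.  The same seed always
#' reproduces the same perturbation; the caller's RNG state is untouched.
#'
#' @param study A [flip_study()].
#' @param noise_sd Noise standard deviation (mm, >= 0).
#' @param seed Integer seed.
#' @return The perturbed study.
#' @export
add_noise <- function(study, noise_sd, seed = 1L) {
  stopifnot(inherits(study, "flip_study"))
  check_scalar(noise_sd, "noise_sd", function(x) x >= 0, "non-negative")
  if (noise_sd == 0) return(study)
  eps <- with_local_seed(seed, stats::rnorm(length(study$diameters), 0, noise_sd))
  study$diameters <- pmax(study$diameters + eps, 0.3)
  study
}
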