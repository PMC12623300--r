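#' Cross-sectional area from luminal diameter
#'
#' Impedance planimetry reports luminal diameter; the distensibility index
#' uses cross-sectional area under a circular-lumen assumption,
#' CSA = pi (d/2)^2.
#'
#' @param diameter_mm Positive diameter(s), mm.
#' @return Area(s), mm^2.
#' @export
#' @examples
#' compute_csa(16) # 201.06 mm^2
compute_csa <- function(diameter_mm) {
  if (any(!is.finite(diameter_mm)) || any(diameter_mm <= 0)) {
    abort_panometry("diameters must be positive and finite.",
                    "panometry_invalid_argument")
  }
  pi * (diameter_mm / 2)^2
}

#' EGJ opening metrics
#'
#' Computes the three EGJ-opening quantities the classifier consumes:
#'
#' * `egj_di_60`: EGJ distensibility index at the 60-mL fill volume —
#'   median narrowest-EGJ cross-sectional area divided by median bag
#'   pressure, both over the final `params$egj_window_s` seconds of the
#'   60-mL step (mm^2/mmHg);
#' * `max_egj_diameter`: maximum over the 60- and 70-mL steps of the
#'   narrowest EGJ-channel diameter (mm);
#' * `pressure_60`: median bag pressure over the same 60-mL window (mmHg).
#'
#' Medians, not means, summarise each window so brief transients cannot
#' drag the estimate.  Studies missing the 60- or 70-mL step are
#' protocol-incomplete (such exams are excluded clinically) and raise an
#' error.
#'
#' @param study A [flip_study()].
#' @param params A [flip_params()].
#' @return One-row tibble with `egj_di_60`, `max_egj_diameter`,
#'   `pressure_60`.
#' @export
compute_egj_metrics <- function(study, params = flip_params()) {
  stopifnot(inherits(study, "flip_study"))
  if (!all(c(60, 70) %in% study$fill_volume)) {
    abort_panometry(
      "protocol-incomplete study: the 60- and 70-mL fill steps are required.",
      "panometry_protocol_incomplete")
  }
  dt <- study$time[2] - study$time[1]
  idx60 <- which(study$fill_volume == 60)
  n_win <- min(length(idx60), round(params$egj_window_s / dt))
  win <- idx60[(length(idx60) - n_win + 1):length(idx60)]

  narrowest <- apply(study$diameters[, study$egj_channels, drop = FALSE], 1, min)
  csa_med <- stats::median(compute_csa(narrowest[win]))
  p60 <- stats::median(study$bag_pressure[win])

  idx6070 <- which(study$fill_volume %in% c(60, 70))
  tibble::tibble(
    egj_di_60 = csa_med / p60,
    max_egj_diameter = max(narrowest[idx6070]),
    pressure_60 = p60
  )
}

#' Detect contraction events in a FLIP diameter topography
#'
#' Algorithmic realisation of the contraction criteria that human raters
#' apply to FLIP topography.  Restricted to the analysed period (fill volume
#' at or above `params$analysis_min_fill`), a sample is "contracting" when
#' its diameter falls strictly below the stricter (smaller) of 50% of the
#' per-channel rolling-median baseline and the 9-mm absolute floor.  Events
#' are maximal connected spatiotemporal regions of contracting samples
#' (8-connectivity); regions closer than `distinct_gap_s` seconds *and*
#' `distinct_gap_ch` channels are merged — only separated regions count as
#' distinct contractions.  Per event:
#'
#' * direction from the fitted slope of the band centre (mean contracting
#'   channel) against time: antegrade / retrograde when |slope| exceeds
#'   `direction_slope_cm_s`, otherwise mixed;
#' * `axial_extent` = channel span in cm (1 cm per channel);
#' * `occluding` when the minimum diameter within the event is at or below
#'   `occluding_mm`; `sustained` when the event lasts at least
#'   `sustained_s`; `at_egj` when every involved channel lies in the EGJ
#'   interval;
#' * `pressure_rise` = peak bag pressure during the event minus the median
#'   over the `pressure_baseline_s` seconds before onset.
#'
#' @param study A [flip_study()].
#' @param params A [flip_params()].
#' @return Tibble of events (possibly empty) with columns `onset_time`,
#'   `offset_time`, `channel_lo`, `channel_hi`, `axial_extent`, `direction`,
#'   `occluding`, `sustained`, `at_egj`, `pressure_rise`.
#' @export
detect_contraction_events <- function(study, params = flip_params()) {
  stopifnot(inherits(study, "flip_study"))
  thr <- contraction_threshold(study, params)
  keep <- study$fill_volume >= params$analysis_min_fill
  mask <- (study$diameters < thr) & keep

  labels <- label_components(mask)
  n_comp <- max(labels, 0)
  if (n_comp == 0) return(empty_event_table())

  groups <- merge_indistinct(labels, study$time, params)
  events <- lapply(groups, function(ids) {
    summarise_component(which(labels %in% ids), labels, study, params)
  })
  events <- dplyr::bind_rows(events)
  events[order(events$onset_time), ]
}

# internal: per-sample contraction threshold, the stricter of the relative
# and absolute criteria, from a per-channel rolling-median baseline
contraction_threshold <- function(study, params) {
  dt <- study$time[2] - study$time[1]
  k <- round(params$baseline_window_s / dt)
  if (k %% 2 == 0) k <- k + 1
  k <- min(k, length(study$time) - (1 - length(study$time) %% 2))
  baseline <- apply(study$diameters, 2, function(x) {
    if (length(x) <= 2) x else stats::runmed(x, k, endrule = "median")
  })
  pmin(params$rel_threshold * baseline, params$abs_floor_mm)
}

# internal: 8-connected component labelling of a logical matrix (rows =
# time, cols = channels) by breadth-first search over the TRUE cells
label_components <- function(mask) {
  labels <- matrix(0L, nrow(mask), ncol(mask))
  cells <- which(mask)
  if (length(cells) == 0) return(labels)
  nr <- nrow(mask)
  nc <- ncol(mask)
  current <- 0L
  for (start in cells) {
    if (labels[start] != 0L) next
    current <- current + 1L
    queue <- start
    labels[start] <- current
    while (length(queue) > 0) {
      cell <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r <- (cell - 1L) %% nr + 1L
      c <- (cell - 1L) %/% nr + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr
        cc <- c + dc
        if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
        nb <- (cc - 1L) * nr + rr
        if (mask[nb] && labels[nb] == 0L) {
          labels[nb] <- current
          queue <- c(queue, nb)
        }
      }
    }
  }
  labels
}

# internal: group component labels whose bounding boxes are separated by
# less than the distinctness gaps in both time and channel; iterated to a
# fixpoint so chains merge transitively
merge_indistinct <- function(labels, time, params) {
  ids <- sort(unique(labels[labels > 0]))
  nr <- nrow(labels)
  box <- lapply(ids, function(id) {
    cells <- which(labels == id)
    r <- (cells - 1L) %% nr + 1L
    c <- (cells - 1L) %/% nr + 1L
    list(t0 = time[min(r)], t1 = time[max(r)], c0 = min(c), c1 = max(c))
  })
  group <- seq_along(ids)
  repeat {
    changed <- FALSE
    for (i in seq_along(ids)) for (j in seq_along(ids)) {
      if (group[i] == group[j]) next
      bi <- box[[i]]
      bj <- box[[j]]
      tgap <- max(bi$t0, bj$t0) - min(bi$t1, bj$t1)
      cgap <- max(bi$c0, bj$c0) - min(bi$c1, bj$c1) - 1L
      if (tgap < params$distinct_gap_s && cgap < params$distinct_gap_ch) {
        group[group == group[j]] <- group[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  lapply(unique(group), function(g) ids[group == g])
}

# internal: event summary for one (possibly merged) component
summarise_component <- function(cells, labels, study, params) {
  nr <- nrow(labels)
  r <- (cells - 1L) %% nr + 1L
  c <- (cells - 1L) %/% nr + 1L
  onset <- study$time[min(r)]
  offset <- study$time[max(r)]

  # ridge: mean contracting channel per time slice, slope in cm/s
  centre <- tapply(c, r, mean)
  tt <- study$time[as.integer(names(centre))]
  slope <- if (length(tt) > 1) {
    stats::coef(stats::lm(centre ~ tt))[["tt"]]
  } else 0
  direction <- if (slope >= params$direction_slope_cm_s) "antegrade"
    else if (slope <= -params$direction_slope_cm_s) "retrograde"
    else "mixed"

  pre <- which(study$time >= onset - params$pressure_baseline_s & study$time < onset)
  if (length(pre) == 0) pre <- which(study$time == onset)
  p_base <- stats::median(study$bag_pressure[pre])
  in_ev <- which(study$time >= onset & study$time <= offset)

  tibble::tibble(
    onset_time = onset, offset_time = offset,
    channel_lo = min(c), channel_hi = max(c),
    axial_extent = as.numeric(max(c) - min(c) + 1),
    direction = direction,
    occluding = min(study$diameters[cells]) <= params$occluding_mm,
    sustained = (offset - onset) >= params$sustained_s,
    at_egj = all(c %in% study$egj_channels),
    pressure_rise = max(study$bag_pressure[in_ev]) - p_base
  )
}

#' Extract classification metrics from a FLIP study
#'
#' Aggregates [detect_contraction_events()] (within the analysed 50-70 mL
#' period) and [compute_egj_metrics()] into the per-study metric row the
#' classifiers consume:
#'
#' * `n_qualifying_antegrade`: distinct antegrade contractions of axial
#'   extent at least `min_extent_cm` with pressure rise above
#'   `min_pressure_rise`, outside the EGJ;
#' * `any_contractility`: any esophageal-body contraction detected;
#' * `sustained_occluding` / `sustained_les`: the spastic features;
#' * `rac_pattern`: descriptive flag for a repetitive (3+) antegrade
#'   contraction train — never alters classification;
#' * the EGJ metrics `egj_di_60`, `max_egj_diameter`, `pressure_60`.
#'
#' @param study A [flip_study()].
#' @param params A [flip_params()].
#' @return One-row tibble of metrics.
#' @export
extract_metrics <- function(study, params = flip_params()) {
  events <- detect_contraction_events(study, params)
  egj <- compute_egj_metrics(study, params)
  body <- events[!events$at_egj, ]
  qualifying <- body$direction == "antegrade" &
    body$axial_extent >= params$min_extent_cm &
    body$pressure_rise > params$min_pressure_rise
  tibble::tibble(
    egj_di_60 = egj$egj_di_60,
    max_egj_diameter = egj$max_egj_diameter,
    pressure_60 = egj$pressure_60,
    n_qualifying_antegrade = sum(qualifying),
    any_contractility = nrow(body) > 0,
    sustained_occluding = any(body$occluding & body$sustained),
    sustained_les = any(events$at_egj & events$sustained),
    rac_pattern = sum(qualifying) >= 3
  )
}
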