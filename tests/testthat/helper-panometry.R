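# shared helpers for the panometry test suite

# a one-row metrics tibble with overridable fields
make_metrics <- function(...) {
  defaults <- tibble::tibble(
    egj_di_60 = 4, max_egj_diameter = 18, pressure_60 = 35,
    n_qualifying_antegrade = 0L, any_contractility = FALSE,
    sustained_occluding = FALSE, sustained_les = FALSE, rac_pattern = FALSE
  )
  dots <- list(...)
  for (nm in names(dots)) defaults[[nm]] <- dots[[nm]]
  defaults
}

# a minimal hand-built study: constant diameters per channel group, 4 fill
# steps of `dwell` seconds at `fs` Hz — independent of the simulator
make_flat_study <- function(egj_diameter = 16, body_diameter = 16,
                            pressure = 50, dwell = 30, fs = 2,
                            volumes = c(40, 50, 60, 70)) {
  n <- dwell * fs * length(volumes)
  d <- matrix(body_diameter, n, 16)
  d[, 13:15] <- egj_diameter
  flip_study(
    time = (seq_len(n) - 1) / fs,
    fill_volume = rep(volumes, each = dwell * fs),
    bag_pressure = rep(pressure, n),
    diameters = d,
    egj_channels = 13:15
  )
}

# naive fixpoint label-propagation connected components (8-connectivity);
# the independent oracle for the detector's BFS labelling
naive_label_components <- function(mask) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  lab[mask] <- seq_len(sum(mask))
  repeat {
    changed <- FALSE
    for (r in seq_len(nr)) for (c in seq_len(nc)) {
      if (!mask[r, c]) next
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr
        cc <- c + dc
        if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
        if (mask[rr, cc] && lab[rr, cc] < lab[r, c]) {
          lab[r, c] <- lab[rr, cc]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  lab
}

# partition of TRUE cells induced by a labelling, order-independent
component_partition <- function(lab) {
  cells <- which(lab > 0)
  unname(lapply(split(cells, lab[cells]), sort))
}

# simulator phenotype code -> classifier pattern code
sim_cr_to_pattern <- c(normal = "NORMAL", diminished = "DIMINISHED",
                       disordered = "DISORDERED", absent = "ABSENT",
                       spastic = "SPASTIC")
sim_egjo_to_class <- c(normal = "NORMAL", inconclusive = "INCONCLUSIVE",
                       reduced = "REDUCED")
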