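test_that("absent phenotype with zero noise is exactly the smooth baseline", {
  study <- simulate_topography(topography_spec("absent", "normal"))
  expect_identical(study$diameters, study$baseline)
  expect_equal(nrow(study$events), 0)
})

test_that("identical spec and seed give bit-identical studies", {
  spec <- topography_spec("normal", "inconclusive", noise_sd = 0.5, seed = 42)
  a <- simulate_topography(spec)
  b <- simulate_topography(spec)
  expect_identical(a$diameters, b$diameters)
  expect_identical(a$bag_pressure, b$bag_pressure)
  expect_identical(a$events, b$events)
})

test_that("generated studies satisfy every protocol invariant", {
  for (cr in c("normal", "diminished", "disordered", "absent", "spastic")) {
    for (eg in c("normal", "inconclusive", "reduced")) {
      study <- simulate_topography(topography_spec(cr, eg))
      expect_silent(validate_flip_study(study))
      expect_true(all(study$diameters > 0))
      expect_true(all(diff(study$fill_volume) >= 0))
      expect_identical(ncol(study$diameters), 16L)
    }
  }
})

test_that("the detector recovers injected bands: count, direction, extent", {
  study <- simulate_topography(
    topography_spec("normal", "normal", n_contractions = 3,
                    contraction_extent_cm = 8))
  events <- detect_contraction_events(study)
  expect_equal(nrow(events), 3)
  expect_true(all(events$direction == "antegrade"))
  expect_true(all(abs(events$axial_extent - 8) <= 0.5))

  retro <- simulate_topography(topography_spec("disordered", "normal"))
  rev <- detect_contraction_events(retro)
  expect_equal(nrow(rev), 2)
  expect_true(all(rev$direction == "retrograde"))
  expect_true(all(abs(rev$axial_extent - 7) <= 0.5))
})

test_that("ground truth and detection agree for every phenotype (round trip)", {
  for (cr in c("normal", "diminished", "disordered", "absent", "spastic")) {
    study <- simulate_topography(topography_spec(cr, "normal"))
    events <- detect_contraction_events(study)
    truth <- study$events
    expect_equal(nrow(events), nrow(truth), info = cr)
    if (nrow(truth) > 0) {
      expect_equal(sort(events$direction), sort(truth$direction), info = cr)
      expect_true(all(abs(sort(events$axial_extent) - sort(truth$axial_extent)) <= 0.5),
                  info = cr)
    }
  }
})

test_that("sustained occluding and LES bands carry the spastic flags", {
  occ <- simulate_topography(topography_spec("spastic", "reduced"))
  ev <- detect_contraction_events(occ)
  expect_equal(nrow(ev), 1)
  expect_true(ev$occluding && ev$sustained && !ev$at_egj)

  les <- simulate_topography(topography_spec("spastic", "reduced",
                                             spastic_type = "les"))
  ev <- detect_contraction_events(les)
  expect_equal(nrow(ev), 1)
  expect_true(ev$sustained && ev$at_egj)
})

test_that("contradictory specs are rejected with a contradiction message", {
  expect_error(topography_spec("absent", "normal", n_contractions = 2),
               class = "panometry_contradictory_spec")
  expect_error(topography_spec("normal", "normal", n_contractions = 1),
               class = "panometry_contradictory_spec")
  expect_error(topography_spec("diminished", "normal", pressure_60 = 55),
               class = "panometry_contradictory_spec")
  expect_error(topography_spec("disordered", "normal", pressure_60 = 30),
               class = "panometry_contradictory_spec")
  # implied 60-mL EGJ diameter exceeding the requested maximum
  expect_error(topography_spec("normal", "normal", egj_di_60 = 8,
                               max_egj_diameter = 12),
               class = "panometry_contradictory_spec")
  expect_error(topography_spec("normal", "normal", noise_sd = -1),
               class = "panometry_invalid_argument")
})

test_that("add_noise is a no-op at zero, deterministic per seed, calibrated", {
  study <- simulate_topography(topography_spec("absent", "normal"))
  expect_identical(add_noise(study, 0), study)
  a <- add_noise(study, 0.5, seed = 7)
  b <- add_noise(study, 0.5, seed = 7)
  expect_identical(a$diameters, b$diameters)
  expect_gt(sum(abs(a$diameters - study$diameters)), 0)

  # sample-moment check on >= 1e4 samples, far from the positivity floor
  eps <- a$diameters - study$diameters
  expect_gte(length(eps), 1e4)
  expect_true(stats::sd(eps) >= 0.4 && stats::sd(eps) <= 0.6)
  expect_lt(abs(mean(eps)), 0.05)
  expect_error(add_noise(study, -0.1), class = "panometry_invalid_argument")
})

test_that("noise never drives a diameter non-positive", {
  study <- simulate_topography(topography_spec("spastic", "reduced",
                                               noise_sd = 1.5, seed = 3))
  expect_true(all(study$diameters > 0))
})

test_that("a study round-trips through the text format", {
  study <- simulate_topography(topography_spec("normal", "reduced"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_flip_study(study, path)
  back <- read_flip_study(path)
  expect_equal(back$diameters, study$diameters, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(back$bag_pressure, study$bag_pressure, tolerance = 1e-9)
  expect_equal(back$fill_volume, study$fill_volume)
  expect_equal(back$egj_channels, study$egj_channels)
  expect_equal(nrow(back$events), nrow(study$events))
})
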