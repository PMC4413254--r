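test_that("the 14 dB channel gate is strict", {
  noise <- rep(100, 6)
  expect_true(1L %in% select_channels(c(120, rep(118, 5)), noise))
  # 13.9 dB over noise is dropped
  keep <- select_channels(c(113.9, rep(118, 5)), noise)
  expect_false(1L %in% keep)
  # fewer than 5 retained channels refuses the fit
  expect_error(select_channels(c(120, 120, 100, 100, 100), rep(100, 5)),
               "refused")
  # noise-free simulation keeps all channels
  s <- star_click_energies("small", 1)
  expect_equal(length(select_channels(s$prop$efd_db, rep(-Inf, 37))), 37L)
})

test_that("energy-surface axis lands within one cell of the aim", {
  src <- piston_source()
  for (aim in list(c(0, 0), c(0.03, -0.02))) {
    s <- star_click_energies("small", 1, axis_xz = aim)
    surf <- fit_energy_surface(s$prop$efd_db,
                               s$geometry$positions[, c(1, 3)], 1,
                               source_position = s$position)
    expect_lt(sqrt(sum((surf$axis_xz - aim)^2)), 0.005 + 1e-9)
    expect_false(surf$boundary_flag)
    # axis on the 0.5 cm grid
    expect_equal(surf$axis_xz, round(surf$axis_xz / 0.005) * 0.005,
                 tolerance = 1e-9)
  }
  expect_error(fit_energy_surface(rep(NA_real_, 37),
                                  build_star_array("small")$positions[, c(1, 3)],
                                  1), "gated")
})

test_that("piston self-fit is exact for on-grid diameters", {
  src <- piston_source()
  sp <- source_spectrum(src)
  for (d in c(0.0417, 0.0837, 0.1197)) {  # candidate-grid diameters
    s <- star_click_energies("small", 1, diameter = d)
    fit <- fit_piston_star(s$prop$efd_db, s$geometry$positions,
                           s$position, c(0, 0), spectrum = sp)
    expect_equal(fit$best_diameter, d, tolerance = 1e-9)
    expect_lt(fit$lse, 1e-10)
    expect_equal(fit$r_squared, 1, tolerance = 1e-9)
    expect_true(fit$included)
    # spread contains the best-fit beamwidth
    expect_lte(fit$spread_deg[1], fit$beamwidth_deg)
    expect_gte(fit$spread_deg[2], fit$beamwidth_deg)
  }
})

test_that("off-grid diameters are recovered to the 0.1 cm grid step", {
  src <- piston_source()
  sp <- source_spectrum(src)
  s <- star_click_energies("large", 2, axis_xz = c(0.04, 0.02),
                           diameter = 0.083)
  gate <- s$prop$efd_db >= max(s$prop$efd_db) - 16
  surf <- fit_energy_surface(ifelse(gate, s$prop$efd_db, NA),
                             s$geometry$positions[, c(1, 3)], 2,
                             source_position = s$position)
  fit <- fit_piston_star(s$prop$efd_db[gate],
                         s$geometry$positions[gate, ], s$position,
                         surf$axis_xz, spectrum = sp)
  expect_lt(abs(fit$best_diameter - 0.083), 0.001)
  expect_gt(fit$r_squared, 0.999)
})

test_that("R^2 gate and flat-curve flag set exclusion reasons", {
  src <- piston_source()
  sp <- source_spectrum(src)
  s <- star_click_energies("small", 1)
  set.seed(7)
  noisy <- s$prop$efd_db + rnorm(length(s$prop$efd_db), 0, 12)
  fit <- fit_piston_star(noisy, s$geometry$positions, s$position,
                         c(0, 0), spectrum = sp)
  if (fit$r_squared <= 0.8) {
    expect_false(fit$included)
    expect_match(fit$reason, "R\\^2")
  }
  expect_lt(fit$r_squared, 0.9)  # heavy noise degrades the fit
})

test_that("R^2 degrades monotonically with noise in expectation", {
  src <- piston_source()
  sp <- source_spectrum(src)
  s <- star_click_energies("small", 1)
  mean_r2 <- vapply(c(0.1, 1, 4), function(sd) {
    mean(vapply(1:8, function(seed) {
      set.seed(seed)
      e <- s$prop$efd_db + rnorm(length(s$prop$efd_db), 0, sd)
      fit_piston_star(e, s$geometry$positions, s$position, c(0, 0),
                      spectrum = sp)$r_squared
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_r2) < 0))
})

test_that("inclusion criteria apply the printed bounds", {
  # bearing beyond +/-15 degrees excludes
  r <- apply_inclusion_criteria(c(0, 0), azimuth = 16, elevation = 0,
                                config = "small", phase = "buzz")
  expect_false(r$included)
  # large array: 11 cm displacement is inside the 12 cm bound
  r2 <- apply_inclusion_criteria(c(0.11, 0), 0, 0, "large", "pre_buzz")
  expect_true(r2$included)
  r2b <- apply_inclusion_criteria(c(0.125, 0), 0, 0, "large", "pre_buzz")
  expect_false(r2b$included)
  # small array in-buzz: 7 cm displacement is beyond the 6 cm bound
  r3 <- apply_inclusion_criteria(c(0.07, 0), 0, 0, "small", "buzz")
  expect_false(r3$included)
  r4 <- apply_inclusion_criteria(c(0.07, 0), 0, 0, "small", "pre_buzz")
  expect_true(r4$included)
  # missing phase: conservative 6 cm bound
  r5 <- apply_inclusion_criteria(c(0.07, 0), 0, 0, "small", NA)
  expect_false(r5$included)
})

test_that("linear and star methods agree on the same source", {
  src <- piston_source()
  sp <- source_spectrum(src)
  # same piston observed by both experiments
  trial <- make_linear_trial(position = c(0.3, 3, 0), aim = c(0, 0, 0))
  m <- measure_trial_clicks(trial)
  fix <- localize_source(
    tdoa_estimate(m$peak_times[1, ], which.max(m$efd_db[1, ])),
    trial$geometry)
  rng <- sqrt(rowSums(sweep(trial$geometry$positions, 2,
                            fix$position)^2))
  pat <- build_radiation_pattern(
    apparent_source_level(m$efd_db[1, ], rng), fix, trial$geometry)
  fit_lin <- fit_piston_to_pattern(pat, spectrum = sp)
  s <- star_click_energies("large", 2)
  surf <- fit_energy_surface(s$prop$efd_db,
                             s$geometry$positions[, c(1, 3)], 2,
                             source_position = s$position)
  fit_star <- fit_piston_star(s$prop$efd_db, s$geometry$positions,
                              s$position, surf$axis_xz, spectrum = sp)
  ear <- max(effective_angular_resolution(0.6, 3),
             effective_angular_resolution(0.05, 2))
  expect_lt(abs(fit_lin$beamwidth_deg - fit_star$beamwidth_deg), ear)
})
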