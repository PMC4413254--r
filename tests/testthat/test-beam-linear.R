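test_that("apparent source level back-corrects spherical spreading", {
  expect_equal(apparent_source_level(120, 3), 129.54, tolerance = 1e-2)
  expect_equal(apparent_source_level(114, 2), 120.02, tolerance = 1e-2)
  expect_equal(apparent_source_level(137, 1), 137)
  expect_error(apparent_source_level(120, 0))
  # mutual inverse of the forward propagation (noise-free channels)
  src <- piston_source()
  geom <- build_linear_array()
  prop <- propagate_click(src, c(0, 3, 0), c(0, -1, 0), geom)
  asl <- apparent_source_level(prop$efd_db, prop$range_m)
  spec <- source_piston_spec(src)
  expect_equal(asl, src$source_level +
                 10 * log10(piston_directivity(spec, prop$theta_deg)),
               tolerance = 1e-6)
})

test_that("radiation-pattern vertex follows the Lagrange parabola", {
  geom <- build_linear_array()
  fix <- c(0, 3, 0)
  # symmetric neighbours: vertex at the peak hydrophone, unchanged level
  asl <- c(80, 85, 92, 95, 92, 85, 80, 70)
  pat <- build_radiation_pattern(asl, fix, geom)
  # hydrophones 4 and 5 straddle the axis symmetrically; peak is at 4
  expect_lt(abs(pat$peak_asl - 95), 0.6)
  # the printed three-point example: (-2, 0, -4) dB at (-5, 0, 5) deg
  v <- sonarbeam:::parabola_vertex(c(-5, 0, 5), c(-2, 0, -4))
  expect_equal(v[1], -0.8333, tolerance = 1e-3)
  expect_equal(v[2], 0.0833, tolerance = 1e-3)
  # peak on an outermost hydrophone rejects the click
  asl_edge <- seq(70, 98, by = 4)
  expect_error(build_radiation_pattern(asl_edge, fix, geom),
               "outermost")
  # 0.1 degree grid
  expect_equal(diff(pat$angles)[1], 0.1, tolerance = 1e-9)
})

test_that("noise-free vertex lands within 0.2 deg of the true axis", {
  src <- piston_source()
  trial <- make_linear_trial(position = c(0.3, 3, 0), aim = c(0, 0, 0))
  m <- measure_trial_clicks(trial)
  fix <- localize_source(
    tdoa_estimate(m$peak_times[1, ], which.max(m$efd_db[1, ])),
    trial$geometry)
  rng <- sqrt(rowSums(sweep(trial$geometry$positions, 2,
                            fix$position)^2))
  asl <- apparent_source_level(m$efd_db[1, ], rng)
  pat <- build_radiation_pattern(asl, fix, trial$geometry)
  # the source aims at the array centre: vertex at 0 off-centre
  expect_lt(abs(pat$peak_angle), 0.2)
})

test_that("piston fit recovers the generating diameter", {
  src <- piston_source()
  spec <- source_piston_spec(src)
  # pattern generated directly from D(theta): self-fit is exact
  th <- seq(-12, 12, by = 0.1)
  asl <- 140 + 10 * log10(piston_directivity(spec, th))
  pat <- structure(list(angles = th, asl = asl, peak_angle = 0,
                        peak_asl = 140, raw = NULL),
                   class = "radiation_pattern")
  fit <- fit_piston_to_pattern(pat, spectrum = source_spectrum(src))
  expect_equal(fit$best_diameter, 0.0827, tolerance = 1e-9)  # grid cell
  expect_gt(fit$r_squared, 0.999)
  # full chain, d = 8.3 cm at 3 m: within the EAR at that range
  trial <- make_linear_trial(position = c(0.3, 3, 0), aim = c(0, 0, 0))
  m <- measure_trial_clicks(trial)
  fix <- localize_source(
    tdoa_estimate(m$peak_times[1, ], which.max(m$efd_db[1, ])),
    trial$geometry)
  rng <- sqrt(rowSums(sweep(trial$geometry$positions, 2,
                            fix$position)^2))
  pat2 <- build_radiation_pattern(
    apparent_source_level(m$efd_db[1, ], rng), fix, trial$geometry)
  fit2 <- fit_piston_to_pattern(pat2, spectrum = source_spectrum(src))
  ear <- effective_angular_resolution(0.6, 3)
  expect_lt(abs(fit2$beamwidth_deg - 8.2), ear)
  expect_equal(fit2$best_diameter, 0.083, tolerance = 0.002 / 0.083)
  # widened source (d = 4.15 cm) at 1 m: 16.5 +/- 1 deg.  At 1 m the
  # hydrophone spacing subtends ~31 deg, so the vertex refinement only
  # resolves the axis for a symmetric approach down the array normal.
  trial3 <- make_linear_trial(position = c(0, 1, 0), aim = c(0, 0, 0),
                              diameter = 0.0415)
  m3 <- measure_trial_clicks(trial3)
  fix3 <- localize_source(
    tdoa_estimate(m3$peak_times[1, ], which.max(m3$efd_db[1, ])),
    trial3$geometry)
  rng3 <- sqrt(rowSums(sweep(trial3$geometry$positions, 2,
                             fix3$position)^2))
  pat3 <- build_radiation_pattern(
    apparent_source_level(m3$efd_db[1, ], rng3), fix3, trial3$geometry)
  fit3 <- fit_piston_to_pattern(pat3, spectrum = source_spectrum(src))
  expect_equal(fit3$beamwidth_deg, 16.45, tolerance = 1 / 16.45)
})
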