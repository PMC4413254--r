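test_that("click waveform has the contracted energy, centroid and span", {
  src <- piston_source(source_level = 140, click_centroid = 130e3,
                       click_duration = 80e-6)
  w <- synth_click_waveform(src, 500e3)
  # energy flux density equals the source level (uPa^2 s at 1 m)
  expect_equal(10 * log10(sum(w$waveform^2) / w$fs), 140,
               tolerance = 0.02)
  # spectral centroid within 1 kHz of fc
  expect_equal(centroid_frequency(w$waveform, w$fs), 130e3,
               tolerance = 1e3 / 130e3)
  # >= 99% of energy inside the 120 us analysis window
  i0 <- w$centre_index - round(30e-6 * w$fs)
  i1 <- w$centre_index + round(90e-6 * w$fs) - 1L
  expect_gt(sum(w$waveform[i0:i1]^2) / sum(w$waveform^2), 0.99)
  # Parseval: time-domain energy equals spectral energy
  X <- fft(w$waveform)
  expect_equal(sum(w$waveform^2), sum(Mod(X)^2) / length(X))
  expect_error(synth_click_waveform(src, 200e3), "aliasing|too low")
})

test_that("schedule_approach produces the contracted click trains", {
  src <- piston_source()
  tr <- schedule_approach(7, 2, speed = 1,
                          ici_profile = function(r) 0.05, source = src)
  expect_equal(nrow(tr), 100L)
  # buzz switch: clicks inside the buzz region have ICI <= 13 ms (the
  # single click straddling the switch carries the last regular
  # interval)
  tr2 <- schedule_approach(4, 0.5, speed = 2, buzz_switch_range = 2,
                           source = src)
  icis <- tr2$ici[-1]
  ranges <- tr2$range[-1]
  expect_true(all(icis[ranges <= 2 - 2 * 0.041] <= 0.013))
  expect_true(all(icis[ranges > 2.1] > 0.013))
  # constant beamwidth profile gives a constant diameter
  tr3 <- schedule_approach(5, 3, speed = 1,
                           ici_profile = function(r) 0.1,
                           beamwidth_profile = function(r) rep(9.1,
                                                               length(r)),
                           source = src)
  expect_equal(length(unique(tr3$diameter)), 1L)
  expect_equal(piston_beamwidth(piston_spec(tr3$diameter[1], 130e3)),
               9.1, tolerance = 1e-4)
  expect_error(schedule_approach(2, 3))
})

test_that("propagation follows spherical spreading and directivity", {
  src <- piston_source(source_level = 140)
  geom <- array_geometry(rbind(c(0, 0, 0), c(0.6, 0, 0)), c(0, 3, 0),
                         "linear")
  on_axis <- propagate_click(src, c(0, 1, 0), c(0, -1, 0), geom)
  expect_equal(on_axis$efd_db[1], 140, tolerance = 1e-6)
  at2 <- propagate_click(src, c(0, 2, 0), c(0, -1, 0), geom)
  expect_equal(at2$efd_db[1], 140 - 6.02, tolerance = 1e-2)
  # a channel at the -3 dB angle sits 3 dB below an equal-range on-axis one
  spec <- source_piston_spec(src)
  half <- piston_beamwidth(spec) / 2
  r <- 2
  geom2 <- array_geometry(rbind(c(0, 0, 0),
                                c(r * sin(half * pi / 180),
                                  r - r * cos(half * pi / 180), 0)),
                          c(0, 3, 0), "linear")
  p <- propagate_click(src, c(0, r, 0), c(0, -1, 0), geom2)
  expect_equal(p$efd_db[1] - p$efd_db[2], 3, tolerance = 0.02)
  # received ordering matches directivity ordering at equal range
  expect_true(all(diff(order(p$theta_deg)) ==
                    diff(order(-p$efd_db + 20 * log10(p$range_m)))))
  expect_error(propagate_click(src, c(0, 0.01, 0), c(0, -1, 0), geom))
})

test_that("trial rendering is deterministic and exact without noise", {
  t1 <- make_linear_trial(noise_level = 70, seed = 5)
  t2 <- make_linear_trial(noise_level = 70, seed = 5)
  expect_identical(t1$audio, t2$audio)
  t3 <- make_linear_trial(noise_level = 70, seed = 6)
  expect_false(identical(t3$audio, t1$audio))
  # noise-free received energy matches the propagation model to 0.1 dB
  t0 <- make_linear_trial(noise_level = -Inf)
  m <- measure_trial_clicks(t0)
  prop <- propagate_click(t0$source, c(0.3, 3, 0), c(-0.3, -3, 0),
                          t0$geometry)
  expect_equal(as.numeric(m$efd_db[1, ]), prop$efd_db, tolerance = 0.012)
})

test_that("channel sensitivity offsets are applied and corrected", {
  src <- piston_source()
  geom <- build_linear_array()
  geom$sensitivity <- seq(-1.4, 1.4, by = 0.4)
  track <- data.frame(time = 0, x = 0, y = 3, z = 0, ox = 0, oy = -1,
                      oz = 0, diameter = 0.083, ici = NA_real_)
  trial <- synthesize_trial(geom, track, src, noise_level = -Inf)
  m <- measure_trial_clicks(trial)
  geom0 <- build_linear_array()
  trial0 <- synthesize_trial(geom0, track, src, noise_level = -Inf)
  m0 <- measure_trial_clicks(trial0)
  # click_energy subtracts the offset the channel applied
  expect_equal(as.numeric(m$efd_db[1, ]), as.numeric(m0$efd_db[1, ]),
               tolerance = 1e-6)
})
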