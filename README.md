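# sonarbeam

Estimation of toothed-whale biosonar transmission beams from
multichannel hydrophone-array recordings, with a synthetic-data
generator that supplies ground truth for every estimate.

## The scientific problem

An echolocating porpoise interrogates its surroundings with short
(~100 µs), high-frequency (~130 kHz) clicks whose radiated energy is
concentrated in a narrow forward beam.  The −3 dB beamwidth of that
beam sets the animal's acoustic field of view; whether and how much
the animal can widen the beam during the terminal buzz of a prey
capture (inter-click intervals ≤ 13 ms) is measured by recording
clicks on arrays of calibrated hydrophones and fitting an aperture
model to the received energies.  `sonarbeam` is for bioacousticians
who want that entire measurement chain — click detection and
energetics, localization, two independent beam-estimation methods,
the virtual-source simulations that validate them, and the
field-of-view statistics — as tested, scriptable R.

## The model

All beam quantities derive from the circular piston of diameter `d`
(radius `a = d/2`) in an infinite baffle.  At wavenumber `k = 2πf/c`
(water, `c` = 1500 m/s) the off-axis energy ratio is

    D(θ) = [ 2 J1(k a sin θ) / (k a sin θ) ]²

Broadband clicks use the energy-weighted average of `D` over the
click spectrum.  The full −3 dB beamwidth solves `D(θ/2) = 1/2`; the
directivity index is `10·log10(4π / ∫ D dΩ)` over the front
hemisphere.  Two estimation routes are implemented:

* **linear array** — apparent source levels (`ASL = EFD +
  20·log10 r`) against hydrophone angle, peak refined by Lagrange
  (parabolic) interpolation, piston fitted to the 1-D pattern;
* **star array** — per-channel click energies gated at 14 dB over
  channel noise, an energy surface gridded at 0.5 cm over the ±20°
  disc whose peak is the beam axis, then a Monte-Carlo piston fit
  over candidate diameters 2.77–24.9 cm (0.1 cm steps) anchored to
  the axis-nearest hydrophone, kept only when R² > 0.8.

## Worked example

Simulate one click of an 8.3 cm piston source 2 m in front of the
large star array, aimed 4 cm right and 2 cm above the array centre,
then run the full star-array chain:

```r
library(sonarbeam)

src  <- piston_source(diameter = 0.083)        # 130 kHz, 80 us pip
geom <- build_star_array("large")
pos  <- c(0, 2, 0)                             # 2 m on the normal
aim  <- c(0.04, 0, 0.02) - pos
prop <- propagate_click(src, pos, aim, geom)

surf <- fit_energy_surface(prop$efd_db, geom$positions[, c(1, 3)],
                           range = 2, source_position = pos)
fit  <- fit_piston_star(prop$efd_db, geom$positions, pos,
                        surf$axis_xz, spectrum = source_spectrum(src))
surf$axis_xz
#> [1] 0.040 0.020
fit
#> <piston_fit (star): d = 8.3 cm, -3 dB beamwidth = 8.23 deg, R^2 = 1.000>
fit$spread_deg
#> [1] 7.425233 8.880038
```

The estimated axis lands on the aim point to the 0.5 cm grid; the
recovered aperture is the true 8.3 cm (nearest 0.1 cm candidate), its
broadband −3 dB beamwidth is 8.23°, and the spread interval collects
every candidate inside the lowest 5% of the error-curve extent.
`run_error_simulation()` repeats this over a grid of diameters,
bearings, axis displacements and ranges with noise, and
`summarize_error_surface()` reports the error bounds inside the
inclusion region (bearing within ±15° per axis; axis displacement
within ±12 cm large array, ±8 cm small pre-buzz, ±6 cm in buzz):
beamwidth error ≤ ±0.5° and axis error ≤ ±1.5 cm.

## Package tour

| module | entry points |
|---|---|
| geometry | `build_linear_array`, `build_star_array`, `effective_angular_resolution`, geometry JSON I/O |
| beam model | `piston_spec`, `piston_directivity`, `piston_beamwidth`, `directivity_index`, `inverse_beamwidth` |
| simulator | `piston_source`, `synth_click_waveform`, `schedule_approach`, `propagate_click`, `synthesize_trial`, `write_trial` |
| click processing | `detect_clicks`, `click_energy`, `snr_gate`, `centroid_frequency`, `ici_and_buzz`, `measure_trial_clicks` |
| localization | `tdoa_estimate`, `localize_source`, `bearing_to_centre`, `emission_time` |
| linear-array method | `apparent_source_level`, `build_radiation_pattern`, `fit_piston_to_pattern` |
| star-array method | `select_channels`, `fit_energy_surface`, `fit_piston_star`, `apply_inclusion_criteria` |
| validation | `run_error_simulation`, `derive_inclusion_mask`, `summarize_error_surface` |
| tag echograms | `build_echogram`, `delay_to_range`, `raol_series`, `echogram_ridge` |
| field-of-view statistics | `ensonified_area`, `area_ratio_series`, `detection_range`, `beamwidth_range_regression`, `cluster_anova` |

The methods vignette (`vignettes/beam-estimation-methods.Rmd`)
documents the model assumptions, the synthetic world and its limits,
the numerical design of the surface fitter, and known limitations.
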