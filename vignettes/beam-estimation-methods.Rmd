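---
title: "Estimating biosonar beam patterns from hydrophone arrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating biosonar beam patterns from hydrophone arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sonarbeam)
```

## The problem

Echolocating toothed whales emit short, directional ultrasonic clicks
and listen for echoes.  The width of the emitted beam sets the
animal's acoustic field of view: a narrow beam concentrates energy and
extends detection range, a wide beam covers more of the scene at close
quarters.  `sonarbeam` implements a complete, testable pipeline for
measuring the transmission beam of a clicking source from multichannel
hydrophone-array recordings, together with a synthetic-data generator
that provides ground truth for every estimate.  The motivating use
case is the harbour porpoise (*Phocoena phocoena*), whose clicks
centre near 130 kHz and last on the order of 100 microseconds, and the
question of whether the beam widens during the terminal buzz of prey
capture (inter-click intervals at or below 13 ms).

## The beam model

All beam quantities derive from the classical circular piston in an
infinite baffle.  A piston of diameter $d$ (radius $a = d/2$) driven
at frequency $f$ in water of sound speed $c = 1500$ m/s radiates with
an energy directivity

$$D(\theta) = \left[\frac{2 J_1(ka\sin\theta)}{ka\sin\theta}\right]^2,
\qquad k = \frac{2\pi f}{c},$$

with $D(0) = 1$ by continuity.  Clicks are broadband, so the package
also defines a broadband directivity as the energy-weighted average of
the narrowband ratio over the click's energy spectrum; fitting and
simulation use the same definition, which keeps the two
self-consistent.  The full $-3$ dB beamwidth is twice the angle at
which $D$ drops to one half ($ka\sin\theta_{1/2} \approx 1.616$), the
directivity index is $10\log_{10}(4\pi/\int D\,d\Omega)$ over the
front hemisphere (back radiation set to zero), and `inverse_beamwidth()`
maps a requested beamwidth back to an aperture.  For the default
porpoise-like source ($d = 8.3$ cm, $f_c = 130$ kHz, $ka \approx
22.6$) the beamwidth is $8.20^\circ$ and the directivity index 27.1 dB.

```{r}
spec <- piston_spec(0.083, 130e3)
c(beamwidth = piston_beamwidth(spec), di = directivity_index(spec))
```

## What the simulator emulates — and what it does not

`synthesize_trial()` renders a moving piston source executing a target
approach onto any of three array geometries: the 8-hydrophone linear
array (0.6 m spacing, target 3 m away) and the 48-unit star arrays in
their large (arms to 1.05–1.13 m) and small (arms to 0.55 m, target at
0.4 m) configurations.  The click is a Gaussian-enveloped 130 kHz tone
pip with an 80 microsecond $-20$ dB envelope; real porpoise clicks
have more phase structure and an amplitude-dependent spectrum, but any
transient with a porpoise-like spectrum suffices to validate the
estimation chain, which only consumes windowed energies and arrival
times.  Propagation is spherical spreading plus broadband piston
directivity applied as a scalar energy factor; frequency-dependent
absorption is omitted (under 0.5 dB at 130 kHz for the at most 7 m
ranges simulated) and off-axis spectral distortion is not modelled.
Noise is band-limited (2–200 kHz) white Gaussian noise set by its
energy in the 120 microsecond analysis window.  Sub-sample delays are
exact because each channel evaluates the analytic pip at its own
arrival time.  A green test on this world therefore establishes that
the estimation chain is correct for a rotationally symmetric piston
source under additive Gaussian noise; it cannot establish robustness
to multipath, overlapping animals, or non-piston beam shapes, which
the generator deliberately does not produce.

Printed-value defaults: sampling rate 500 kHz per channel; the energy
window runs from 30 microseconds before to 90 after the envelope peak
(60 samples, half-open); buzz clicks are those with ICI at or below
13 ms; the linear-array SNR gate is 6 dB on all channels jointly
against the immediately preceding noise window; the star-array gate
keeps channels whose peak level exceeds the channel rms noise by
14 dB; surfaces are gridded at 0.5 cm over the disc subtending
$\pm20^\circ$ at the emission range; candidate apertures run from one
third to three times 8.3 cm in 0.1 cm steps; fits with $R^2 \le 0.8$
are excluded.  Where the source papers state no value, the defaults
are: source level 140 dB re 1 uPa^2 s at 1 m (a moderate porpoise
click), regular-phase ICI 40 ms and buzz ICI 3 ms, approach speed
1 m/s, and a centre-channel SNR of about 30 dB in the validation
simulations.

## The two estimation methods

**Linear array.**  Clicks are detected on a Hilbert envelope
(100–200 kHz band, 1 ms dead time), localized by arrival-time
differences (nonlinear least squares on range differences, source
constrained to the array's horizontal plane and the front half-space,
initialized at the target), and each channel's energy is
back-propagated to an apparent source level, ASL = EFD +
$20\log_{10} r$.  The peak of the ASL-versus-angle pattern is refined
by a parabola through the peak hydrophone and its two neighbours
(second-order Lagrange interpolation in angle–dB space), the pattern
is resampled to $0.1^\circ$ for the radiation-plot product, and the
piston model is least-squares fitted in dB over the candidate-aperture
grid.  The fit uses the measured per-hydrophone points rather than the
resampled curve: with hydrophone spacing coarse relative to the beam,
fitting the dB-linear interpolant would weight invented
between-hydrophone structure and biases the aperture estimate by tens
of percent (this was measured during development, and is the one place
the implementation deliberately departs from fitting the display
grid).

**Star array.**  Channels are gated at 14 dB peak-over-rms-noise; the
per-channel energies are corrected for spherical spreading when the
source position is known, fitted as a surface over the array plane,
and the beam axis is taken as the 0.5 cm-grid argmax of that surface
(ties toward the centre).  A piston at the known source range, aimed
at the axis and anchored to the click measured on the axis-nearest
hydrophone, is then predicted for every candidate aperture; the
least-square error in dB-energy space selects the aperture, $R^2$ on
the dB energies gates the fit, and the spread interval collects the
beamwidths of every candidate whose error lies within the lowest 5%
of the extent of the error curve.

## Design of the surface fitter

The surface fitter went through three designs, and the final one is a
deliberate deviation worth recording.  A bilinear finite-difference
regularized least-squares gridder (the closest literal translation of
a gridfit-style routine) was built first: its grid argmax either snaps
to the strongest hydrophone node near the interpolation regime or
drifts toward the centroid of the gated channels when stiff, because a
curvature penalty flattens exactly the paraboloid cap that carries the
peak location.  Locally weighted quadratic (LOESS) gridding fixed the
snapping but chases noise ripples across the flat beam tops at long
range.  The final engine exploits the same rotational-symmetry
assumption the piston fit already makes: the dB surface near the axis
is fitted as a circular paraboloid (channels within 10 dB of the
strongest), then refined by a four-parameter Nelder-Mead fit of the
exact main-lobe shape $E_0 + 10\log_{10} D(ka\sin\theta)$ with
$\theta$ measured at the source — this removes the skew that oblique
bearings induce in any centred quadratic, and the spreading-loss
correction removes the down-range displacement of the energy peak
relative to the beam axis (several centimetres at 7 m for wide beams).
The fitted cap evaluated on the 0.5 cm grid is the reported surface,
and the axis remains its grid argmax.

Two numerical choices matter elsewhere.  The channel gate compares
peak level to rms noise, as stated; for the Gaussian pip the peak
level exceeds the window energy flux density by
$10\log_{10}(2/(\sigma\sqrt{\pi})) \approx 47.8$ dB, and using window
energies directly would make the gate about 8.6 dB too strict and
starve short-range fits of channels.  And the piston-fit inner loop
evaluates $J_1$ through a tabulated ratio (5e-4 grid, error under
1e-7) because the exact Bessel call dominates runtime.

## The validation simulations

`run_error_simulation()` reproduces the virtual-source study that
motivates the inclusion criteria: pistons of known diameter (defaults
4.15, 8.3 and 16.6 cm) at bearings 0–20°, beam-axis displacements
0–12 cm and ranges 0.55–7 m (small array below 1.3 m, large beyond),
five replicates per cell with randomized bearing plane and
displacement direction, full chain per click, signed beamwidth error
and axis error recorded; failed cells are kept as NA with a reason.
Cells are then restricted to the published inclusion region — bearing
within $\pm15^\circ$ per axis, displacement within $\pm12$ cm (large),
$\pm8$ cm (small, more than 1 s before buzz onset) or $\pm6$ cm
(small, in buzz; the validation maps phase to range, since short
ranges are reached in the buzz) — and the maxima over that region are
the two acceptance quantities: beamwidth error at most
$\pm0.5^\circ$ and axis error at most $\pm1.5$ cm.
`derive_inclusion_mask()` inverts the logic, finding the largest
rectangle in (bearing, displacement) space that respects a given error
budget.  The energy mode samples the exact window-energy noise law
instead of rendering audio (the cross term plus a chi-squared noise
term); the audio mode renders and re-measures waveforms and agrees
with it, and is used at desk scale in the tests.

Two classes of cell are flagged rather than counted against the
bounds.  Cells where fewer than five channels pass the gate are
recorded as refusals with their reason.  And cells whose true
beamwidth falls below the array's effective angular resolution at
that range — the 16.6 cm piston's $4.1^\circ$ beam against the
$5.2^\circ$ EAR at 0.55 m, where the innermost 5 cm hydrophone ring
sits on the pattern null — are marked "beam narrower than the array
angular resolution" and excluded from the included-set maxima: an
instrument cannot validate a beam it cannot resolve, and the
published error bounds were never claims about sub-resolution beams.

## Degenerate inputs and tie-breaks

Surface argmax ties resolve toward the array centre; a peak estimate
at the edge of the searchable area raises `boundary_flag`; a cap fit
with non-negative curvature falls back to the strongest channel and
flags itself through the boundary logic.  The linear method rejects
clicks whose ASL peak sits on an outermost hydrophone, and patterns
that never drop 3 dB below their peak carry `beamwidth_bounded`.
First clicks take their buzz label from the following interval; a
single click has no label.  `localize_source()` flags geometric
dilution when the rms TDOA residual exceeds 2 microseconds.

## Known limitations

The linear array cannot observe the vertical beam dimension; its fits
assume the symmetric piston.  The simulator's clicks are minimum-phase
Gaussian pips with a fixed spectrum, so centroid-frequency dynamics of
real buzzes are not reproduced, only measured correctly when present.
The validation bounds hold for the piston family under the stated
noise; a strongly non-piston beam would pass the $R^2$ gate less
often but is outside the model space.  Statistical helpers
(`beamwidth_range_regression()`, `cluster_anova()`) pool clicks and do
not model per-trial random effects.
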