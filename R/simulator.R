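#' Synthetic trials: a clicking piston source approaching an array
#'
#' The generator renders multichannel recordings of a directional transient
#' source (a porpoise-like ~130 kHz click stand-in) moving along an
#' approach trajectory, with per-channel spherical-spreading propagation,
#' piston directivity, sensitivity offsets and band-limited Gaussian
#' noise, plus a single-channel tag stream carried at the source.  Ground
#' truth for every downstream estimate is returned alongside the audio.
#'
#' @name simulator
NULL

#' Piston click source
#'
#' @param diameter effective aperture d, m (0.01-0.30).
#' @param source_level on-axis energy flux density at 1 m,
#'   dB re 1 uPa^2 s.
#' @param click_centroid centroid frequency fc, Hz.
#' @param click_duration -20 dB envelope duration, s (<= 200 us).
#' @param sound_speed m/s.
#' @return list of class `piston_source`.
#' @export
piston_source <- function(diameter = 0.083, source_level = 140,
                          click_centroid = 130e3, click_duration = 80e-6,
                          sound_speed = 1500) {
  stopifnot(diameter >= 0.01, diameter <= 0.30, click_duration <= 200e-6)
  # Gaussian envelope: exp(-t^2/(2 sigma^2)) = 0.1 at t = +/- duration/2
  sigma <- click_duration / (2 * sqrt(2 * log(10)))
  # amplitude so that the on-axis energy flux density at 1 m is source_level
  amp <- sqrt(2 * undb(source_level) / (sigma * sqrt(pi)))
  structure(list(diameter = diameter, source_level = source_level,
                 click_centroid = click_centroid,
                 click_duration = click_duration,
                 sound_speed = sound_speed, sigma = sigma, amp = amp),
            class = "piston_source")
}

# Peak level minus window energy flux density, dB, for the Gaussian
# pip: peak pressure^2 = 2 E / (sigma sqrt(pi)).  Converts window-energy
# SNRs to the peak-vs-rms-noise scale of the 14 dB channel gate.
peak_excess_db <- function(source) 10 * log10(2 / (source$sigma * sqrt(pi)))

# Pressure of the pip (uPa at 1 m on-axis) at times t relative to the
# pip centre.
.pip_pressure <- function(source, t) {
  source$amp * exp(-t^2 / (2 * source$sigma^2)) *
    cos(2 * pi * source$click_centroid * t)
}

#' Sampled click waveform
#'
#' Gaussian-enveloped tone pip centred at the click centroid frequency,
#' scaled so the energy flux density of the 120 us analysis window at 1 m
#' on-axis equals the source level.
#'
#' @param source a `piston_source`.
#' @param fs sampling rate, Hz (>= 4 * fc).
#' @return list with `waveform` (pressure samples, uPa at 1 m on-axis),
#'   `fs`, and `centre_index` (sample index of the envelope peak).
#' @export
synth_click_waveform <- function(source, fs) {
  # Nyquist over the occupied band: fc plus ~3 envelope-spectrum sigmas
  f_max <- source$click_centroid + 3 / (2 * pi * source$sigma)
  if (fs < 2 * f_max)
    stop("fs too low: aliasing over the click's occupied band")
  half <- ceiling(5 * source$sigma * fs)
  t <- (-half:half) / fs
  list(waveform = .pip_pressure(source, t), fs = fs,
       centre_index = half + 1L)
}

#' Analytic energy spectrum of the source click
#'
#' Energy-density weights on a frequency grid around fc, used as the
#' broadband spectrum for piston directivity.
#'
#' @param source a `piston_source`.
#' @param n_bins odd number of bins.
#' @param span half-width in energy-spectrum standard deviations.
#' @return data.frame `frequency`, `energy`.
#' @export
source_spectrum <- function(source, n_bins = 13, span = 3) {
  # |FT of the envelope|^2 = exp(-4 pi^2 sigma^2 df^2)
  sigma_f <- 1 / (2 * pi * source$sigma * sqrt(2))
  f <- source$click_centroid + seq(-span, span, length.out = n_bins) * sigma_f
  w <- exp(-4 * pi^2 * source$sigma^2 * (f - source$click_centroid)^2)
  data.frame(frequency = f, energy = w)
}

#' Default piston spec of a source (broadband)
#' @param source a `piston_source`.
#' @param diameter optional override of the source diameter, m.
#' @export
source_piston_spec <- function(source, diameter = source$diameter) {
  piston_spec(diameter, frequency = source$click_centroid,
              spectrum = source_spectrum(source),
              sound_speed = source$sound_speed)
}

#' Schedule a straight-line target approach
#'
#' The source moves from `start_range` to `end_range` along the line from
#' the target through the array normal (+y), always aiming at the target.
#' The inter-click interval switches from regular clicking to buzz at
#' `buzz_switch_range`; the beamwidth profile maps range to an effective
#' aperture through the inverse piston model.
#'
#' @param start_range,end_range m, start > end > 0 (ranges to the target).
#' @param speed m/s.
#' @param ici_profile function(range_m) -> ICI s, or NULL for the default
#'   (regular 40 ms, buzz 3 ms, switching at `buzz_switch_range`).
#' @param beamwidth_profile function(range_m) -> full -3 dB beamwidth deg,
#'   or NULL for the default (9.1 deg at long range, widening linearly to
#'   15.1 deg between `buzz_switch_range` and `end_range`).
#' @param buzz_switch_range m.
#' @param source a `piston_source` (sets fc for the beamwidth inversion).
#' @param target_position 3-vector m (default origin-front target at
#'   `c(0, 0, 0)` offset is not used; pass the geometry's target).
#' @return data.frame of class `trajectory`: `time`, `x`, `y`, `z`,
#'   `ox`, `oy`, `oz` (unit acoustic-axis direction), `diameter`,
#'   `beamwidth_deg`, `ici`, `range` (to target).
#' @export
schedule_approach <- function(start_range, end_range, speed = 1,
                              ici_profile = NULL, beamwidth_profile = NULL,
                              buzz_switch_range = 2,
                              source = piston_source(),
                              target_position = c(0, 0, 0)) {
  stopifnot(start_range > end_range, end_range > 0, speed > 0)
  if (is.null(ici_profile))
    ici_profile <- function(r) ifelse(r > buzz_switch_range, 0.040, 0.003)
  if (is.null(beamwidth_profile))
    beamwidth_profile <- function(r) {
      w <- (buzz_switch_range - r) / (buzz_switch_range - end_range)
      ifelse(r > buzz_switch_range, 9.1, 9.1 + pmin(pmax(w, 0), 1) * 6)
    }
  times <- numeric(0); ranges <- numeric(0); icis <- numeric(0)
  t <- 0; r <- start_range
  while (r > end_range + 1e-9) {
    ici <- ici_profile(r)
    if (!is.finite(ici) || ici <= 0)
      stop("ici_profile must be positive over the approach")
    times <- c(times, t); ranges <- c(ranges, r); icis <- c(icis, ici)
    t <- t + ici
    r <- start_range - speed * t
  }
  bw <- beamwidth_profile(ranges)
  if (any(!is.finite(bw)))
    stop("beamwidth_profile undefined over the approach")
  # invert beamwidth -> diameter once per distinct value
  ubw <- unique(bw)
  ud <- vapply(ubw, inverse_beamwidth, numeric(1),
               frequency = source$click_centroid,
               sound_speed = source$sound_speed)
  d <- ud[match(bw, ubw)]
  # approach along +y toward the target
  pos <- cbind(target_position[1], target_position[2] + ranges,
               target_position[3])
  out <- data.frame(time = times, x = pos[, 1], y = pos[, 2], z = pos[, 3],
                    ox = 0, oy = -1, oz = 0,
                    diameter = d, beamwidth_deg = bw,
                    ici = c(NA_real_, diff(times)), range = ranges)
  class(out) <- c("trajectory", "data.frame")
  out
}

#' Propagate one click to the array
#'
#' Spherical spreading at c = 1500 m/s: each channel receives the click
#' delayed by r/c and scaled so the received energy flux density is
#' SL - 20 log10(r / 1 m) + 10 log10 D(theta) + sensitivity offset, with
#' D the broadband piston energy directivity at the angle between the
#' acoustic axis and the source-to-hydrophone line.
#'
#' @param source a `piston_source`.
#' @param position source position, 3-vector m.
#' @param orientation unit 3-vector, acoustic-axis direction.
#' @param geometry an `array_geometry`.
#' @param diameter instantaneous aperture, m (default the source's).
#' @return data.frame: `channel`, `range_m`, `theta_deg`, `delay_s`,
#'   `efd_db` (received energy flux density), `amp_scale` (pressure scale
#'   relative to 1 m on-axis).
#' @export
propagate_click <- function(source, position, orientation, geometry,
                            diameter = source$diameter) {
  orientation <- orientation / vnorm(orientation)
  rel <- sweep(geometry$positions, 2, position)
  rng <- sqrt(rowSums(rel^2))
  if (any(rng <= 0.05))
    stop("hydrophone closer than 0.05 m to the source")
  cosang <- pmin(1, pmax(-1, (rel %*% orientation) / rng))
  theta <- rad2deg(acos(as.numeric(cosang)))
  spec <- source_piston_spec(source, diameter)
  D <- piston_directivity(spec, pmin(theta, 90))
  D[theta > 90] <- 0  # baffled piston: no back radiation
  efd <- source$source_level - 20 * log10(rng) + db(pmax(D, 1e-300)) +
    geometry$sensitivity
  data.frame(channel = geometry$ids, range_m = rng, theta_deg = theta,
             delay_s = rng / source$sound_speed, efd_db = efd,
             amp_scale = 10^((efd - source$source_level) / 20))
}

# Add one pip into a sample buffer at centre time tc with pressure scale.
.render_pip <- function(buf, fs, source, tc, scale) {
  half <- 5 * source$sigma
  i0 <- max(1L, floor((tc - half) * fs) + 1L)
  i1 <- min(length(buf), ceiling((tc + half) * fs) + 1L)
  if (i1 < i0) return(buf)
  t <- (i0:i1 - 1L) / fs - tc
  buf[i0:i1] <- buf[i0:i1] + scale * .pip_pressure(source, t)
  buf
}

#' Render a full synthetic trial
#'
#' Sums all propagated clicks into per-channel streams, adds band-limited
#' (2-200 kHz) white Gaussian noise at `noise_level` (energy flux density
#' per 120 us window, dB re 1 uPa^2 s; `-Inf` for none), and renders a tag
#' stream at the moving source including a delayed target echo.
#' Deterministic given `seed`.
#'
#' @param geometry an `array_geometry`.
#' @param track a `trajectory` from [schedule_approach()] (or a compatible
#'   data.frame).
#' @param source a `piston_source`.
#' @param fs sampling rate, Hz.
#' @param noise_level dB re 1 uPa^2 s per 120 us window; `-Inf` disables.
#' @param seed integer.
#' @param tag render the tag stream?
#' @param target_strength echo target strength, dB.
#' @param tag_click_offset level of the outgoing click on the tag relative
#'   to the source level, dB (tag sits behind the sound source).
#' @param full_scale optional peak pressure (uPa) of the recording chain;
#'   exceeding it raises a warning (`clipped` attribute set).
#' @return list of class `simulated_trial`: `audio` (samples x channels
#'   matrix, uPa), `tag_audio`, `fs`, `truth` (per-click ground truth),
#'   `geometry`, `source`, `noise_level`, `seed`.
#' @export
synthesize_trial <- function(geometry, track, source, fs = 500e3,
                             noise_level = -Inf, seed = 1, tag = TRUE,
                             target_strength = -36, tag_click_offset = -25,
                             full_scale = NULL) {
  stopifnot(nrow(track) >= 1L)
  nch <- n_hydrophones(geometry)
  max_range <- max(sqrt(rowSums(
    sweep(as.matrix(track[, c("x", "y", "z")]), 2,
          colMeans(geometry$positions))^2)))
  dur <- max(track$time) + max_range / source$sound_speed + 2e-3
  if (tag) {
    # cover the two-way target echo of the last click
    r_last <- sqrt(sum((as.numeric(track[nrow(track), c("x", "y", "z")]) -
                          geometry$target_position)^2))
    dur <- max(dur, max(track$time) + 2 * r_last / source$sound_speed +
                 1e-3)
  }
  n <- ceiling(dur * fs)
  audio <- matrix(0, n, nch)
  tag_audio <- numeric(n)
  truth <- vector("list", nrow(track))
  for (k in seq_len(nrow(track))) {
    pos <- as.numeric(track[k, c("x", "y", "z")])
    ori <- as.numeric(track[k, c("ox", "oy", "oz")])
    dk <- track$diameter[k]
    prop <- propagate_click(source, pos, ori, geometry, diameter = dk)
    for (j in seq_len(nch))
      audio[, j] <- .render_pip(audio[, j], fs, source,
                                track$time[k] + prop$delay_s[j],
                                prop$amp_scale[j])
    r_t <- vnorm(pos - geometry$target_position)
    if (tag) {
      tag_audio <- .render_pip(tag_audio, fs, source, track$time[k],
                               10^(tag_click_offset / 20))
      echo_db <- tag_click_offset - 40 * log10(r_t) + target_strength
      tag_audio <- .render_pip(tag_audio, fs, source,
                               track$time[k] + 2 * r_t / source$sound_speed,
                               10^(echo_db / 20))
    }
    truth[[k]] <- data.frame(
      click = k, t_emit = track$time[k], x = pos[1], y = pos[2], z = pos[3],
      ox = ori[1], oy = ori[2], oz = ori[3], diameter = dk,
      beamwidth_deg = piston_beamwidth(source_piston_spec(source, dk)),
      ici = track$ici[k], range_target = r_t,
      range_centre = vnorm(pos))
  }
  truth <- do.call(rbind, truth)
  clipped <- FALSE
  if (is.finite(noise_level)) {
    set.seed(seed)
    sigma_n <- sqrt(undb(noise_level) / 120e-6)
    for (j in seq_len(nch)) {
      w <- fft_bandpass(stats::rnorm(n), fs, c(2e3, 200e3))
      audio[, j] <- audio[, j] + w * (sigma_n / stats::sd(w))
    }
    if (tag) {
      w <- fft_bandpass(stats::rnorm(n), fs, c(2e3, 200e3))
      tag_audio <- tag_audio + w * (sigma_n / stats::sd(w))
    }
  }
  if (!is.null(full_scale) && max(abs(audio)) > full_scale) {
    clipped <- TRUE
    warning("peak pressure exceeds full scale; audio left unclipped")
  }
  structure(list(audio = audio, tag_audio = if (tag) tag_audio else NULL,
                 fs = fs, truth = truth, geometry = geometry,
                 source = source, noise_level = noise_level, seed = seed,
                 clipped = clipped),
            class = "simulated_trial")
}

#' @export
print.simulated_trial <- function(x, ...) {
  cat(sprintf("<simulated_trial: %d clicks, %d channels, %.3f s at %g kHz>\n",
              nrow(x$truth), ncol(x$audio), nrow(x$audio) / x$fs,
              x$fs / 1e3))
  invisible(x)
}

#' Write a trial to disk as plain text
#'
#' One CSV per channel plus a ground-truth CSV and the geometry JSON.
#' (Plain-text stand-in for multichannel WAV output.)
#'
#' @param trial a `simulated_trial`.
#' @param dir output directory.
#' @export
write_trial <- function(trial, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(trial$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  write_geometry_json(trial$geometry, file.path(dir, "geometry.json"))
  utils::write.csv(data.frame(trial$audio),
                   file.path(dir, "audio.csv"), row.names = FALSE)
  if (!is.null(trial$tag_audio))
    utils::write.csv(data.frame(tag = trial$tag_audio),
                     file.path(dir, "tag.csv"), row.names = FALSE)
  invisible(dir)
}
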