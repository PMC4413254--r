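# Shared fixtures, all generated in code.

# One-click linear-array trial at a known pose, optionally noisy.
make_linear_trial <- function(position = c(0.3, 3, 0),
                              aim = c(0, 0, 0), diameter = 0.083,
                              noise_level = -Inf, seed = 1,
                              source = piston_source()) {
  geom <- build_linear_array()
  ori <- aim - position
  track <- data.frame(time = 0, x = position[1], y = position[2],
                      z = position[3], ox = ori[1], oy = ori[2],
                      oz = ori[3], diameter = diameter, ici = NA_real_)
  synthesize_trial(geom, track, source, noise_level = noise_level,
                   seed = seed, tag = FALSE)
}

# Per-channel energies for one star-array click, via the propagation
# model (exact window energies, no audio rendering).
star_click_energies <- function(config = "small", range = 1,
                                axis_xz = c(0, 0), diameter = 0.083,
                                source = piston_source()) {
  geom <- build_star_array(config)
  pos <- c(0, range, 0)
  aim <- c(axis_xz[1], 0, axis_xz[2]) - pos
  prop <- propagate_click(source, pos, aim, geom, diameter = diameter)
  list(geometry = geom, position = pos, prop = prop)
}

# Full energy-domain star chain for every click of a trajectory:
# returns per-click beamwidth estimates with ground truth.  The array
# configuration follows the pooling rule (small below 1.3 m, large
# beyond).
estimate_track_beamwidths <- function(track, noise_snr = 30, seed = 1,
                                      source = piston_source()) {
  geoms <- list(small = build_star_array("small"),
                large = build_star_array("large"))
  spectrum <- source_spectrum(source)
  set.seed(seed)
  out <- lapply(seq_len(nrow(track)), function(k) {
    pos <- as.numeric(track[k, c("x", "y", "z")])
    ori <- as.numeric(track[k, c("ox", "oy", "oz")])
    rng <- vnorm_test(pos)
    geom <- if (rng < 1.3) geoms$small else geoms$large
    prop <- propagate_click(source, pos, ori, geom,
                            diameter = track$diameter[k])
    nl <- source$source_level - 20 * log10(rng) - noise_snr
    efd <- sonarbeam:::.noisy_energy_db(prop$efd_db, nl)
    gated <- tryCatch(select_channels(efd, rep(nl, length(efd))),
                      error = function(e) integer(0))
    if (length(gated) < 5L) return(NULL)
    e <- rep(NA_real_, length(efd)); e[gated] <- efd[gated]
    surf <- fit_energy_surface(e, geom$positions[, c(1, 3)], rng,
                               source_position = pos)
    fit <- fit_piston_star(efd[gated], geom$positions[gated, ], pos,
                           surf$axis_xz, spectrum = spectrum)
    data.frame(time = track$time[k], range = rng,
               est_bw = fit$beamwidth_deg,
               true_bw = track$beamwidth_deg[k],
               r2 = fit$r_squared, ici = track$ici[k])
  })
  do.call(rbind, out)
}

vnorm_test <- function(v) sqrt(sum(v^2))
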