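#' Star-array beam-axis estimation and Monte-Carlo piston fitting
#'
#' The 2D-array method: gate channels at 14 dB over channel noise, fit a
#' regularized least-squares surface to the per-channel click energies on
#' a 0.5 cm grid over the area subtending +/-20 degrees at the emission
#' range, take the beam axis as the surface peak, then fit theoretical
#' piston transducers (diameters 1/3 to 3 times 8.3 cm in 0.1 cm steps)
#' placed at the source range, aimed at the axis and anchored to the
#' click measured on the axis-nearest hydrophone.  Fits with R^2 <= 0.8
#' are excluded from final analyses.
#'
#' @name beam_star
NULL

#' Select channels by the 14 dB rule
#'
#' @param peak_db per-channel peak received level (or click energy), dB.
#' @param noise_db per-channel rms noise reference, dB (same units).
#' @param threshold_db dB (default 14).
#' @param min_channels minimum retained channels for a fit.
#' @return integer vector of retained channel indices.
#' @export
select_channels <- function(peak_db, noise_db, threshold_db = 14,
                            min_channels = 5L) {
  keep <- which((peak_db - noise_db) >= threshold_db)
  if (length(keep) < min_channels)
    stop(sprintf("only %d channels pass the %g dB gate (need >= %d): fit refused",
                 length(keep), threshold_db, min_channels))
  keep
}

# Surface-gridding engine: least-squares circular-paraboloid fit of
# the spreading-corrected dB energies of the near-axis channels.  Near
# its axis the dB beam surface of a rotationally symmetric source is a
# paraboloid cap (the same symmetry assumption the piston fit makes),
# so the cap vertex is the beam axis.  Penalized-spline and locally
# weighted (LOESS) gridding were tried first and rejected: their argmax
# either snaps to the strongest hydrophone node, drifts toward the data
# centroid when stiff, or chases noise ripples across flat beam tops at
# long range.
surface_fitter <- function(xz, extent, grid_step = 0.005) {
  xz <- as.matrix(xz)
  # node lattice centred on the array centre (always contains 0)
  n_half <- floor(extent / grid_step)
  g <- seq(-n_half, n_half) * grid_step
  gx <- rep(g, times = length(g))
  gz <- rep(g, each = length(g))
  disc <- sqrt(gx^2 + gz^2) <= extent + 1e-12
  use <- which(sqrt(rowSums(xz^2)) <= extent + 1e-12)
  list(grid = g, node_x = gx[disc], node_z = gz[disc], use = use,
       p = xz[use, , drop = FALSE], extent = extent,
       grid_step = grid_step)
}

#' Fit an energy surface and estimate the beam axis
#'
#' Least-squares gridding of per-channel click energies over the array
#' plane (0.5 cm cells), restricted to the disc subtending
#' +/- `max_half_angle` at the emission range (capped at the array
#' extent); the beam axis is the grid argmax, ties broken toward the
#' array centre.  The fitted surface is a circular paraboloid in dB
#' (`e0 - a * |p - axis|^2`), the near-axis shape of a rotationally
#' symmetric beam, fitted to the channels within `axis_top_db` of the
#' strongest gated channel.
#'
#' @param energies_db per-channel energies, dB, aligned with `xz`;
#'   channels excluded by the gate are passed as NA.
#' @param xz channel positions on the array plane, n x 2 matrix, m.
#' @param range emission range, m.
#' @param grid_step m (default 0.005).
#' @param max_half_angle degrees.
#' @param axis_top_db only channels within this many dB of the strongest
#'   gated channel enter the surface fit: the peak estimate rests on the
#'   quasi-parabolic beam core, not the steep skirt toward the first
#'   null (at least the 5 strongest channels are always kept).
#' @param fitter optional prebuilt grid descriptor (reused across
#'   clicks on the same geometry and range).
#' @param source_position optional source position (3-vector, m); when
#'   given, channel energies are corrected for spherical spreading
#'   (+20 log10 of the source-to-hydrophone range) before the fit, so
#'   that the surface peaks where the directivity peaks.  Without the
#'   correction the energy peak is displaced down-range of the beam
#'   axis under oblique bearings (by several cm at long range for wide
#'   beams).
#' @return list of class `energy_surface`: `axis_xz` (m), `values`
#'   (fitted values on the candidate nodes), `node_x`, `node_z`,
#'   `boundary_flag` (argmax at the edge of the searchable area),
#'   `n_channels`, `fitter`.
#' @export
fit_energy_surface <- function(energies_db, xz, range,
                               grid_step = 0.005, max_half_angle = 20,
                               axis_top_db = 10,
                               fitter = NULL, source_position = NULL) {
  if (is.null(fitter)) {
    extent <- min(range * tan(deg2rad(max_half_angle)),
                  max(sqrt(rowSums(as.matrix(xz)^2))))
    extent <- max(extent, 3 * grid_step)
    fitter <- surface_fitter(xz, extent, grid_step)
  }
  b <- energies_db[fitter$use]
  if (!is.null(source_position)) {
    rel <- cbind(fitter$p[, 1] - source_position[1],
                 -source_position[2],
                 fitter$p[, 2] - source_position[3])
    b <- b + 20 * log10(sqrt(rowSums(rel^2)))
  }
  S <- which(is.finite(b))
  if (length(S) < 5L) stop("too few gated channels inside the fit area")
  core <- S[b[S] >= max(b[S]) - axis_top_db]
  if (length(core) < 5L) core <- S[order(b[S], decreasing = TRUE)[1:5]]
  S <- sort(core)
  p <- fitter$p[S, , drop = FALSE]
  co <- stats::lm.fit(cbind(1, p[, 1], p[, 2],
                            p[, 1]^2 + p[, 2]^2), b[S])$coefficients
  if (any(is.na(co)) || co[4] >= 0) {
    # degenerate cap: fall back to a peak at the strongest channel
    imax <- which.max(b[S])
    co <- c(0, 2 * p[imax, 1], 2 * p[imax, 2], -1)
  }
  vertex <- -co[2:3] / (2 * co[4])
  # Refine with the exact beam-cap shape: dB = E0 + 10 log10 of the
  # piston energy ratio at x = ka sin(theta), with theta measured at
  # the source between the candidate axis direction and each
  # source-to-channel line (falling back to in-plane radial distance
  # when the source position is unknown).  The paraboloid is only the
  # leading term of the cap, and under oblique bearings the cap in
  # plane coordinates is skewed, which biases any centred quadratic.
  e0 <- co[1] - (co[2]^2 + co[3]^2) / (4 * co[4])  # value at the vertex
  if (!is.null(source_position)) {
    w <- cbind(p[, 1] - source_position[1], -source_position[2],
               p[, 2] - source_position[3])
    wn <- w / sqrt(rowSums(w^2))
    r0 <- sqrt(sum(source_position^2))
    sin_theta <- function(v) {
      u <- c(v[1], 0, v[2]) - source_position
      ct <- pmin(1, pmax(-1, (wn %*% (u / vnorm(u)))[, 1]))
      sqrt(1 - ct^2)
    }
    kap0 <- r0 * sqrt(max(-co[4], 1e-6) / 1.0857)
  } else {
    sin_theta <- function(v)
      sqrt((p[, 1] - v[1])^2 + (p[, 2] - v[2])^2)
    kap0 <- sqrt(max(-co[4], 1e-6) / 1.0857)
  }
  obj <- function(par) {
    pred <- par[1] + db(pmax(.piston_ratio_fast(
      exp(par[4]) * sin_theta(par[2:3])), 1e-12))
    sum((pred - b[S])^2)
  }
  # multi-start Nelder-Mead (paraboloid vertex and strongest channel)
  # with one restart from the best solution to escape premature
  # simplex collapse
  imax <- which.max(b[S])
  starts <- list(c(e0, vertex, log(kap0)),
                 c(b[S][imax], p[imax, 1], p[imax, 2], log(kap0)))
  best <- NULL
  for (st in starts) {
    o <- stats::optim(st, obj, method = "Nelder-Mead",
                      control = list(maxit = 400L, reltol = 1e-10))
    if (is.null(best) || o$value < best$value) best <- o
  }
  best <- stats::optim(best$par, obj, method = "Nelder-Mead",
                       control = list(maxit = 400L, reltol = 1e-10))
  cap <- best$par
  vertex <- cap[2:3]
  # argmax over the 0.5 cm grid, restricted to the data-supported part
  # of the fit area (beyond the outermost gated channel the surface is
  # pure extrapolation); ties broken toward the array centre
  r_data <- max(sqrt(rowSums(p^2))) + fitter$grid_step
  node_r <- sqrt(fitter$node_x^2 + fitter$node_z^2)
  near <- which(node_r <= r_data &
                  abs(fitter$node_x - vertex[1]) <= 6 * fitter$grid_step &
                  abs(fitter$node_z - vertex[2]) <= 6 * fitter$grid_step)
  if (length(near) == 0L) near <- which(node_r <= r_data)
  if (!is.null(source_position)) {
    u <- c(vertex[1], 0, vertex[2]) - source_position
    u <- u / vnorm(u)
    wng <- cbind(fitter$node_x[near] - source_position[1],
                 -source_position[2],
                 fitter$node_z[near] - source_position[3])
    wng <- wng / sqrt(rowSums(wng^2))
    ct <- pmin(1, pmax(-1, (wng %*% u)[, 1]))
    rho_n <- sqrt(1 - ct^2)
  } else {
    rho_n <- sqrt((fitter$node_x[near] - vertex[1])^2 +
                    (fitter$node_z[near] - vertex[2])^2)
  }
  vn <- cap[1] + db(pmax(.piston_ratio_fast(exp(cap[4]) * rho_n), 1e-12))
  best_val <- max(vn)
  ties <- near[which(vn >= best_val - 1e-12)]
  axis_i <- ties[which.min(node_r[ties])]
  axis <- c(fitter$node_x[axis_i], fitter$node_z[axis_i])
  boundary <- sqrt(sum(axis^2)) >
    min(fitter$extent, r_data) - 1.5 * fitter$grid_step
  structure(list(axis_xz = axis, values = vn,
                 node_x = fitter$node_x[near],
                 node_z = fitter$node_z[near], boundary_flag = boundary,
                 n_channels = length(S), coef = co, cap = cap,
                 fitter = fitter),
            class = "energy_surface")
}

#' Monte-Carlo piston fit on the star array
#'
#' For each candidate diameter, predicts the energy at every gated
#' hydrophone from a piston at the source position aimed at the estimated
#' axis, anchored to the click measured on the axis-nearest hydrophone;
#' the best diameter minimizes the least-square error in dB-energy space.
#' The spread interval collects the beamwidths of all diameters whose
#' error lies within the lowest 5% of the extent of the error curve.
#'
#' @param energies_db gated per-channel energies, dB.
#' @param positions gated hydrophone positions, n x 3, m.
#' @param source_position 3-vector, m.
#' @param axis_xz estimated beam-axis position on the array plane, m.
#' @param spectrum optional click energy spectrum for broadband
#'   directivity (data.frame `frequency`, `energy`).
#' @param frequency narrowband frequency, Hz.
#' @param candidates candidate diameters, m (default 2.77-24.9 cm in
#'   0.1 cm increments).
#' @param sound_speed m/s.
#' @param r2_threshold fits at or below are flagged excluded.
#' @param lse_threshold optional absolute error gate (alternative error
#'   gate; NULL disables).
#' @param spread_frac fraction of the error-curve extent defining the
#'   spread set.
#' @param floor_db dB floor applied at model nulls.
#' @return a `piston_fit` with `best_diameter`, `beamwidth_deg`,
#'   `spread_deg` (low, high), `r_squared`, `lse`, `axis_xz`,
#'   `n_channels`, `included`, `reason`, `candidates`, `lse_curve`.
#' @export
fit_piston_star <- function(energies_db, positions, source_position,
                            axis_xz, spectrum = NULL, frequency = 130e3,
                            candidates = seq(0.0277, 0.249, by = 0.001),
                            sound_speed = 1500, r2_threshold = 0.8,
                            lse_threshold = NULL, spread_frac = 0.05,
                            floor_db = -60) {
  positions <- as.matrix(positions)
  n <- length(energies_db)
  stopifnot(nrow(positions) == n, n >= 5L)
  axis_point <- c(axis_xz[1], 0, axis_xz[2])
  u_axis <- axis_point - source_position
  u_axis <- u_axis / vnorm(u_axis)
  rel <- sweep(positions, 2, source_position)
  rng <- sqrt(rowSums(rel^2))
  cosang <- pmin(1, pmax(-1, (rel %*% u_axis) / rng))
  theta <- rad2deg(acos(as.numeric(cosang)))
  anchor <- which.min((positions[, 1] - axis_xz[1])^2 +
                      (positions[, 3] - axis_xz[2])^2)
  if (is.null(spectrum)) {
    freqs <- frequency; w <- 1
  } else {
    freqs <- spectrum$frequency
    w <- spectrum$energy / sum(spectrum$energy)
  }
  nb <- length(freqs)
  a_cand <- candidates / 2
  st <- sin(deg2rad(pmin(theta, 90)))
  # x[bin, cand, channel] = k_f * a_d * sin(theta_j), one besselJ pass
  k <- 2 * pi * freqs / sound_speed
  x <- as.vector(outer(k, a_cand)) %o% st
  r <- .piston_ratio_fast(x)
  dim(r) <- c(nb, length(candidates) * n)
  D <- matrix(as.numeric(crossprod(w, matrix(r, nb))),
              length(candidates), n)  # broadband energy directivity
  D[, theta > 90] <- 0
  Ddb <- pmax(db(pmax(D, 1e-300)), floor_db)
  # anchored prediction in dB-energy space; both prediction and data
  # are clamped at floor_db below the anchor so that channels sitting
  # in pattern nulls (arbitrarily small energies) cannot dominate the
  # dB residuals
  pred <- (energies_db[anchor] + 20 * log10(rng[anchor])) -
    outer(rep(1, length(candidates)), 20 * log10(rng)) +
    Ddb - Ddb[, anchor]
  floor_abs <- energies_db[anchor] + floor_db
  obs <- pmax(energies_db, floor_abs)
  resid <- sweep(pmax(pred, floor_abs), 2, obs)
  lse <- rowSums(resid^2)
  best <- which.min(lse)
  d <- candidates[best]
  sst <- sum((obs - mean(obs))^2)
  r2 <- 1 - lse[best] / sst
  bw_of <- function(dd) piston_beamwidth(
    piston_spec(dd, frequency, spectrum = spectrum,
                sound_speed = sound_speed))
  thr <- min(lse) + spread_frac * (max(lse) - min(lse))
  sel <- candidates[lse <= thr]
  spread <- c(bw_of(max(sel)), bw_of(min(sel)))
  reason <- character(0)
  if (r2 <= r2_threshold)
    reason <- c(reason, sprintf("R^2 <= %.2f", r2_threshold))
  if (!is.null(lse_threshold) && lse[best] >= lse_threshold)
    reason <- c(reason, "error gate")
  if (diff(range(lse)) < 1e-9)
    reason <- c(reason, "flat error curve (unconstrained fit)")
  structure(list(best_diameter = d, beamwidth_deg = bw_of(d),
                 spread_deg = spread, r_squared = r2, lse = lse[best],
                 axis_xz = axis_xz, n_channels = n, anchor = anchor,
                 included = length(reason) == 0L,
                 reason = if (length(reason)) paste(reason, collapse = "; ")
                          else "ok",
                 candidates = candidates, lse_curve = lse,
                 method = "star"),
            class = "piston_fit")
}

#' Inclusion criteria for star-array fits
#'
#' A click enters the final analysis only when the animal's bearing is
#' within +/-15 degrees both vertically and horizontally from the array
#' centre AND the beam axis lies within the configuration- and
#' phase-dependent displacement bound: +/-12 cm for the large array;
#' +/-8 cm for small-array clicks produced up to 1 s before the start of
#' buzz; +/-6 cm from 1 s before buzz onward.
#'
#' @param axis_xz beam-axis position on the array plane, m.
#' @param azimuth,elevation source bearing, degrees.
#' @param config `"large"` or `"small"`.
#' @param phase `"pre_buzz"` (more than 1 s before buzz onset) or
#'   `"buzz"` (1 s before onset and onwards); NA applies the conservative
#'   +/-6 cm bound.
#' @param bearing_limit degrees.
#' @return list `included` (logical), `reason` (character).
#' @export
apply_inclusion_criteria <- function(axis_xz, azimuth, elevation,
                                     config = c("large", "small"),
                                     phase = c("pre_buzz", "buzz"),
                                     bearing_limit = 15) {
  config <- match.arg(config)
  if (length(phase) != 1L || is.na(phase)) {
    bound <- 0.06
  } else {
    phase <- match.arg(phase)
    bound <- if (config == "large") 0.12
             else if (phase == "pre_buzz") 0.08 else 0.06
  }
  if (config == "large") bound <- 0.12
  disp <- sqrt(sum(axis_xz^2))
  reason <- character(0)
  if (abs(azimuth) > bearing_limit)
    reason <- c(reason, sprintf("azimuth %.1f deg beyond +/-%g", azimuth,
                                bearing_limit))
  if (abs(elevation) > bearing_limit)
    reason <- c(reason, sprintf("elevation %.1f deg beyond +/-%g",
                                elevation, bearing_limit))
  if (disp > bound + 1e-9)
    reason <- c(reason, sprintf("axis displacement %.1f cm beyond %.0f cm",
                                100 * disp, 100 * bound))
  list(included = length(reason) == 0L,
       reason = if (length(reason)) paste(reason, collapse = "; ") else "ok")
}
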