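#' Virtual-source error simulations
#'
#' Reproduces the validation of the star-array chain: virtual piston
#' sources of known diameter are placed at controlled bearings, beam-axis
#' displacements and ranges; each synthetic click is pushed through the
#' channel gate, energy-surface axis estimation and Monte-Carlo piston
#' fit, and the signed beamwidth error and axis position error are
#' recorded.  Restricting to the derived inclusion region bounds the
#' beamwidth error at +/-0.5 degrees and the axis error at +/-1.5 cm.
#'
#' @name validation_sim
NULL

# Noisy window energies without rendering audio: for white Gaussian
# noise of window energy En over an m-sample window, the measured window
# energy is Es + 2 Z sqrt(Es En / m) + En X/m with Z ~ N(0,1),
# X ~ chi^2_m (signal-noise cross term plus noise energy).
.noisy_energy_db <- function(efd_db, noise_win_db, m = 60L) {
  if (!is.finite(noise_win_db)) return(efd_db)
  es <- undb(efd_db)
  en <- undb(noise_win_db)
  n <- length(es)
  e <- es + 2 * stats::rnorm(n) * sqrt(es * en / m) +
    en * stats::rchisq(n, df = m) / m
  db(pmax(e, 1e-300))
}

#' Run the virtual-source error simulation
#'
#' For every cell of the (diameter, bearing, displacement, range) grid,
#' `n_rep` synthetic clicks are generated (random displacement direction
#' and bearing plane per replicate), the full star-array estimation chain
#' is run, and the beamwidth and axis errors are recorded.  Cells where
#' the chain fails are recorded as NA with a reason, not dropped.
#' Deterministic for a fixed seed.
#'
#' @param diameters true piston diameters, m.
#' @param bearings source bearings off the array normal, degrees.
#' @param displacements beam-axis displacements from the array centre, m.
#' @param ranges source ranges, m; ranges below `config_switch` use the
#'   small array, others the large array.
#' @param noise_snr approximate centre-channel SNR, dB (noise window
#'   energy is set to on-axis received level minus this; `Inf` disables
#'   noise).
#' @param n_rep replicates per cell.
#' @param seed integer.
#' @param source a `piston_source` (click model; its diameter is
#'   overridden per cell).
#' @param mode `"energy"` (fast: exact window energies plus analytic
#'   window-noise statistics) or `"audio"` (render waveforms and measure
#'   them with the click-processing chain).
#' @param config_switch m; array-configuration switch range.
#' @param grid_step surface grid, m.
#' @param r2_threshold piston-fit gate.
#' @return data.frame of class `error_surface`: one row per replicate
#'   with `diameter`, `bearing`, `displacement`, `range`, `rep`,
#'   `config`, `true_beamwidth`, `est_beamwidth`, `bw_error`,
#'   `axis_error_cm`, `r_squared`, `n_channels`, `included`, `reason`.
#' @export
run_error_simulation <- function(diameters = c(0.0415, 0.083, 0.166),
                                 bearings = seq(0, 20, by = 5),
                                 displacements = seq(0, 0.12, by = 0.02),
                                 ranges = c(0.55, 1, 2, 4, 7),
                                 noise_snr = 30, n_rep = 5, seed = 1,
                                 source = piston_source(),
                                 mode = c("energy", "audio"),
                                 config_switch = 1.3,
                                 grid_step = 0.005,
                                 r2_threshold = 0.8) {
  mode <- match.arg(mode)
  set.seed(seed)
  geoms <- list(large = build_star_array("large"),
                small = build_star_array("small"))
  fitters <- list()
  spectrum <- source_spectrum(source)
  true_bw <- vapply(diameters, function(d)
    piston_beamwidth(source_piston_spec(source, d)), numeric(1))
  grid <- expand.grid(diameter = diameters, bearing = bearings,
                      displacement = displacements, range = ranges,
                      rep = seq_len(n_rep))
  grid <- grid[order(grid$range, grid$bearing, grid$displacement,
                     grid$diameter, grid$rep), ]
  out <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    config <- if (g$range < config_switch) "small" else "large"
    geom <- geoms[[config]]
    extent <- min(g$range * tan(deg2rad(20)),
                  max(sqrt(rowSums(geom$positions^2))))
    key <- sprintf("%s_%.4f", config, extent)
    if (is.null(fitters[[key]]))
      fitters[[key]] <- surface_fitter(geom$positions[, c(1, 3)], extent,
                                       grid_step = grid_step)
    fitter <- fitters[[key]]
    # random bearing plane and displacement direction per replicate
    phi_b <- stats::runif(1, 0, 2 * pi)
    phi_d <- stats::runif(1, 0, 2 * pi)
    b <- deg2rad(g$bearing)
    src_pos <- g$range * c(sin(b) * cos(phi_b), cos(b), sin(b) * sin(phi_b))
    axis_true <- c(g$displacement * cos(phi_d),
                   g$displacement * sin(phi_d))
    aim <- c(axis_true[1], 0, axis_true[2]) - src_pos
    res <- tryCatch({
      if (mode == "energy") {
        prop <- propagate_click(source, src_pos, aim, geom,
                                diameter = g$diameter)
        noise_db <- if (is.finite(noise_snr))
          source$source_level - 20 * log10(g$range) - noise_snr else -Inf
        efd <- .noisy_energy_db(prop$efd_db, noise_db)
        snr_ref <- noise_db
      } else {
        src_k <- source
        track <- data.frame(time = 0.0, x = src_pos[1], y = src_pos[2],
                            z = src_pos[3], ox = aim[1], oy = aim[2],
                            oz = aim[3], diameter = g$diameter,
                            ici = NA_real_)
        noise_db <- if (is.finite(noise_snr))
          source$source_level - 20 * log10(g$range) - noise_snr else -Inf
        trial <- synthesize_trial(geom, track, src_k,
                                  noise_level = noise_db,
                                  seed = sample.int(2^31 - 1, 1),
                                  tag = FALSE)
        meas <- measure_trial_clicks(trial)
        if (nrow(meas$clicks) != 1L) stop("detection failed")
        efd <- meas$efd_db[1, ]
        snr_ref <- noise_db
      }
      # the 14 dB gate compares peak received level to channel rms
      # noise; convert the window energies to that scale
      peak_db <- efd + peak_excess_db(source)
      rms_db <- snr_ref - 10 * log10(120e-6)
      gated <- select_channels(peak_db, rep(rms_db, length(efd)),
                               threshold_db = 14)
      efd_gated <- rep(NA_real_, length(efd))
      efd_gated[gated] <- efd[gated]
      surf <- fit_energy_surface(efd_gated, geom$positions[, c(1, 3)],
                                 g$range, fitter = fitter,
                                 source_position = src_pos)
      fit <- fit_piston_star(efd[gated], geom$positions[gated, ],
                             src_pos, surf$axis_xz, spectrum = spectrum,
                             frequency = source$click_centroid,
                             sound_speed = source$sound_speed,
                             r2_threshold = r2_threshold)
      tb <- true_bw[match(g$diameter, diameters)]
      bearing_az_el <- bearing_to_centre(src_pos)
      # phase follows range: short ranges are reached in the terminal
      # buzz, so small-array cells carry the in-buzz +/-6 cm bound
      incl <- apply_inclusion_criteria(
        surf$axis_xz, bearing_az_el[["azimuth"]],
        bearing_az_el[["elevation"]], config = config,
        phase = if (g$range <= 2) "buzz" else "pre_buzz")
      # a beam narrower than the array's angular resolution at this
      # range cannot be measured (the innermost 5 cm ring falls outside
      # the main lobe, at or beyond the first null): flag, don't count
      if (tb < effective_angular_resolution(0.05, g$range)) {
        incl$included <- FALSE
        if (incl$reason == "ok")
          incl$reason <- "beam narrower than the array angular resolution"
      }
      data.frame(config = config, true_beamwidth = tb,
                 est_beamwidth = fit$beamwidth_deg,
                 bw_error = fit$beamwidth_deg - tb,
                 axis_error_cm = 100 * sqrt(sum((surf$axis_xz -
                                                   axis_true)^2)),
                 r_squared = fit$r_squared,
                 n_channels = fit$n_channels,
                 fit_ok = fit$included && !surf$boundary_flag,
                 included = incl$included,
                 reason = if (incl$included) fit$reason else incl$reason)
    }, error = function(e)
      data.frame(config = config, true_beamwidth = NA_real_,
                 est_beamwidth = NA_real_, bw_error = NA_real_,
                 axis_error_cm = NA_real_, r_squared = NA_real_,
                 n_channels = NA_integer_, fit_ok = FALSE,
                 included = FALSE, reason = conditionMessage(e)))
    out[[i]] <- cbind(grid[i, , drop = FALSE], res)
  }
  surface <- do.call(rbind, out)
  rownames(surface) <- NULL
  attr(surface, "seed") <- seed
  attr(surface, "noise_snr") <- noise_snr
  attr(surface, "mode") <- mode
  class(surface) <- c("error_surface", "data.frame")
  surface
}

#' Derive an inclusion region from an error surface
#'
#' Largest rectangular region in (|bearing|, |displacement|) space whose
#' worst-case absolute beamwidth error stays within the budget.
#'
#' @param surface an `error_surface`.
#' @param error_budget degrees.
#' @return list `bearing_max` (deg), `displacement_max` (m),
#'   `worst_error` (deg inside the region), `feasible` (data.frame of all
#'   candidate rectangles).
#' @export
derive_inclusion_mask <- function(surface, error_budget) {
  ok <- !is.na(surface$bw_error)
  s <- surface[ok, ]
  bs <- sort(unique(s$bearing))
  ds <- sort(unique(s$displacement))
  rows <- expand.grid(bearing_max = bs, displacement_max = ds)
  rows$worst <- mapply(function(b, d) {
    inside <- s$bearing <= b & s$displacement <= d
    if (!any(inside)) return(NA_real_)
    max(abs(s$bw_error[inside]))
  }, rows$bearing_max, rows$displacement_max)
  rows$feasible <- !is.na(rows$worst) & rows$worst <= error_budget
  if (!any(rows$feasible))
    return(list(bearing_max = NA_real_, displacement_max = NA_real_,
                worst_error = NA_real_, feasible = rows))
  area <- rows$bearing_max * rows$displacement_max
  area[!rows$feasible] <- -Inf
  best <- which.max(area)
  list(bearing_max = rows$bearing_max[best],
       displacement_max = rows$displacement_max[best],
       worst_error = rows$worst[best], feasible = rows)
}

#' Summarize an error surface against the published bounds
#'
#' @param surface an `error_surface`.
#' @return list with `max_bw_error_included`, `max_axis_error_cm_included`
#'   (over replicates satisfying the inclusion criteria with successful
#'   fits), `n_included`, `n_failed`, and the same maxima over all cells.
#' @export
summarize_error_surface <- function(surface) {
  ok <- !is.na(surface$bw_error) & surface$fit_ok
  inc <- ok & surface$included
  list(max_bw_error_included = max(abs(surface$bw_error[inc])),
       max_axis_error_cm_included = max(surface$axis_error_cm[inc]),
       n_included = sum(inc), n_failed = sum(is.na(surface$bw_error)),
       max_bw_error_all = max(abs(surface$bw_error[ok])),
       max_axis_error_cm_all = max(surface$axis_error_cm[ok]))
}
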