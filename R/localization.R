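#' Source localization from hydrophone arrival-time differences
#'
#' Nonlinear least-squares solution of the hyperbolic range-difference
#' equations at c = 1500 m/s.  For the linear array the left/right and
#' vertical ambiguities are resolved by constraining the source to the
#' half-space y > 0 and the array's horizontal plane z = 0.
#'
#' @name localization
NULL

#' Arrival-time differences relative to a reference channel
#'
#' @param peak_times per-channel envelope peak times, s (already refined
#'   to sub-sample precision at detection).
#' @param ref reference channel index; default the last-arriving strongest
#'   assumption is avoided by using the channel given, or the first.
#' @return list `tdoa` (t_i - t_ref, s), `ref`.
#' @export
tdoa_estimate <- function(peak_times, ref = 1L) {
  peak_times <- as.numeric(peak_times)
  if (sum(is.finite(peak_times)) < 2L) stop("too few channels")
  list(tdoa = peak_times - peak_times[ref], ref = as.integer(ref))
}

#' Localize the source of one click
#'
#' @param tdoas output of [tdoa_estimate()] (or a numeric vector of
#'   t_i - t_ref with attribute-free reference 1).
#' @param geometry an `array_geometry`.
#' @param sound_speed m/s.
#' @param init initial position; default the geometry's target.
#' @param plane_z0 constrain the fix to z = 0 (default for the linear
#'   array, whose vertical direction is unobservable).
#' @param residual_tol rms TDOA misfit (s) above which the fix is flagged
#'   for geometric dilution.
#' @return list of class `source_fix`: `position`, `range` (to the array
#'   centre), `azimuth`, `elevation` (degrees), `residual` (rms s),
#'   `dilution_flag`, `ref`.
#' @export
localize_source <- function(tdoas, geometry, sound_speed = 1500,
                            init = NULL, plane_z0 = NULL,
                            residual_tol = 2e-6) {
  if (is.numeric(tdoas)) tdoas <- list(tdoa = tdoas, ref = 1L)
  keep <- which(is.finite(tdoas$tdoa))
  if (length(keep) < 3L) stop("need TDOAs from at least 3 channels")
  if (is.null(plane_z0)) plane_z0 <- geometry$label == "linear"
  if (is.null(init)) init <- geometry$target_position
  pos_h <- geometry$positions[keep, , drop = FALSE]
  td <- tdoas$tdoa[keep]
  ref_row <- which(keep == tdoas$ref)
  if (length(ref_row) == 0L) stop("reference channel not among finite TDOAs")
  # residuals in metres (range-difference misfit) for optimizer
  # scaling; the common emission-time offset is profiled out, which
  # makes the objective symmetric in the channels rather than tied to
  # the reference
  obj <- function(p) {
    pos <- if (plane_z0) c(p[1], p[2], 0) else p
    rng <- sqrt(rowSums(sweep(pos_h, 2, pos)^2))
    resid <- rng - td * sound_speed
    sum((resid - mean(resid))^2)
  }
  p0 <- if (plane_z0) init[1:2] else init
  lower <- if (plane_z0) c(-Inf, 1e-3) else rep(-Inf, 3)
  fit <- stats::optim(p0, obj, method = "L-BFGS-B", lower = lower,
                      control = list(factr = 1e3, maxit = 500L))
  pos <- if (plane_z0) c(fit$par[1], fit$par[2], 0) else fit$par
  resid <- sqrt(fit$value / length(td)) / sound_speed
  bearing <- bearing_to_centre(pos)
  structure(list(position = pos, range = vnorm(pos),
                 azimuth = bearing[["azimuth"]],
                 elevation = bearing[["elevation"]],
                 residual = resid,
                 dilution_flag = resid > residual_tol,
                 ref = tdoas$ref, plane_z0 = plane_z0),
            class = "source_fix")
}

#' Bearing of a position relative to the array normal
#'
#' Azimuth and elevation (degrees) of the centre-to-source line relative
#' to the array normal (+y toward the animal), decomposed horizontally
#' (x) and vertically (z).
#'
#' @param position 3-vector m (or a `source_fix`).
#' @return named numeric `c(azimuth, elevation)`.
#' @export
bearing_to_centre <- function(position) {
  if (inherits(position, "source_fix")) position <- position$position
  if (vnorm(position) < 1e-12) stop("fix at the origin has no bearing")
  c(azimuth = rad2deg(atan2(position[1], position[2])),
    elevation = rad2deg(atan2(position[3], position[2])))
}

#' Back-compute the emission time of a click
#'
#' @param fix a `source_fix`.
#' @param arrival_time envelope peak time on the reference channel, s.
#' @param geometry an `array_geometry`.
#' @param sound_speed m/s.
#' @return emission time, s.
#' @export
emission_time <- function(fix, arrival_time, geometry, sound_speed = 1500) {
  r_ref <- vnorm(fix$position - geometry$positions[fix$ref, ])
  arrival_time - r_ref / sound_speed
}

#' @export
print.source_fix <- function(x, ...) {
  cat(sprintf(
    "<source_fix: (%.3f, %.3f, %.3f) m, range %.3f m, az %.2f deg, el %.2f deg, rms %.2e s>\n",
    x$position[1], x$position[2], x$position[3], x$range, x$azimuth,
    x$elevation, x$residual))
  invisible(x)
}
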