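#' Circular-piston beam model
#'
#' Classical flat circular piston in an infinite baffle: the radiated
#' energy at off-axis angle theta relative to the on-axis energy is
#' D(theta) = (2 J1(ka sin theta) / (ka sin theta))^2, with k = 2 pi f / c
#' the wavenumber and a = d/2 the piston radius.  Broadband directivity is
#' the energy-weighted average of the narrowband ratio over the spectrum
#' bins of the emitted click.
#'
#' @name beam_model
NULL

# Root of 2 J1(x)/x = 1/sqrt(2): the half-power argument of the piston
# pattern.  Solved once at load time.
.piston_halfpower_x <- local({
  f <- function(x) 2 * besselJ(x, 1) / x - 1 / sqrt(2)
  stats::uniroot(f, c(1, 2), tol = 1e-12)$root
})

#' Piston specification
#'
#' @param diameter piston diameter d, metres (> 0).
#' @param frequency narrowband frequency, Hz; ignored when `spectrum` given.
#' @param spectrum optional broadband description: a data.frame or list
#'   with elements `frequency` (Hz) and `energy` (non-negative weights,
#'   arbitrary scale).
#' @param sound_speed m/s.
#' @return list of class `piston_spec`.
#' @export
piston_spec <- function(diameter, frequency = 130e3, spectrum = NULL,
                        sound_speed = 1500) {
  stopifnot(diameter > 0)
  if (!is.null(spectrum)) {
    stopifnot(all(spectrum$energy >= 0), sum(spectrum$energy) > 0)
  }
  structure(list(diameter = diameter, frequency = frequency,
                 spectrum = spectrum, sound_speed = sound_speed),
            class = "piston_spec")
}

# Narrowband energy directivity at x = ka sin(theta); handles x -> 0.
.piston_ratio <- function(x) {
  x <- abs(x)
  out <- rep(1, length(x))
  nz <- x > 1e-8 & x <= 1e4
  out[nz] <- (2 * besselJ(x[nz], 1) / x[nz])^2
  big <- x > 1e4  # envelope of the asymptotic form, besselJ overflows
  out[big] <- 8 / (pi * x[big]^3)
  out
}

# Tabulated version for the Monte-Carlo fit inner loop: linear
# interpolation on a 5e-4 grid (error < 1e-7; besselJ is ~50x slower).
.ratio_cache <- new.env(parent = emptyenv())
.piston_ratio_fast <- function(x) {
  x <- abs(x)
  if (is.null(.ratio_cache$x)) {
    .ratio_cache$x <- seq(0, 120, by = 5e-4)
    .ratio_cache$y <- .piston_ratio(.ratio_cache$x)
  }
  h <- 5e-4
  xi <- pmin(x, 120) / h
  i0 <- pmin(floor(xi), length(.ratio_cache$x) - 2L)
  w <- xi - i0
  out <- .ratio_cache$y[i0 + 1L] * (1 - w) + .ratio_cache$y[i0 + 2L] * w
  big <- which(x > 120)
  if (length(big)) out[big] <- .piston_ratio(x[big])
  out
}

#' Piston energy directivity D(theta)
#'
#' @param spec a `piston_spec`.
#' @param theta_deg off-axis angle(s), degrees, |theta| <= 90.
#' @return energy ratio(s) in `[0, 1]`; D(0) = 1.
#' @export
piston_directivity <- function(spec, theta_deg) {
  stopifnot(all(abs(theta_deg) <= 90))
  a <- spec$diameter / 2
  st <- sin(deg2rad(theta_deg))
  if (is.null(spec$spectrum)) {
    k <- 2 * pi * spec$frequency / spec$sound_speed
    return(.piston_ratio(k * a * st))
  }
  w <- spec$spectrum$energy / sum(spec$spectrum$energy)
  ka <- 2 * pi * spec$spectrum$frequency / spec$sound_speed * a
  # rows: spectrum bins, cols: angles
  m <- .piston_ratio(outer(ka, st))
  dim(m) <- c(length(ka), length(st))
  as.numeric(crossprod(w, m))
}

#' Full -3 dB (half-power) beamwidth of a piston
#'
#' @param spec a `piston_spec`.
#' @return full angle in degrees within which radiated energy is within
#'   3 dB of the on-axis maximum.
#' @export
piston_beamwidth <- function(spec) {
  if (is.null(spec$spectrum)) {
    ka <- 2 * pi * spec$frequency / spec$sound_speed * spec$diameter / 2
    if (ka <= .piston_halfpower_x)
      stop("beam wider than the hemisphere: ka too small")
    return(2 * rad2deg(asin(.piston_halfpower_x / ka)))
  }
  f <- function(th) piston_directivity(spec, th) - 0.5
  if (f(90) > 0) stop("beam wider than the hemisphere")
  2 * stats::uniroot(f, c(1e-6, 90), tol = 1e-9)$root
}

#' Directivity index of a piston
#'
#' DI = 10 log10(4 pi / integral of D over solid angle), integrating the
#' axially symmetric pattern over the front hemisphere (back radiation
#' taken as zero).
#'
#' @param spec a `piston_spec`.
#' @return dB.
#' @export
directivity_index <- function(spec) {
  integrand <- function(th_rad)
    piston_directivity(spec, rad2deg(th_rad)) * sin(th_rad)
  I <- stats::integrate(integrand, 0, pi / 2, rel.tol = 1e-9,
                        subdivisions = 500L)$value
  db(2 / I)
}

#' Piston diameter from a -3 dB beamwidth
#'
#' Inverse of [piston_beamwidth()]: finds d such that the piston at the
#' given frequency has the requested full half-power beamwidth.
#'
#' @param beamwidth_deg full -3 dB beamwidth, degrees.
#' @param frequency Hz.
#' @param sound_speed m/s.
#' @param interval diameter search interval, m.
#' @return diameter, m.
#' @export
inverse_beamwidth <- function(beamwidth_deg, frequency = 130e3,
                              sound_speed = 1500,
                              interval = c(0.01, 0.30)) {
  f <- function(d)
    piston_beamwidth(piston_spec(d, frequency, sound_speed = sound_speed)) -
      beamwidth_deg
  lo <- f(interval[1]); hi <- f(interval[2])
  if (lo < 0 || hi > 0)
    stop("beamwidth not achievable for a diameter in the search interval")
  stats::uniroot(f, interval, tol = 1e-10)$root
}

#' Export a directivity curve
#'
#' @param spec a `piston_spec`.
#' @param theta_deg angle grid, degrees.
#' @return data.frame with `theta_deg`, `d_ratio`, `d_db`.
#' @export
directivity_curve <- function(spec, theta_deg = seq(0, 90, by = 0.1)) {
  D <- piston_directivity(spec, theta_deg)
  data.frame(theta_deg = theta_deg, d_ratio = D, d_db = db(pmax(D, 1e-12)))
}
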