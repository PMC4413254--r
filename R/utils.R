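# Internal signal-processing and small-numeric helpers.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

db <- function(x) 10 * log10(x)
undb <- function(x) 10^(x / 10)

#' @keywords internal
#' @noRd
vnorm <- function(v) sqrt(sum(v^2))

# Envelope of the analytic signal, optionally band-limited first and
# smoothed with a short moving average (seconds).
analytic_envelope <- function(x, fs, band = NULL, smooth = 0) {
  n <- length(x)
  if (n == 0L) stop("empty signal")
  X <- stats::fft(x)
  f <- seq(0, fs, length.out = n + 1L)[seq_len(n)]
  f[f > fs / 2] <- f[f > fs / 2] - fs
  if (!is.null(band)) {
    keep <- abs(f) >= band[1] & abs(f) <= band[2]
    X[!keep] <- 0
  }
  # analytic signal: zero the negative frequencies, double the positive
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) {
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[2:((n + 1) / 2)] <- 2
  }
  env <- Mod(stats::fft(X * h, inverse = TRUE) / n)
  if (smooth > 0) {
    w <- max(1L, round(smooth * fs))
    if (w > 1L) {
      kernel <- rep(1 / w, w)
      env <- stats::filter(env, kernel, sides = 2)
      env[is.na(env)] <- 0
      env <- as.numeric(env)
    }
  }
  env
}

# Zero-phase FFT brick-wall bandpass.
fft_bandpass <- function(x, fs, band) {
  n <- length(x)
  X <- stats::fft(x)
  f <- seq(0, fs, length.out = n + 1L)[seq_len(n)]
  f[f > fs / 2] <- f[f > fs / 2] - fs
  X[abs(f) < band[1] | abs(f) > band[2]] <- 0
  Re(stats::fft(X, inverse = TRUE) / n)
}

# Vertex of the parabola through three (x, y) points; x need not be
# equidistant.  Returns c(x0, y0).
parabola_vertex <- function(x, y) {
  stopifnot(length(x) == 3L, length(y) == 3L)
  co <- solve(cbind(1, x, x^2), y)
  if (abs(co[3]) < .Machine$double.eps) stop("collinear points, no vertex")
  x0 <- -co[2] / (2 * co[3])
  y0 <- co[1] + co[2] * x0 + co[3] * x0^2
  unname(c(x0, y0))
}

# Refine the index of a sampled peak by parabolic interpolation of
# log-amplitude (exact for a Gaussian envelope).  Returns fractional index.
refine_peak <- function(env, i) {
  n <- length(env)
  if (i <= 1L || i >= n) return(as.numeric(i))
  y <- env[(i - 1L):(i + 1L)]
  if (any(y <= 0)) return(as.numeric(i))
  y <- log(y)
  d <- y[1] - 2 * y[2] + y[3]
  if (d >= 0) return(as.numeric(i))
  i + (y[1] - y[3]) / (2 * d)
}
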