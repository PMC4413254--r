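#' Tag-channel echograms and relative output levels
#'
#' Click-synchronized stack plots of received sound envelopes on the
#' animal-borne tag: one row per outgoing click, delay axis convertible
#' to target range via one-half of the sound speed (1500 m/s assumed).
#'
#' @name tag_echogram
NULL

#' Build a click-synchronized echogram
#'
#' For each outgoing click the tag envelope segment `[0, window]` after
#' emission is extracted; echoes arriving after the next click appear
#' repeatedly in consecutive rows.
#'
#' @param tag_channel tag pressure samples.
#' @param fs Hz.
#' @param click_times outgoing click (emission) times on the tag, s.
#' @param window_s row length, s (default 3.3 ms).
#' @param smooth envelope moving-average length, s.
#' @return list of class `echogram`: `rows` (clicks x delay-bins matrix
#'   of envelope values), `delay_s`, `range_m`, `click_times`,
#'   `truncated` (logical per row).
#' @export
build_echogram <- function(tag_channel, fs, click_times,
                           window_s = 3.3e-3, smooth = 20e-6) {
  if (length(click_times) == 0L) stop("no clicks")
  env <- analytic_envelope(tag_channel, fs, band = c(100e3, 200e3),
                           smooth = smooth)
  nb <- round(window_s * fs)
  rows <- matrix(NA_real_, length(click_times), nb)
  truncated <- logical(length(click_times))
  for (k in seq_along(click_times)) {
    i0 <- round(click_times[k] * fs) + 1L
    i1 <- i0 + nb - 1L
    if (i1 > length(env)) {
      truncated[k] <- TRUE
      i1 <- length(env)
    }
    if (i0 <= length(env))
      rows[k, seq_len(i1 - i0 + 1L)] <- env[i0:i1]
  }
  delay <- (seq_len(nb) - 1L) / fs
  structure(list(rows = rows, delay_s = delay,
                 range_m = delay_to_range(delay),
                 click_times = click_times, truncated = truncated),
            class = "echogram")
}

#' Convert echo delay to target range
#'
#' range = delay * c / 2.
#'
#' @param delay s (>= 0).
#' @param sound_speed m/s.
#' @return m.
#' @export
delay_to_range <- function(delay, sound_speed = 1500) {
  if (any(delay < 0)) stop("negative delay")
  delay * sound_speed / 2
}

#' Relative apparent output level series
#'
#' Each click's tag-recorded energy flux density relative to the trial
#' maximum (<= 0 dB).
#'
#' @param efd_db per-click tag energies, dB.
#' @return dB (<= 0).
#' @export
raol_series <- function(efd_db) {
  if (length(efd_db) == 0L) stop("empty click list")
  efd_db - max(efd_db)
}

#' Delay of the strongest echo per echogram row
#'
#' Helper for tracking a target ridge: the delay of the envelope maximum
#' in each row after masking the outgoing click.
#'
#' @param echogram an `echogram`.
#' @param blank_s initial delay to ignore (the outgoing click), s.
#' @return numeric vector of delays, s.
#' @export
echogram_ridge <- function(echogram, blank_s = 3e-4) {
  vapply(seq_len(nrow(echogram$rows)), function(k) {
    row <- echogram$rows[k, ]
    row[echogram$delay_s < blank_s] <- -Inf
    row[is.na(row)] <- -Inf
    echogram$delay_s[which.max(row)]
  }, numeric(1))
}

#' @export
print.echogram <- function(x, ...) {
  cat(sprintf("<echogram: %d clicks x %d delay bins (%.1f ms window)>\n",
              nrow(x$rows), ncol(x$rows), 1e3 * max(x$delay_s)))
  invisible(x)
}
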