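#' Hydrophone-array geometries
#'
#' Coordinate convention: origin at the array centre, +y pointing from the
#' array toward the approaching animal, x horizontal in the array plane and
#' z vertical.  The linear array lies along x at depth z = 0; the star
#' arrays occupy the x-z plane at y = 0.
#'
#' @name geometry
NULL

#' Construct a hydrophone
#'
#' @param id integer id, unique within an array.
#' @param position numeric 3-vector, metres (x, y, z).
#' @param sensitivity_offset relative channel sensitivity correction in dB
#'   applied to received levels (0 = nominal).
#' @return list of class `hydrophone`.
#' @export
hydrophone <- function(id, position, sensitivity_offset = 0) {
  stopifnot(length(position) == 3L, is.finite(sensitivity_offset))
  structure(list(id = as.integer(id), position = as.numeric(position),
                 sensitivity_offset = as.numeric(sensitivity_offset)),
            class = "hydrophone")
}

#' Construct an array geometry
#'
#' @param positions numeric matrix, one hydrophone per row, columns x, y, z
#'   in metres.
#' @param target_position numeric 3-vector, metres.
#' @param label one of `"linear"`, `"star_large"`, `"star_small"`.
#' @param sensitivity numeric vector of per-channel sensitivity offsets, dB.
#' @return object of class `array_geometry` with elements `positions`
#'   (n x 3 matrix), `sensitivity`, `ids`, `target_position`, `label`.
#' @export
array_geometry <- function(positions, target_position, label,
                           sensitivity = NULL) {
  positions <- as.matrix(positions)
  stopifnot(ncol(positions) == 3L, nrow(positions) >= 2L)
  label <- match.arg(label, c("linear", "star_large", "star_small"))
  n <- nrow(positions)
  if (is.null(sensitivity)) sensitivity <- numeric(n)
  stopifnot(length(sensitivity) == n, all(is.finite(sensitivity)))
  if (label != "linear") {
    d0 <- sqrt(rowSums(positions^2))
    if (min(d0) > 1e-9)
      stop("star arrays must have a hydrophone at the array centre")
    if (any(abs(positions[, 2]) > 1e-9))
      stop("star-array hydrophones must be coplanar (y = 0)")
  }
  structure(list(positions = unname(positions),
                 sensitivity = as.numeric(sensitivity),
                 ids = seq_len(n),
                 target_position = as.numeric(target_position),
                 label = label),
            class = "array_geometry")
}

#' @export
print.array_geometry <- function(x, ...) {
  cat(sprintf("<array_geometry '%s': %d hydrophones, target at (%.2f, %.2f, %.2f) m>\n",
              x$label, nrow(x$positions), x$target_position[1],
              x$target_position[2], x$target_position[3]))
  invisible(x)
}

#' Number of hydrophones in an array
#' @param geometry an `array_geometry`.
#' @export
n_hydrophones <- function(geometry) nrow(geometry$positions)

#' Build the 8-element linear array
#'
#' Eight hydrophones spaced 0.6 m apart along x at y = z = 0, spanning
#' -2.1 ... +2.1 m, with the target 3 m in front of the array centre.
#'
#' @return an `array_geometry` labelled `"linear"`.
#' @export
build_linear_array <- function() {
  x <- seq(-2.1, 2.1, by = 0.6)
  pos <- cbind(x, 0, 0)
  array_geometry(pos, target_position = c(0, 3, 0), label = "linear")
}

# Cumulative arm offsets (m) reproducing the printed inter-hydrophone
# spacings; diagonal values carry 1 mm rounding.
.star_offsets <- list(
  large = list(axis = c(5, 15, 30, 50, 75, 105) / 100,
               diag = c(14.1, 28.2, 49.4, 77.7, 113.1) / 100),
  small = list(axis = c(5, 10, 15, 30, 55) / 100,
               diag = c(7.1, 14.2, 28.3, 49.5) / 100)
)

#' Build a star-shaped array
#'
#' 8 arms (4 axis-aligned, 4 diagonal) plus a centre hydrophone in the x-z
#' plane.  The `"large"` configuration extends to 1.05-1.13 m from the
#' centre for long-range recordings; the `"small"` configuration extends to
#' 0.5 m with the target displaced outward to 0.4 m for short ranges.
#'
#' @param config `"large"` or `"small"`.
#' @param target_standoff distance (m) from the array centre to the target
#'   along +y; defaults 0.05 (large) and 0.40 (small).
#' @return an `array_geometry` labelled `"star_large"` or `"star_small"`.
#' @export
build_star_array <- function(config = c("large", "small"),
                             target_standoff = NULL) {
  config <- match.arg(config)
  off <- .star_offsets[[config]]
  if (is.null(target_standoff))
    target_standoff <- if (config == "large") 0.05 else 0.40
  # arm unit vectors in the x-z plane
  axis_dirs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 0, 1), c(0, 0, -1))
  s <- 1 / sqrt(2)
  diag_dirs <- rbind(c(s, 0, s), c(-s, 0, s), c(s, 0, -s), c(-s, 0, -s))
  pos <- rbind(
    c(0, 0, 0),
    do.call(rbind, lapply(seq_len(4), function(k)
      outer(off$axis, axis_dirs[k, ]))),
    do.call(rbind, lapply(seq_len(4), function(k)
      outer(off$diag, diag_dirs[k, ]))))
  array_geometry(pos, target_position = c(0, target_standoff, 0),
                 label = paste0("star_", config))
}

#' Effective angular resolution of an array
#'
#' The finest angle a pair of hydrophones can resolve:
#' EAR = atan(spacing / range), in degrees.
#'
#' @param spacing hydrophone spacing, m (> 0).
#' @param range source range, m (> 0).
#' @return degrees.
#' @export
effective_angular_resolution <- function(spacing, range) {
  if (any(spacing <= 0) || any(range <= 0))
    stop("spacing and range must be positive")
  rad2deg(atan(spacing / range))
}

#' Serialize / read an array geometry as JSON
#'
#' Format: `{label, hydrophones: [{id, xyz_m, sens_db}], target_xyz_m}`.
#'
#' @param geometry an `array_geometry`.
#' @param path file path.
#' @export
write_geometry_json <- function(geometry, path) {
  hyd <- lapply(seq_len(nrow(geometry$positions)), function(i)
    list(id = geometry$ids[i],
         xyz_m = geometry$positions[i, ],
         sens_db = geometry$sensitivity[i]))
  obj <- list(label = geometry$label, hydrophones = hyd,
              target_xyz_m = geometry$target_position)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_geometry_json
#' @export
read_geometry_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  array_geometry(do.call(rbind, obj$hydrophones$xyz_m),
                 target_position = obj$target_xyz_m,
                 label = obj$label,
                 sensitivity = obj$hydrophones$sens_db)
}
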