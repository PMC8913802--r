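#' Detector arrays
#'
#' A detector array is a data frame with one row per acoustic sensor and
#' columns `detector_id`, `x` and `y` (planar metres, x east / y north).
#' Spatial count models need at least two detectors so that counts carry
#' spatial information.
#'
#' @param detector_id character vector of unique sensor labels.
#' @param x,y numeric coordinates in metres.
#' @return A `detector_array` (also a `data.frame`).
#' @export
detector_array <- function(detector_id, x, y) {
  detector_id <- as.character(detector_id)
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(detector_id) != length(x) || length(x) != length(y)) {
    stop_invalid("detector_id, x and y must have equal length")
  }
  if (length(detector_id) < 2L) {
    stop_invalid("a detector array needs at least 2 detectors")
  }
  if (anyDuplicated(detector_id)) {
    stop_invalid("detector ids must be unique")
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop_invalid("detector coordinates must be finite")
  }
  structure(
    data.frame(detector_id = detector_id, x = x, y = y,
               stringsAsFactors = FALSE),
    class = c("detector_array", "data.frame")
  )
}

#' Build a regular grid of detectors
#'
#' Lays out `nx * ny` sensors on a rectangular grid, the standard acoustic
#' survey design (the motivating surveys used 5 x 5 grids at 400 m spacing,
#' giving a 1600 m x 1600 m envelope).
#'
#' @param nx,ny number of columns and rows of sensors.
#' @param spacing distance between adjacent sensors, metres (> 0).
#' @param origin coordinates of the south-west sensor, metres.
#' @return A [detector_array()].
#' @examples
#' a <- make_grid_array(5, 5, 400)
#' nrow(a)           # 25
#' diff(range(a$x))  # 1600
#' @export
make_grid_array <- function(nx, ny, spacing, origin = c(0, 0)) {
  if (!is.numeric(nx) || !is.numeric(ny) || nx < 1 || ny < 1) {
    stop_invalid("nx and ny must be counts >= 1")
  }
  if (!is.numeric(spacing) || length(spacing) != 1L || spacing <= 0) {
    stop_invalid("spacing must be a positive number of metres")
  }
  nx <- as.integer(nx); ny <- as.integer(ny)
  if (nx * ny < 2L) {
    stop_invalid("grid must contain at least 2 detectors (nx * ny >= 2)")
  }
  g <- expand.grid(ix = seq_len(nx) - 1L, iy = seq_len(ny) - 1L)
  detector_array(
    detector_id = sprintf("D%03d", seq_len(nrow(g))),
    x = origin[1] + g$ix * spacing,
    y = origin[2] + g$iy * spacing
  )
}

#' @export
print.detector_array <- function(x, ...) {
  cat(sprintf("Detector array: %d sensors, envelope %.0f m x %.0f m\n",
              nrow(x), diff(range(x$x)), diff(range(x$y))))
  NextMethod()
}

# J x 2 coordinate matrix
trap_matrix <- function(array) {
  as.matrix(array[, c("x", "y")])
}
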