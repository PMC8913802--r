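#' Posterior density surface
#'
#' Turns retained (z, s) snapshots into a pixel raster of posterior mean
#' density: each pixel's value is the mean (over snapshots) number of
#' included activity centres falling in the pixel, divided by the pixel area
#' in hectares. Mass is conserved exactly: summing `value * pixel_ha` over
#' the raster returns the snapshot-mean abundance.
#'
#' @param draws a `posterior_draws` object from [run_chains()], or a
#'   snapshot data frame with columns `chain`, `iteration`, `x`, `y`, `z`.
#' @param state_space the [state_space()] the raster should cover (taken
#'   from `draws` when available).
#' @param pixel_size pixel side, metres (> 0). Default 100 m: well below
#'   detector spacing but coarse enough that per-pixel values stay
#'   interpretable.
#' @return A `density_raster`: list with `origin` (lower-left corner),
#'   `pixel_size`, `nx`, `ny` and `values` (ny x nx matrix, row 1 = southern
#'   row, in individuals per hectare).
#' @export
rasterize_density <- function(draws, state_space = NULL, pixel_size = 100) {
  if (!is.numeric(pixel_size) || pixel_size <= 0) {
    stop_invalid("pixel_size must be positive (metres)")
  }
  if (inherits(draws, "posterior_draws")) {
    state_space <- state_space %||% draws$state_space
    snap <- draws$snapshots
  } else {
    snap <- as.data.frame(draws)
  }
  if (is.null(state_space)) stop_invalid("state_space is required")
  if (!nrow(snap)) stop_invalid("no snapshots to rasterize")
  n_snap <- nrow(unique(snap[, c("chain", "iteration")]))
  inc <- snap[snap$z > 0, , drop = FALSE]

  nx <- max(1L, ceiling((state_space$xmax - state_space$xmin) / pixel_size - 1e-9))
  ny <- max(1L, ceiling((state_space$ymax - state_space$ymin) / pixel_size - 1e-9))
  ix <- pmin(pmax(floor((inc$x - state_space$xmin) / pixel_size) + 1L, 1L), nx)
  iy <- pmin(pmax(floor((inc$y - state_space$ymin) / pixel_size) + 1L, 1L), ny)
  totals <- matrix(0, ny, nx)
  if (nrow(inc)) {
    tab <- table(factor((ix - 1L) * ny + iy, levels = seq_len(nx * ny)))
    totals <- matrix(as.numeric(tab), ny, nx)
  }
  pixel_ha <- pixel_size^2 / 1e4
  structure(
    list(origin = c(state_space$xmin, state_space$ymin),
         pixel_size = pixel_size, nx = nx, ny = ny,
         n_snapshots = n_snap,
         values = totals / n_snap / pixel_ha),
    class = "density_raster"
  )
}

#' @export
print.density_raster <- function(x, ...) {
  cat(sprintf(
    "Density raster: %d x %d pixels of %.0f m (mean %.4f, max %.4f per ha)\n",
    x$nx, x$ny, x$pixel_size, mean(x$values), max(x$values)))
  invisible(x)
}

# pixel-centre coordinates as a data.frame(x, y, value)
raster_centres <- function(raster) {
  xs <- raster$origin[1] + (seq_len(raster$nx) - 0.5) * raster$pixel_size
  ys <- raster$origin[2] + (seq_len(raster$ny) - 0.5) * raster$pixel_size
  data.frame(x = rep(xs, each = raster$ny), y = rep(ys, times = raster$nx),
             value = as.vector(raster$values))
}

#' Forest categories as labelled polygons
#'
#' @param polygons list of polygons, each a list with `coords` (closed or
#'   open ring as a 2-column matrix), `category` (label) and optional `id`.
#' @return A `category_map`.
#' @export
category_map <- function(polygons) {
  if (!length(polygons)) stop_invalid("category map needs at least one polygon")
  polygons <- lapply(seq_along(polygons), function(i) {
    p <- polygons[[i]]
    coords <- as.matrix(p$coords)
    if (ncol(coords) != 2 || nrow(coords) < 3) {
      stop_invalid("each polygon needs >= 3 vertices with x, y columns")
    }
    # drop an explicit closing vertex; the ring is treated as closed
    if (all(coords[1, ] == coords[nrow(coords), ]) && nrow(coords) > 3) {
      coords <- coords[-nrow(coords), , drop = FALSE]
    }
    if (is.null(p$category) || !nzchar(p$category)) {
      stop_invalid("every polygon needs a non-empty category label")
    }
    list(coords = coords, category = as.character(p$category),
         id = as.character(p$id %||% paste0("poly_", i)))
  })
  structure(list(polygons = polygons), class = "category_map")
}

# Even-odd ray-casting point-in-polygon; points on an edge count as inside
# on one side only, which is immaterial at raster resolution.
point_in_polygon <- function(px, py, coords) {
  n <- nrow(coords)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- coords[i, 1]; yi <- coords[i, 2]
    xj <- coords[j, 1]; yj <- coords[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Summarise density by forest category
#'
#' Overlays a density raster on a polygon map: each pixel is assigned to a
#' polygon if its centre falls inside (no area weighting); each polygon gets
#' the mean of its pixel values; each category gets the mean over its
#' polygons and a standard error from the among-polygon standard deviation
#' (`sd / sqrt(n_polygons)`, `NA` for single-polygon categories). Polygons
#' containing no pixel centres are dropped with a warning.
#'
#' @param raster a `density_raster`.
#' @param map a [category_map()].
#' @return Data frame with columns `category`, `n_polygons`, `mean_density`,
#'   `se`.
#' @export
category_density <- function(raster, map) {
  stopifnot(inherits(raster, "density_raster"), inherits(map, "category_map"))
  centres <- raster_centres(raster)
  poly_means <- lapply(map$polygons, function(p) {
    inside <- point_in_polygon(centres$x, centres$y, p$coords)
    if (!any(inside)) {
      warning("polygon '", p$id, "' contains no pixel centres; excluded",
              call. = FALSE)
      return(NULL)
    }
    data.frame(id = p$id, category = p$category,
               mean = mean(centres$value[inside]))
  })
  poly_means <- do.call(rbind, poly_means)
  if (is.null(poly_means)) stop_invalid("no polygon overlaps the raster")
  out <- do.call(rbind, lapply(split(poly_means, poly_means$category), function(d) {
    data.frame(category = d$category[1], n_polygons = nrow(d),
               mean_density = mean(d$mean),
               se = if (nrow(d) > 1) stats::sd(d$mean) / sqrt(nrow(d)) else NA_real_)
  }))
  rownames(out) <- NULL
  out[order(out$category), , drop = FALSE]
}
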