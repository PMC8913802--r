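#' Read and write workflow files
#'
#' All tabular interchange is CSV; categories are GeoJSON (or a CSV vertex
#' list); rasters are ESRI ASCII grids; run configs are JSON or YAML by file
#' extension. Coordinates are planar metres throughout.
#'
#' * detectors: columns `detector_id`, `x`, `y`.
#' * counts: long format, columns `detector_id`, `night`, `count`; missing
#'   detector-nights are omitted from the counts file and declared in a
#'   sidecar mask CSV (`detector_id`, `night`; an empty/`NA` night masks the
#'   whole detector).
#' * paired design: columns `pair`, `control_before`, `treatment_before`,
#'   `control_after`, `treatment_after`.
#' * harvest records: columns `forest`, `years`, `area_ha`, `volume_m3`.
#'
#' @param path,mask_path file paths.
#' @param array,counts,design objects to write.
#' @name io
NULL

read_csv_checked <- function(path, required) {
  if (!file.exists(path)) stop_invalid("file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(d))
  if (length(missing)) {
    stop_invalid(path, ": missing column(s) ", paste(missing, collapse = ", "))
  }
  d
}

#' @rdname io
#' @export
read_detectors <- function(path) {
  d <- read_csv_checked(path, c("detector_id", "x", "y"))
  if (anyDuplicated(d$detector_id)) {
    line <- which(duplicated(d$detector_id))[1] + 1L
    stop_invalid(path, ": duplicate detector_id at line ", line)
  }
  bad <- which(!is.finite(d$x) | !is.finite(d$y))
  if (length(bad)) {
    stop_invalid(path, ": non-finite coordinates at line ", bad[1] + 1L)
  }
  detector_array(d$detector_id, d$x, d$y)
}

#' @rdname io
#' @export
write_detectors <- function(array, path) {
  utils::write.csv(as.data.frame(array)[, c("detector_id", "x", "y")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname io
#' @param detectors optional [detector_array()]; when given, count rows must
#'   reference its ids and the matrix follows its row order.
#' @export
read_counts <- function(path, mask_path = NULL, detectors = NULL) {
  d <- read_csv_checked(path, c("detector_id", "night", "count"))
  bad <- which(!is.finite(d$count) | d$count < 0 | d$count != floor(d$count))
  if (length(bad)) {
    stop_invalid(path, ": invalid count at line ", bad[1] + 1L)
  }
  mask <- if (!is.null(mask_path) && file.exists(mask_path)) {
    m <- utils::read.csv(mask_path, stringsAsFactors = FALSE)
    if (!"detector_id" %in% names(m)) {
      stop_invalid(mask_path, ": missing column detector_id")
    }
    if (!"night" %in% names(m)) m$night <- NA
    m
  } else {
    data.frame(detector_id = character(0), night = integer(0))
  }
  ids <- if (!is.null(detectors)) {
    unknown <- setdiff(unique(c(d$detector_id, mask$detector_id)),
                       detectors$detector_id)
    if (length(unknown)) {
      stop_invalid(path, ": unknown detector id(s): ",
                   paste(unknown, collapse = ", "))
    }
    detectors$detector_id
  } else {
    sort(unique(c(d$detector_id, mask$detector_id)))
  }
  K <- max(c(d$night, mask$night, 1), na.rm = TRUE)
  m <- matrix(NA_real_, length(ids), K, dimnames = list(ids, NULL))
  m[cbind(match(d$detector_id, ids), d$night)] <- d$count
  counts <- nightly_counts(m)
  unexplained <- is.na(counts$counts)
  if (nrow(mask)) {
    whole <- mask$detector_id[is.na(mask$night)]
    unexplained[match(whole, ids), ] <- FALSE
    cell <- mask[!is.na(mask$night), , drop = FALSE]
    if (nrow(cell)) {
      unexplained[cbind(match(cell$detector_id, ids), cell$night)] <- FALSE
    }
  }
  if (any(unexplained)) {
    rc <- which(unexplained, arr.ind = TRUE)[1, ]
    stop_invalid(path, ": detector ", ids[rc[1]], " night ", rc[2],
                 " neither reported nor masked")
  }
  counts
}

#' @rdname io
#' @export
write_counts <- function(counts, path, mask_path = NULL) {
  m <- counts$counts
  obs <- which(!is.na(m), arr.ind = TRUE)
  long <- data.frame(detector_id = rownames(m)[obs[, 1]],
                     night = obs[, 2], count = m[obs])
  long <- long[order(long$detector_id, long$night), ]
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  if (!is.null(mask_path)) {
    mis <- which(is.na(m), arr.ind = TRUE)
    mask <- data.frame(detector_id = rownames(m)[mis[, 1]], night = mis[, 2])
    mask <- mask[order(mask$detector_id, mask$night), ]
    utils::write.csv(mask, mask_path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @rdname io
#' @export
read_design <- function(path) {
  d <- read_csv_checked(path, c("pair", "control_before", "treatment_before",
                                "control_after", "treatment_after"))
  paired_design(d$pair, d$control_before, d$treatment_before,
                d$control_after, d$treatment_after)
}

#' @rdname io
#' @export
write_design <- function(design, path) {
  utils::write.csv(as.data.frame(design), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
read_harvest <- function(path) {
  d <- read_csv_checked(path, c("forest", "area_ha", "volume_m3"))
  bad <- which(d$area_ha <= 0 | d$volume_m3 < 0)
  if (length(bad)) stop_invalid(path, ": invalid harvest record at line ", bad[1] + 1L)
  d
}

#' Read forest categories
#'
#' GeoJSON (`.json`/`.geojson`): a FeatureCollection of Polygon or
#' MultiPolygon features, each with a `category` property (and optional
#' `id`); only outer rings are used. CSV fallback: an ordered vertex list
#' with columns `polygon_id`, `category`, `x`, `y`.
#'
#' @param path file path.
#' @return A [category_map()].
#' @export
read_categories <- function(path) {
  if (!file.exists(path)) stop_invalid("file not found: ", path)
  if (grepl("\\.(geo)?json$", path, ignore.case = TRUE)) {
    gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    feats <- gj$features %||% stop_invalid(path, ": not a GeoJSON FeatureCollection")
    polys <- list()
    for (f in feats) {
      cat_label <- f$properties$category %||%
        stop_invalid(path, ": feature without a 'category' property")
      id <- f$properties$id %||% NULL
      geom <- f$geometry
      rings <- switch(geom$type,
        Polygon = list(geom$coordinates[[1]]),
        MultiPolygon = lapply(geom$coordinates, function(p) p[[1]]),
        stop_invalid(path, ": unsupported geometry type ", geom$type)
      )
      for (r in seq_along(rings)) {
        coords <- do.call(rbind, lapply(rings[[r]], function(pt) {
          c(as.numeric(pt[[1]]), as.numeric(pt[[2]]))
        }))
        pid <- if (is.null(id)) NULL else if (length(rings) > 1) {
          paste0(id, "_", r)
        } else {
          id
        }
        polys[[length(polys) + 1L]] <-
          list(coords = coords, category = cat_label, id = pid)
      }
    }
    category_map(polys)
  } else {
    d <- read_csv_checked(path, c("polygon_id", "category", "x", "y"))
    polys <- lapply(split(d, d$polygon_id), function(p) {
      list(coords = cbind(p$x, p$y), category = p$category[1],
           id = as.character(p$polygon_id[1]))
    })
    category_map(unname(polys))
  }
}

#' Write a density raster as an ESRI ASCII grid
#'
#' Plain-text grid with the conventional lower-left-corner header; rows are
#' written north to south.
#'
#' @param raster a `density_raster`.
#' @param path output path (conventionally `.asc`).
#' @export
write_raster_asc <- function(raster, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", raster$nx),
    sprintf("nrows %d", raster$ny),
    sprintf("xllcorner %.6f", raster$origin[1]),
    sprintf("yllcorner %.6f", raster$origin[2]),
    sprintf("cellsize %.6f", raster$pixel_size),
    "NODATA_value -9999"
  ), con)
  for (r in rev(seq_len(raster$ny))) {
    writeLines(paste(format(raster$values[r, ], trim = TRUE, digits = 10),
                     collapse = " "), con)
  }
  invisible(path)
}

#' @rdname io
#' @param draws a `posterior_draws` object.
#' @param dir output directory (created if needed).
#' @export
write_draws <- function(draws, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- draws$draws
  long <- do.call(rbind, lapply(c("N", "D", "lambda0", "sigma", "psi"),
    function(p) data.frame(chain = d$chain, iteration = d$iteration,
                           parameter = p, value = d[[p]])))
  utils::write.csv(long, file.path(dir, "draws.csv"), row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(draws$snapshots, file.path(dir, "snapshots.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Read or write a run configuration (JSON or YAML by extension)
#'
#' @param path config path ending in `.json`, `.yaml` or `.yml`.
#' @param config a named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_invalid("file not found: ", path)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(config, path)
  } else {
    jsonlite::write_json(config, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
  }
  invisible(path)
}
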