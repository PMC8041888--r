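#' Lightweight in-memory raster grid
#'
#' A `raster_grid` is the raster currency of the package: a numeric matrix
#' with a north-up geotransform (top-left origin, square pixels) and a CRS
#' tag. Row 1 is the northernmost row; `NA` is the nodata marker. Cell
#' centers are at `origin + (index - 0.5) * pixel`.
#'
#' @param values numeric matrix (row 1 = north).
#' @param origin numeric length-2, map coordinates `(x, y)` of the top-left
#'   corner of the top-left pixel, in meters.
#' @param px pixel size in meters (square pixels).
#' @param crs free-text CRS tag; synthetic scenes use a local planar frame.
#' @return an object of class `raster_grid`.
#' @export
raster_grid <- function(values, origin = c(0, 0), px = 10, crs = "local-planar-m") {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.numeric(px) || length(px) != 1L || !is.finite(px) || px <= 0)
    stop("pixel size must be a single positive number")
  if (length(origin) != 2L || any(!is.finite(origin)))
    stop("origin must be two finite map coordinates (x, y)")
  structure(
    list(values = values, origin = as.numeric(origin), px = as.numeric(px),
         crs = as.character(crs)),
    class = "raster_grid")
}

#' @export
print.raster_grid <- function(x, ...) {
  v <- x$values
  cat(sprintf("<raster_grid> %d x %d px @ %g m, origin (%g, %g), crs '%s'\n",
              nrow(v), ncol(v), x$px, x$origin[1], x$origin[2], x$crs))
  rng <- suppressWarnings(range(v, na.rm = TRUE))
  cat(sprintf("  values: [%g, %g], %d nodata cells\n",
              rng[1], rng[2], sum(is.na(v))))
  invisible(x)
}

#' @export
dim.raster_grid <- function(x) dim(x$values)

#' @export
as.matrix.raster_grid <- function(x, ...) x$values

#' New grid sharing a template's geometry
#'
#' @param template a `raster_grid` supplying geotransform and CRS.
#' @param values matrix of the same dimensions (default: all `NA`).
#' @return a `raster_grid`.
#' @export
grid_like <- function(template, values = NULL) {
  stopifnot(inherits(template, "raster_grid"))
  if (is.null(values))
    values <- matrix(NA_real_, nrow(template$values), ncol(template$values))
  if (!is.matrix(values) || !all(dim(values) == dim(template$values)))
    stop("values do not match the template dimensions")
  raster_grid(values, template$origin, template$px, template$crs)
}

#' Check that rasters are co-registered
#'
#' Co-registration (same shape, origin, pixel size, CRS) is a precondition of
#' every pixelwise operation; mismatches are programming errors, not data.
#'
#' @param ... two or more `raster_grid` objects.
#' @return invisibly `TRUE`; stops on mismatch.
#' @export
check_coregistered <- function(...) {
  gs <- list(...)
  stopifnot(length(gs) >= 2L)
  ref <- gs[[1L]]
  for (g in gs[-1L]) {
    if (!inherits(g, "raster_grid") || !inherits(ref, "raster_grid"))
      stop("inputs must be raster_grid objects")
    if (!all(dim(g$values) == dim(ref$values)) ||
        any(abs(g$origin - ref$origin) > 1e-6) ||
        abs(g$px - ref$px) > 1e-9 || !identical(g$crs, ref$crs))
      stop("rasters are not co-registered (geotransform mismatch)")
  }
  invisible(TRUE)
}

#' Map coordinates of all cell centers
#'
#' @param grid a `raster_grid`.
#' @return list with `x` (length ncol) and `y` (length nrow) center coords.
#' @export
cell_centers <- function(grid) {
  d <- dim(grid$values)
  list(x = grid$origin[1] + (seq_len(d[2]) - 0.5) * grid$px,
       y = grid$origin[2] - (seq_len(d[1]) - 0.5) * grid$px)
}

#' Row/column indices of map points
#'
#' Points outside the raster get `NA` indices.
#'
#' @param grid a `raster_grid`.
#' @param x,y map coordinates.
#' @return data.frame with integer `row`, `col`.
#' @export
locate_cells <- function(grid, x, y) {
  d <- dim(grid$values)
  col <- floor((x - grid$origin[1]) / grid$px) + 1L
  row <- floor((grid$origin[2] - y) / grid$px) + 1L
  bad <- !is.finite(col) | !is.finite(row) | col < 1L | col > d[2] | row < 1L | row > d[1]
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' Read raster values at map points
#'
#' @inheritParams locate_cells
#' @return numeric vector; `NA` outside the raster or on nodata cells.
#' @export
extract_at <- function(grid, x, y) {
  rc <- locate_cells(grid, x, y)
  out <- rep(NA_real_, length(x))
  ok <- !is.na(rc$row)
  out[ok] <- grid$values[cbind(rc$row[ok], rc$col[ok])]
  out
}

#' Area of one pixel in hectares
#' @param grid a `raster_grid`.
#' @return hectares per pixel (`px^2 / 1e4`).
#' @export
pixel_area_ha <- function(grid) grid$px^2 / 1e4

# ---------------------------------------------------------------------------
# Scene collections

#' Ordered multi-date collection of co-registered rasters
#'
#' @param grids list (one element per date) of named lists of `raster_grid`
#'   objects, e.g. `list(list(red = ..., nir = ...), ...)`.
#' @param dates character or numeric date stamps, one per element of `grids`.
#' @return an object of class `scene_collection`.
#' @export
scene_collection <- function(grids, dates) {
  if (length(grids) == 0L) stop("a scene collection needs at least one date")
  if (length(grids) != length(dates)) stop("one date stamp per scene required")
  bands <- names(grids[[1L]])
  if (is.null(bands) || any(!nzchar(bands))) stop("scenes must carry named bands")
  ref <- grids[[1L]][[1L]]
  for (sc in grids) {
    if (!identical(sort(names(sc)), sort(bands)))
      stop("all dates must carry the same band set")
    for (b in bands) check_coregistered(ref, sc[[b]])
  }
  structure(list(grids = grids, dates = dates, bands = bands),
            class = "scene_collection")
}

#' @export
length.scene_collection <- function(x) length(x$grids)

#' @export
print.scene_collection <- function(x, ...) {
  cat(sprintf("<scene_collection> %d dates, bands: %s\n",
              length(x$grids), paste(x$bands, collapse = ", ")))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Polygon sets (simple planar polygons, outer rings only)

#' Planar polygon set
#'
#' Minimal vector container used for administrative divisions, the
#' forest/elevated-terrain exclusion mask and validation geometry. Each
#' feature is a single outer ring (no holes) in raster map coordinates.
#'
#' @param features list of features, each `list(name =, ring =)` where `ring`
#'   is an n x 2 matrix of vertices (closed implicitly).
#' @return an object of class `polygon_set`.
#' @export
polygon_set <- function(features = list()) {
  for (f in features) {
    r <- f$ring
    if (is.null(r) || !is.matrix(r) || ncol(r) != 2L || nrow(r) < 3L ||
        any(!is.finite(r)))
      stop("invalid geometry: each feature needs a finite n x 2 ring, n >= 3")
  }
  nm <- vapply(features, function(f) as.character(f$name %||% ""), character(1))
  if (length(features) && any(!nzchar(nm)))
    nm[!nzchar(nm)] <- paste0("feature_", which(!nzchar(nm)))
  structure(list(features = features, names = nm), class = "polygon_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
length.polygon_set <- function(x) length(x$features)

#' @export
print.polygon_set <- function(x, ...) {
  cat(sprintf("<polygon_set> %d feature(s): %s\n", length(x$features),
              paste(utils::head(x$names, 8), collapse = ", ")))
  invisible(x)
}

#' Axis-aligned rectangular polygon
#'
#' @param xmin,xmax,ymin,ymax rectangle bounds in map coordinates.
#' @param name feature name.
#' @return a single-feature `polygon_set`.
#' @export
rect_polygon <- function(xmin, xmax, ymin, ymax, name = "rect") {
  ring <- cbind(c(xmin, xmax, xmax, xmin), c(ymin, ymin, ymax, ymax))
  polygon_set(list(list(name = name, ring = ring)))
}

#' Concatenate polygon sets
#' @param ... `polygon_set` objects.
#' @return a combined `polygon_set`.
#' @export
c_polygons <- function(...) {
  sets <- list(...)
  polygon_set(do.call(c, lapply(sets, function(s) s$features)))
}

#' Cells whose centers fall inside any polygon
#'
#' Even-odd point-in-polygon on pixel centers; boundary cells follow
#' [pracma::inpolygon()]'s boundary convention (on-edge counts as inside).
#'
#' @param polygons a `polygon_set`.
#' @param like a `raster_grid` defining the lattice.
#' @return logical matrix, `TRUE` where the center is covered.
#' @export
polygon_cover <- function(polygons, like) {
  stopifnot(inherits(polygons, "polygon_set"), inherits(like, "raster_grid"))
  d <- dim(like$values)
  cc <- cell_centers(like)
  xs <- rep(cc$x, each = d[1]); ys <- rep(cc$y, times = d[2])
  inside <- rep(FALSE, d[1] * d[2])
  for (f in polygons$features) {
    todo <- !inside
    if (!any(todo)) break
    inside[todo] <- pracma::inpolygon(xs[todo], ys[todo],
                                      f$ring[, 1], f$ring[, 2],
                                      boundary = TRUE)
  }
  matrix(inside, d[1], d[2])
}

#' Rasterize polygon features to integer labels
#'
#' @inheritParams polygon_cover
#' @param check_overlap error if two features claim the same cell center
#'   (required for administrative divisions, which must partition the extent).
#' @return integer matrix; `i` where covered by feature `i`, `0` outside all.
#' @export
rasterize_features <- function(polygons, like, check_overlap = FALSE) {
  d <- dim(like$values)
  lab <- matrix(0L, d[1], d[2])
  cc <- cell_centers(like)
  xs <- rep(cc$x, each = d[1]); ys <- rep(cc$y, times = d[2])
  for (i in seq_along(polygons$features)) {
    f <- polygons$features[[i]]
    hit <- pracma::inpolygon(xs, ys, f$ring[, 1], f$ring[, 2], boundary = FALSE)
    hit <- matrix(hit, d[1], d[2])
    if (check_overlap && any(lab[hit] != 0L))
      stop("overlapping polygons: features must partition the extent")
    lab[hit & lab == 0L] <- i
  }
  lab
}

# ---------------------------------------------------------------------------
# File I/O: TIFF + JSON georeferencing sidecar, GeoJSON vectors, CSV points

#' Write a raster as TIFF with a JSON georeferencing sidecar
#'
#' Pixel data go to a 32-bit float TIFF; origin, pixel size, CRS and the
#' nodata sentinel go to `<path>.json`.
#'
#' @param grid a `raster_grid`.
#' @param path output file (`.tif`).
#' @param nodata sentinel written in place of `NA`.
#' @return invisibly `path`.
#' @export
write_raster <- function(grid, path, nodata = -9999) {
  v <- grid$values
  v[is.na(v)] <- nodata
  # the tiff writer stores [0, 1] floats; rescale and keep the affine
  # transform (scale, offset) in the sidecar
  lo <- min(v); hi <- max(v)
  scale <- max(hi - lo, 1)
  tiff::writeTIFF((v - lo) / scale, path, bits.per.sample = 32L,
                  compression = "none", reduce = FALSE)
  meta <- list(origin = grid$origin, px = grid$px, crs = grid$crs,
               nodata = nodata, value_offset = lo, value_scale = scale,
               nrow = nrow(v), ncol = ncol(v))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a raster written by [write_raster()]
#' @param path `.tif` file with `<path>.json` sidecar alongside.
#' @return a `raster_grid`.
#' @export
read_raster <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  v <- tiff::readTIFF(path, as.is = FALSE)
  if (length(dim(v)) == 3L) v <- v[, , 1L]
  v <- v * meta$value_scale + meta$value_offset
  v[abs(v - meta$nodata) < 1e-3 * max(1, abs(meta$nodata))] <- NA_real_
  raster_grid(v, origin = meta$origin, px = meta$px, crs = meta$crs)
}

#' Write polygons as GeoJSON
#' @param polygons a `polygon_set`.
#' @param path output `.geojson` file.
#' @return invisibly `path`.
#' @export
write_polygons <- function(polygons, path) {
  feats <- lapply(seq_along(polygons$features), function(i) {
    f <- polygons$features[[i]]
    ring <- rbind(f$ring, f$ring[1L, , drop = FALSE])  # closed ring
    list(type = "Feature",
         properties = list(name = polygons$names[i]),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(k) ring[k, ]))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read polygons from GeoJSON (outer rings only)
#' @param path `.geojson` file.
#' @return a `polygon_set`.
#' @export
read_polygons <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  feats <- lapply(gj$features, function(f) {
    ring <- t(vapply(f$geometry$coordinates[[1L]],
                     function(p) as.numeric(unlist(p)), numeric(2)))
    if (nrow(ring) > 3L &&
        all(abs(ring[1L, ] - ring[nrow(ring), ]) < 1e-9))
      ring <- ring[-nrow(ring), , drop = FALSE]
    list(name = f$properties$name %||% "", ring = ring)
  })
  polygon_set(feats)
}

#' Write ground control points as CSV
#' @param gcps data.frame with columns `x`, `y`, `elevation_m`.
#' @param path output `.csv`.
#' @return invisibly `path`.
#' @export
write_gcps <- function(gcps, path) {
  stopifnot(all(c("x", "y", "elevation_m") %in% names(gcps)))
  utils::write.csv(gcps[, c("x", "y", "elevation_m")], path, row.names = FALSE)
  invisible(path)
}

#' Read ground control points from CSV
#' @param path `.csv` with columns `x`, `y`, `elevation_m`.
#' @return data.frame.
#' @export
read_gcps <- function(path) {
  g <- utils::read.csv(path)
  stopifnot(all(c("x", "y", "elevation_m") %in% names(g)))
  g
}
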