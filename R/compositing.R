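#' Normalized difference vegetation index
#'
#' `(NIR - red) / (NIR + red)`. Nodata propagates; cells where both bands are
#' zero (degenerate denominator) become nodata.
#'
#' @param red,nir co-registered reflectance grids (values >= 0).
#' @return NDVI `raster_grid` in \[-1, 1\].
#' @export
compute_ndvi <- function(red, nir) {
  check_coregistered(red, nir)
  r <- red$values; n <- nir$values
  if (any(r < 0, na.rm = TRUE) || any(n < 0, na.rm = TRUE))
    stop("reflectances must be non-negative")
  den <- n + r
  out <- (n - r) / den
  out[!is.finite(out)] <- NA_real_
  out[is.na(r) | is.na(n) | den == 0] <- NA_real_
  grid_like(red, out)
}

#' Greenest-pixel optical composite
#'
#' Per pixel, selects the acquisition date with the maximum NDVI (a "quality
#' mosaic") and carries every band from that date; the composite NDVI is the
#' per-pixel maximum. Dates where a pixel is nodata are ignored; ties are
#' broken by the earliest date. Pixels that are nodata at all dates stay
#' nodata.
#'
#' @param collection a [scene_collection()] with `red` and `nir` bands.
#' @return an object of class `optical_composite`: list with `bands` (named
#'   list of `raster_grid`), `ndvi`, `greenest_date` (1-based date index
#'   grid) and `dates`.
#' @export
greenest_composite <- function(collection) {
  stopifnot(inherits(collection, "scene_collection"))
  if (length(collection) == 0L) stop("empty collection")
  if (!all(c("red", "nir") %in% collection$bands))
    stop("collection must carry 'red' and 'nir' bands")
  template <- collection$grids[[1L]]$red
  d <- dim(template$values)
  nd_stack <- lapply(collection$grids,
                     function(sc) compute_ndvi(sc$red, sc$nir)$values)
  best_nd <- matrix(-Inf, d[1], d[2])
  best_ix <- matrix(NA_integer_, d[1], d[2])
  for (i in seq_along(nd_stack)) {
    nd <- nd_stack[[i]]
    upd <- !is.na(nd) & (is.na(best_ix) | nd > best_nd)  # ties keep earliest
    best_nd[upd] <- nd[upd]
    best_ix[upd] <- i
  }
  best_nd[is.na(best_ix)] <- NA_real_
  bands <- lapply(collection$bands, function(b) {
    out <- matrix(NA_real_, d[1], d[2])
    for (i in seq_along(collection$grids)) {
      sel <- !is.na(best_ix) & best_ix == i
      out[sel] <- collection$grids[[i]][[b]]$values[sel]
    }
    grid_like(template, out)
  })
  names(bands) <- collection$bands
  structure(list(bands = bands, ndvi = grid_like(template, best_nd),
                 greenest_date = grid_like(template, best_ix + 0),
                 dates = collection$dates),
            class = "optical_composite")
}

#' @export
print.optical_composite <- function(x, ...) {
  cat(sprintf("<optical_composite> bands: %s; %d source dates\n",
              paste(names(x$bands), collapse = ", "), length(x$dates)))
  invisible(x)
}

#' Temporal average of SAR backscatter in the linear power domain
#'
#' dB values are converted to linear power (`10^(dB/10)`), averaged per pixel
#' over non-nodata dates, and re-expressed in dB. Averaging in the linear
#' domain (not the dB domain) is required for a physically meaningful mean
#' backscatter; by Jensen's inequality the result is never below the
#' dB-domain mean.
#'
#' @param collection a [scene_collection()] carrying the band.
#' @param band band label (e.g. `"vh"` or `"vv"`).
#' @return `raster_grid` of mean backscatter in dB.
#' @export
temporal_average_sar <- function(collection, band) {
  stopifnot(inherits(collection, "scene_collection"))
  if (length(collection) == 0L) stop("empty collection")
  if (!band %in% collection$bands) stop(sprintf("band '%s' not present", band))
  template <- collection$grids[[1L]][[band]]
  d <- dim(template$values)
  acc <- matrix(0, d[1], d[2]); cnt <- matrix(0L, d[1], d[2])
  for (sc in collection$grids) {
    v <- sc[[band]]$values
    ok <- !is.na(v)
    acc[ok] <- acc[ok] + 10^(v[ok] / 10)
    cnt <- cnt + ok
  }
  out <- 10 * log10(acc / cnt)
  out[cnt == 0L] <- NA_real_
  grid_like(template, out)
}

#' Fill low-backscatter scan lines from the other pass direction
#'
#' Pixels of the averaged descending image below the threshold (or nodata)
#' take the averaged ascending value and are flagged. There is no second
#' donor: if the ascending value is also low it is retained as-is.
#'
#' @param descending_mean,ascending_mean co-registered dB grids.
#' @param low_db_threshold fill threshold in dB (default -25: well below any
#'   physical backscatter in the scene, so only inter-swath gaps qualify).
#' @return list with `filled` (`raster_grid`) and `fill_flag` (0/1 grid).
#' @export
fill_scan_lines <- function(descending_mean, ascending_mean,
                            low_db_threshold = -25) {
  check_coregistered(descending_mean, ascending_mean)
  dv <- descending_mean$values
  fill <- is.na(dv) | dv < low_db_threshold
  out <- dv
  out[fill] <- ascending_mean$values[fill]
  list(filled = grid_like(descending_mean, out),
       fill_flag = grid_like(descending_mean, fill * 1))
}

#' Build the dual-polarization SAR composite
#'
#' Convenience wrapper: linear-domain temporal averages of VH and VV for both
#' passes, with descending scan-line gaps filled from the ascending pass.
#'
#' @param ascending,descending [scene_collection()]s with `vh`, `vv` bands.
#' @param low_db_threshold scan-line fill threshold in dB.
#' @return object of class `sar_composite`: list with `vh_db`, `vv_db`
#'   (filled descending means) and `fill_flag`.
#' @export
sar_composite <- function(ascending, descending, low_db_threshold = -25) {
  vh_a <- temporal_average_sar(ascending, "vh")
  vv_a <- temporal_average_sar(ascending, "vv")
  vh_d <- temporal_average_sar(descending, "vh")
  vv_d <- temporal_average_sar(descending, "vv")
  fh <- fill_scan_lines(vh_d, vh_a, low_db_threshold)
  fv <- fill_scan_lines(vv_d, vv_a, low_db_threshold)
  structure(list(vh_db = fh$filled, vv_db = fv$filled,
                 fill_flag = fh$fill_flag),
            class = "sar_composite")
}
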