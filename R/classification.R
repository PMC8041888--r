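#' Threshold configuration for TOF classification
#'
#' Decision windows for the optical-radar fusion: NDVI strictly inside
#' (0.3, 0.9) marks photosynthetic cover; VH backscatter in \[-14, -9\] dB
#' marks volumetric (canopy) scattering, with VV in \[-8, -2\] dB as a veto
#' against false positives; connected clumps below 25 pixels (0.25 ha at
#' 10 m) are sieved out. NDVI bounds are exclusive, SAR bounds inclusive,
#' matching how the windows are stated.
#'
#' @param ndvi_low,ndvi_high exclusive NDVI window bounds.
#' @param vh_low,vh_high inclusive VH window bounds (dB).
#' @param vv_low,vv_high inclusive VV window bounds (dB).
#' @param min_patch_pixels sieve threshold (clumps with fewer pixels drop).
#' @param sieve_connectivity 8 (edge or corner, default) or 4 (edge only)
#'   for the sieve clumping. Patch *analysis* uses edge-only connectivity;
#'   the two stages intentionally differ (see the package vignette).
#' @return an object of class `threshold_config`.
#' @export
threshold_config <- function(ndvi_low = 0.3, ndvi_high = 0.9,
                             vh_low = -14, vh_high = -9,
                             vv_low = -8, vv_high = -2,
                             min_patch_pixels = 25L,
                             sieve_connectivity = 8L) {
  if (ndvi_low >= ndvi_high || vh_low >= vh_high || vv_low >= vv_high)
    stop("each threshold window needs low < high")
  if (min_patch_pixels < 1) stop("min_patch_pixels must be >= 1")
  if (!sieve_connectivity %in% c(4L, 8L))
    stop("sieve_connectivity must be 4 or 8")
  structure(list(ndvi_low = ndvi_low, ndvi_high = ndvi_high,
                 vh_low = vh_low, vh_high = vh_high,
                 vv_low = vv_low, vv_high = vv_high,
                 min_patch_pixels = as.integer(min_patch_pixels),
                 sieve_connectivity = as.integer(sieve_connectivity)),
            class = "threshold_config")
}

#' Photosynthetic-cover mask from NDVI
#'
#' 1 where `ndvi_low < NDVI < ndvi_high` (bounds exclusive), 0 elsewhere;
#' nodata propagates.
#'
#' @param ndvi NDVI `raster_grid`.
#' @param cfg a [threshold_config()].
#' @return binary `raster_grid`.
#' @export
threshold_optical <- function(ndvi, cfg = threshold_config()) {
  v <- ndvi$values
  out <- (v > cfg$ndvi_low & v < cfg$ndvi_high) * 1
  grid_like(ndvi, out)
}

#' Structure mask from dual-polarization backscatter
#'
#' 1 where VH lies in \[`vh_low`, `vh_high`\] and VV in \[`vv_low`,
#' `vv_high`\] (bounds inclusive); the VV window vetoes false positives.
#' Nodata in either band propagates.
#'
#' @param vh_db,vv_db co-registered backscatter grids (dB).
#' @param cfg a [threshold_config()].
#' @return binary `raster_grid`.
#' @export
threshold_sar <- function(vh_db, vv_db, cfg = threshold_config()) {
  check_coregistered(vh_db, vv_db)
  vh <- vh_db$values; vv <- vv_db$values
  out <- (vh >= cfg$vh_low & vh <= cfg$vh_high &
          vv >= cfg$vv_low & vv <= cfg$vv_high) * 1
  grid_like(vh_db, out)
}

#' Intersection of the optical and radar masks
#'
#' Logical AND: a pixel is a tree pixel when it is photosynthetic and has
#' structure. Nodata in either input propagates.
#'
#' @param optical,sar co-registered binary `raster_grid`s.
#' @return binary `raster_grid`.
#' @export
fuse_masks <- function(optical, sar) {
  check_coregistered(optical, sar)
  grid_like(optical, (optical$values == 1 & sar$values == 1) * 1)
}

#' Zero out pixels inside exclusion polygons
#'
#' Removes pixels whose centers fall inside any polygon of the manually
#' delineated forest / elevated-terrain mask. An empty polygon set is the
#' identity.
#'
#' @param mask binary `raster_grid`.
#' @param polygons a `polygon_set` in the mask CRS.
#' @return binary `raster_grid`.
#' @export
apply_exclusion <- function(mask, polygons) {
  stopifnot(inherits(polygons, "polygon_set"))
  if (length(polygons) == 0L) return(mask)
  out <- mask$values
  out[polygon_cover(polygons, mask)] <- 0
  grid_like(mask, out)
}

#' Remove connected clumps below the minimum patch size
#'
#' Clumps foreground pixels (8-neighbor by default) and drops components
#' with fewer than `min_patch_pixels` pixels; larger components are
#' untouched. Never adds pixels, and adding foreground to the input can
#' never remove a previously surviving patch.
#'
#' @param mask binary `raster_grid`.
#' @param cfg a [threshold_config()] (uses `min_patch_pixels` and
#'   `sieve_connectivity`).
#' @return binary `raster_grid`.
#' @export
sieve_mask <- function(mask, cfg = threshold_config()) {
  lab <- label_components(mask$values, connectivity = cfg$sieve_connectivity)
  if (max(lab, na.rm = TRUE) == 0) return(mask)
  sizes <- tabulate(lab[lab > 0L])
  drop <- which(sizes < cfg$min_patch_pixels)
  out <- mask$values
  out[lab %in% drop] <- 0
  grid_like(mask, out)
}

#' Full TOF classification from composites
#'
#' Fixed order of operations: threshold the optical and SAR composites, fuse
#' by intersection, remove the forest exclusion polygons, then sieve. The
#' exclusion runs before the sieve so that mask edits cannot resurrect
#' sub-threshold fragments.
#'
#' @param ndvi composite NDVI `raster_grid`.
#' @param vh_db,vv_db averaged (and gap-filled) backscatter grids.
#' @param exclusion `polygon_set` of forest / elevated-terrain polygons
#'   (empty set for none).
#' @param cfg a [threshold_config()].
#' @return binary TOF extent `raster_grid`.
#' @export
classify_tof <- function(ndvi, vh_db, vv_db, exclusion = polygon_set(),
                         cfg = threshold_config()) {
  fused <- fuse_masks(threshold_optical(ndvi, cfg),
                      threshold_sar(vh_db, vv_db, cfg))
  sieve_mask(apply_exclusion(fused, exclusion), cfg)
}
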