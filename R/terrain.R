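#' Inverse-distance-weighted terrain interpolation
#'
#' Estimates bare-earth elevation on a raster lattice from ground control
#' points: `z(x) = sum(w_i z_i) / sum(w_i)` with `w_i = d_i^-power` over
#' GCPs within `radius`. A cell whose center coincides with a GCP (distance
#' below `eps`, default `1e-6 * px`) takes that GCP's elevation exactly,
#' which avoids division by zero deterministically. Cells with no GCP in
#' range become nodata. The surface is a convex combination of contributing
#' elevations, hence bounded by their range.
#'
#' @param gcps data.frame with `x`, `y`, `elevation_m`.
#' @param like `raster_grid` supplying the output geometry.
#' @param power positive IDW exponent (default 2, the common convention of
#'   grid-interpolation tools).
#' @param radius search radius in meters, or `Inf` for all points.
#' @param eps coincidence tolerance in meters.
#' @return `raster_grid` of interpolated elevations.
#' @export
idw_interpolate <- function(gcps, like, power = 2, radius = Inf, eps = NULL) {
  stopifnot(inherits(like, "raster_grid"))
  if (nrow(gcps) == 0L) stop("empty GCP set")
  if (!is.numeric(power) || power <= 0) stop("power must be positive")
  if (is.null(eps)) eps <- 1e-6 * like$px
  d <- dim(like$values)
  cc <- cell_centers(like)
  gx <- gcps$x; gy <- gcps$y; gz <- gcps$elevation_m
  out <- matrix(NA_real_, d[1], d[2])
  # chunk over columns to bound the ncell x ngcp distance matrix
  chunk <- max(1L, floor(2e6 / max(1L, length(gx)) / d[1]))
  for (c0 in seq(1L, d[2], by = chunk)) {
    cols <- c0:min(d[2], c0 + chunk - 1L)
    xs <- rep(cc$x[cols], each = d[1])
    ys <- rep(cc$y, times = length(cols))
    d2 <- outer(xs, gx, "-")^2 + outer(ys, gy, "-")^2
    dist <- sqrt(d2)
    w <- dist^(-power)
    w[dist > radius] <- 0
    num <- w %*% gz
    den <- rowSums(w)
    val <- as.vector(num) / den
    val[den == 0] <- NA_real_
    # exact coincidence overrides the weighted sum
    hit <- dist < eps
    if (any(hit)) {
      hi <- which(rowSums(hit) > 0)
      val[hi] <- gz[apply(hit[hi, , drop = FALSE], 1L, which.max)]
    }
    out[, cols] <- matrix(val, d[1], length(cols))
  }
  grid_like(like, out)
}

#' Root-mean-square error of a terrain model on holdout points
#'
#' Compares interpolated elevations against an independent bare-ground
#' holdout sample. Points falling on nodata cells (or outside the raster)
#' are excluded and counted.
#'
#' @param dtm interpolated terrain `raster_grid`.
#' @param holdout data.frame with `x`, `y`, `elevation_m`, disjoint from the
#'   fitting GCPs.
#' @return RMSE in meters, with attributes `n_used` and `n_excluded`.
#' @export
validate_dtm <- function(dtm, holdout) {
  if (nrow(holdout) == 0L) stop("empty holdout set")
  pred <- extract_at(dtm, holdout$x, holdout$y)
  ok <- !is.na(pred)
  if (!any(ok)) stop("no holdout point falls on a valid DTM cell")
  rmse <- sqrt(mean((pred[ok] - holdout$elevation_m[ok])^2))
  structure(rmse, n_used = sum(ok), n_excluded = sum(!ok))
}

#' Raw canopy height from surface minus terrain
#'
#' `dsm - dtm` on tree pixels, nodata elsewhere. Negative differences are
#' retained at this stage; they are screened later by the calibration
#' thresholds (pixels at or below 0 m are removed before the height
#' transform is applied).
#'
#' @param dsm surface-model `raster_grid`.
#' @param dtm terrain-model `raster_grid`.
#' @param tof_mask binary tree-extent `raster_grid`.
#' @return canopy-height `raster_grid` in meters.
#' @export
canopy_height <- function(dsm, dtm, tof_mask) {
  check_coregistered(dsm, dtm, tof_mask)
  out <- dsm$values - dtm$values
  out[is.na(tof_mask$values) | tof_mask$values != 1] <- NA_real_
  grid_like(dsm, out)
}

#' Fit and validate a terrain model in one call
#'
#' @param gcps,holdout fitting and validation point sets.
#' @param like output geometry.
#' @param power,radius IDW parameters.
#' @return list of class `dtm_result`: `dtm`, `rmse_holdout`, `n_gcp`,
#'   `n_holdout`, `idw_power`, `search_radius`.
#' @export
build_dtm <- function(gcps, holdout, like, power = 2, radius = Inf) {
  dtm <- idw_interpolate(gcps, like, power = power, radius = radius)
  rmse <- validate_dtm(dtm, holdout)
  structure(list(dtm = dtm, rmse_holdout = as.numeric(rmse),
                 n_gcp = nrow(gcps), n_holdout = attr(rmse, "n_used"),
                 idw_power = power, search_radius = radius),
            class = "dtm_result")
}

#' @export
print.dtm_result <- function(x, ...) {
  cat(sprintf("<dtm_result> %d GCPs, power %g, radius %s; holdout RMSE %.2f m (n=%d)\n",
              x$n_gcp, x$idw_power,
              if (is.finite(x$search_radius)) sprintf("%g m", x$search_radius)
              else "all points", x$rmse_holdout, x$n_holdout))
  invisible(x)
}
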