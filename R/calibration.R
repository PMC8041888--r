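#' Aggregate canopy heights into 1-ha plot means
#'
#' Tiles the grid into non-overlapping square plots anchored at the raster
#' origin (100 m x 100 m by default, i.e. 10 x 10 cells at 10 m) and
#' averages the raw and reference canopy heights over tree-mask pixels in
#' each plot. The 1-ha aggregation buffers geolocation and classification
#' error in the pixelwise heights. Plots with no tree pixels are excluded;
#' incomplete edge tiles are dropped.
#'
#' @param chm raw canopy-height `raster_grid`.
#' @param reference reference canopy-surface `raster_grid` (e.g. from stereo
#'   photogrammetry), co-registered with `chm`.
#' @param mask binary tree-extent `raster_grid`.
#' @param plot_m plot side length in meters (default 100, a 1-ha plot).
#' @return data.frame with `plot_id`, `tile_row`, `tile_col`, `mean_raw`,
#'   `mean_reference`, `n_tree_pixels`.
#' @export
aggregate_plots <- function(chm, reference, mask, plot_m = 100) {
  check_coregistered(chm, reference, mask)
  pp <- round(plot_m / chm$px)
  if (pp < 1) stop("plot size below one pixel")
  d <- dim(chm$values)
  ntr <- d[1] %/% pp; ntc <- d[2] %/% pp
  if (ntr < 1 || ntc < 1) stop("extent smaller than one full plot")
  rows <- seq_len(ntr * pp); cols <- seq_len(ntc * pp)
  tile <- (rep(((cols - 1L) %/% pp), each = length(rows)) * ntr +
           rep(((rows - 1L) %/% pp), times = length(cols))) + 1L
  sel <- mask$values[rows, cols] == 1 &
    !is.na(chm$values[rows, cols]) & !is.na(reference$values[rows, cols])
  sel[is.na(sel)] <- FALSE
  t_sel <- tile[sel]
  if (length(t_sel) == 0L)
    return(data.frame(plot_id = integer(), tile_row = integer(),
                      tile_col = integer(), mean_raw = numeric(),
                      mean_reference = numeric(), n_tree_pixels = integer()))
  n <- tabulate(t_sel, nbins = ntr * ntc)
  sum_raw <- rowsum(chm$values[rows, cols][sel], t_sel)
  sum_ref <- rowsum(reference$values[rows, cols][sel], t_sel)
  ids <- as.integer(rownames(sum_raw))
  data.frame(plot_id = ids,
             tile_row = ((ids - 1L) %% ntr) + 1L,
             tile_col = ((ids - 1L) %/% ntr) + 1L,
             mean_raw = as.numeric(sum_raw) / n[ids],
             mean_reference = as.numeric(sum_ref) / n[ids],
             n_tree_pixels = n[ids])
}

#' Exclude gross-disagreement plots
#'
#' Removes plots where the absolute raw-vs-reference difference exceeds
#' twice the 99th percentile of all absolute differences — a screen for
#' erroneous values (e.g. geolocation failures) before fitting.
#'
#' @param plots an [aggregate_plots()] data.frame (>= 2 rows).
#' @return the filtered data.frame, with attribute `n_excluded`.
#' @export
exclude_outliers <- function(plots) {
  if (nrow(plots) < 2L) stop("need at least two plots")
  d <- abs(plots$mean_reference - plots$mean_raw)
  thr <- 2 * stats::quantile(d, 0.99, names = FALSE)
  keep <- d <= thr
  structure(plots[keep, , drop = FALSE], n_excluded = sum(!keep))
}

#' Fit the linear height calibration
#'
#' Ordinary least squares of reference plot height on raw plot height:
#' `reference ~ slope * raw + intercept`. Reports the mean absolute error
#' before (raw vs reference, the identity line) and after applying the
#' fitted line; least-squares optimality does not guarantee a lower MAE,
#' but in practice the correction dominates whenever the raw surface has a
#' multiplicative bias such as radar penetration.
#'
#' @param plots plot table after outlier exclusion (>= 3 rows).
#' @param min_height minimum credible tree height in meters; calibrated
#'   pixels at or below this are discarded when the model is applied.
#' @param cap_percentile per-division upper percentile cap.
#' @return object of class `calibration_model` with `slope`, `intercept`,
#'   `mae_before`, `mae_after`, `n_plots_used`, `n_outliers_excluded`,
#'   `min_height`, `cap_percentile`.
#' @export
fit_calibration <- function(plots, min_height = 2.19, cap_percentile = 99) {
  if (nrow(plots) < 3L) stop("need at least three plots to fit")
  if (stats::sd(plots$mean_raw) < 1e-9)
    stop("degenerate raw-height variance: cannot fit a line")
  if (min_height <= 0) stop("min_height must be positive")
  fit <- stats::lm(mean_reference ~ mean_raw, data = plots)
  pred <- stats::fitted(fit)
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 mae_before = mean(abs(plots$mean_reference - plots$mean_raw)),
                 mae_after = mean(abs(plots$mean_reference - pred)),
                 n_plots_used = nrow(plots),
                 n_outliers_excluded = attr(plots, "n_excluded") %||% 0L,
                 min_height = min_height, cap_percentile = cap_percentile),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf(paste0("<calibration_model> height_ref = %.3f * height_raw %+.3f\n",
                     "  MAE %.2f m -> %.2f m over %d plots (%d outliers excluded)\n",
                     "  min height %.2f m, cap at P%g per division\n"),
              x$slope, x$intercept, x$mae_before, x$mae_after,
              x$n_plots_used, x$n_outliers_excluded,
              x$min_height, x$cap_percentile))
  invisible(x)
}

#' Apply the height calibration with screening rules
#'
#' In order: raw pixels at or below 0 m are removed (erroneously classified
#' tree pixels); the linear correction is applied; calibrated heights below
#' the minimum credible height become nodata; surviving heights above the
#' per-division 99th percentile (computed after the minimum-height filter)
#' are clipped to that percentile. Pixels outside every division fall back
#' to the global percentile with a warning. The transform is monotone within
#' a division.
#'
#' @param chm raw canopy-height `raster_grid` (nodata off the tree mask).
#' @param model a [fit_calibration()] result.
#' @param division_zones `polygon_set` of administrative divisions, or a
#'   pre-rasterized integer label matrix; `NULL` applies a global cap.
#' @return calibrated canopy-height `raster_grid`.
#' @export
apply_calibration <- function(chm, model, division_zones = NULL) {
  stopifnot(inherits(model, "calibration_model"))
  v <- chm$values
  v[v <= 0] <- NA_real_
  v <- model$slope * v + model$intercept
  v[v < model$min_height] <- NA_real_
  p <- model$cap_percentile / 100
  if (is.null(division_zones)) {
    lab <- matrix(1L, nrow(v), ncol(v))
  } else if (is.matrix(division_zones)) {
    lab <- division_zones
  } else {
    lab <- rasterize_features(division_zones, chm)
  }
  if (any(lab[!is.na(v)] == 0L)) {
    warning("pixels outside every division: using the global percentile cap")
    gcap <- stats::quantile(v[!is.na(v)], p, names = FALSE)
    sel <- lab == 0L & !is.na(v) & v > gcap
    v[sel] <- gcap
  }
  for (k in setdiff(unique(lab[!is.na(v)]), 0L)) {
    vals <- v[lab == k & !is.na(v)]
    if (!length(vals)) next
    cap <- stats::quantile(vals, p, names = FALSE)
    sel <- lab == k & !is.na(v) & v > cap
    v[sel] <- cap
  }
  grid_like(chm, v)
}

#' Per-division canopy-height summary
#'
#' Mean and maximum calibrated height per division, plus the mean restricted
#' to trees above the forest-definition height threshold (5 m), and a
#' national total row.
#'
#' @param chm calibrated canopy-height `raster_grid`.
#' @param division_zones `polygon_set` or integer label matrix.
#' @param fra_threshold height threshold in meters (default 5, the common
#'   forest-definition minimum).
#' @return data.frame with `division`, `mean_height_m`, `max_height_m`,
#'   `mean_height_above_threshold_m`, `n_pixels`.
#' @export
height_summary <- function(chm, division_zones, fra_threshold = 5) {
  if (is.matrix(division_zones)) {
    lab <- division_zones
    nms <- as.character(seq_len(max(lab, 1L)))
  } else {
    lab <- rasterize_features(division_zones, chm)
    nms <- division_zones$names
  }
  v <- chm$values
  row_for <- function(sel, name) {
    vals <- v[sel & !is.na(v)]
    if (!length(vals)) {
      warning(sprintf("division '%s' has no valid height pixels", name))
      return(data.frame(division = name, mean_height_m = NA_real_,
                        max_height_m = NA_real_,
                        mean_height_above_threshold_m = NA_real_,
                        n_pixels = 0L))
    }
    above <- vals[vals > fra_threshold]
    data.frame(division = name, mean_height_m = mean(vals),
               max_height_m = max(vals),
               mean_height_above_threshold_m =
                 if (length(above)) mean(above) else NA_real_,
               n_pixels = length(vals))
  }
  rows <- do.call(rbind, lapply(seq_along(nms), function(k)
    row_for(lab == k, nms[k])))
  rbind(rows, row_for(lab > 0L, "Total"))
}
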