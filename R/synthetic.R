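#' Parameters for a synthetic TOF landscape
#'
#' Defines the study conditions a generated scene emulates: a low-lying
#' agricultural floodplain where trees outside forests (TOF) occur as
#' homestead clusters, narrow field-boundary lines and sinuous riparian
#' corridors, observed by multi-date optical imagery (NDVI), dual-pass
#' dual-polarization C-band radar, and a single-date surface model whose
#' canopy return is biased by radar penetration.
#'
#' @param size grid dimensions `c(nrow, ncol)` in pixels (>= 64 each).
#' @param px pixel size in meters.
#' @param tree_fraction target proportion of TOF pixels over the grid.
#' @param archetype_mix weights for patch archetypes
#'   `c(boundary =, homestead =, riparian =)`; field-boundary stands dominate
#'   by default, which skews the patch-size distribution toward sub-1-ha
#'   stands as observed in smallholder agricultural landscapes.
#' @param optical_noise_sd per-date noise sd on the NDVI scale.
#' @param sar_speckle_sd per-date speckle-like noise sd in dB.
#' @param scanline_gap_fraction fraction of pixels covered by low-backscatter
#'   scan-line stripes in the descending pass.
#' @param dsm_noise_sd surface-model noise sd in meters.
#' @param dsm_bias `c(slope, intercept)` applied to true canopy height in the
#'   surface model (slope < 1 mimics X-band penetration into the canopy).
#' @param reference_bias `c(slope, intercept)` for the independent reference
#'   surface used in height calibration.
#' @param optical_dates,sar_dates number of acquisition dates per collection.
#' @param cloud_fraction per-date fraction of pixels occluded (NDVI knocked
#'   down); the greenest composite is expected to see through this.
#' @param terrain_amplitude,terrain_base smooth terrain relief (m) and mean
#'   elevation above datum (m).
#' @param forest_fraction area fraction of a contiguous-forest block that is
#'   rendered tree-like in imagery but excluded from TOF truth (exercises the
#'   forest exclusion mask).
#' @param seed integer seed; the same seed gives bit-identical scenes.
#' @return an object of class `scene_params`.
#' @export
scene_params <- function(size = c(256, 256), px = 10, tree_fraction = 0.15,
                         archetype_mix = c(boundary = 0.40, homestead = 0.35,
                                           riparian = 0.25),
                         optical_noise_sd = 0.05, sar_speckle_sd = 1.5,
                         scanline_gap_fraction = 0.02, dsm_noise_sd = 0.5,
                         dsm_bias = c(slope = 0.8, intercept = 0),
                         reference_bias = c(slope = 1, intercept = 0),
                         optical_dates = 6, sar_dates = 12,
                         cloud_fraction = 0,
                         terrain_amplitude = 5, terrain_base = 12,
                         forest_fraction = 0.05, seed = 1L) {
  size <- as.integer(size)
  if (length(size) != 2L || any(!is.finite(size)) || any(size <= 0))
    stop("grid size must be two positive integers")
  if (any(size < 64L)) stop("grid size must be at least 64 x 64")
  if (px <= 0) stop("pixel size must be positive")
  fr <- c(tree_fraction, scanline_gap_fraction, cloud_fraction, forest_fraction)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (optical_noise_sd < 0 || sar_speckle_sd < 0 || dsm_noise_sd < 0)
    stop("noise standard deviations must be >= 0")
  if (optical_dates < 1 || sar_dates < 1) stop("at least one date per collection")
  mix <- archetype_mix[c("boundary", "homestead", "riparian")]
  if (any(is.na(mix)) || any(mix < 0) || sum(mix) <= 0)
    stop("archetype_mix needs non-negative boundary/homestead/riparian weights")
  structure(list(size = size, px = px, tree_fraction = tree_fraction,
                 archetype_mix = mix / sum(mix),
                 optical_noise_sd = optical_noise_sd,
                 sar_speckle_sd = sar_speckle_sd,
                 scanline_gap_fraction = scanline_gap_fraction,
                 dsm_noise_sd = dsm_noise_sd,
                 dsm_bias = unname(dsm_bias), reference_bias = unname(reference_bias),
                 optical_dates = as.integer(optical_dates),
                 sar_dates = as.integer(sar_dates),
                 cloud_fraction = cloud_fraction,
                 terrain_amplitude = terrain_amplitude,
                 terrain_base = terrain_base,
                 forest_fraction = forest_fraction, seed = as.integer(seed)),
            class = "scene_params")
}

# low-frequency random field in [0, 1]: a few sinusoidal modes, so the
# gradient is bounded at the scale of the interpolation tests
smooth_field <- function(nr, nc, n_modes = 4L) {
  X <- matrix(rep(seq_len(nc), each = nr), nr, nc) / nc
  Y <- matrix(rep(seq_len(nr), times = nc), nr, nc) / nr
  f <- matrix(0, nr, nc)
  for (k in seq_len(n_modes)) {
    fx <- stats::runif(1, 0.5, 2); fy <- stats::runif(1, 0.5, 2)
    ph <- stats::runif(1, 0, 2 * pi)
    f <- f + stats::runif(1, 0.5, 1) * sin(2 * pi * (fx * X + fy * Y) + ph)
  }
  (f - min(f)) / max(f - min(f), 1e-12)
}

# stamp helpers return linear cell indices (column-major) within bounds
.disk_cells <- function(r0, c0, radius, nr, nc) {
  rr <- max(1L, floor(r0 - radius)):min(nr, ceiling(r0 + radius))
  cc <- max(1L, floor(c0 - radius)):min(nc, ceiling(c0 + radius))
  g <- expand.grid(r = rr, c = cc)
  keep <- (g$r - r0)^2 + (g$c - c0)^2 <= radius^2
  (g$c[keep] - 1L) * nr + g$r[keep]
}

.rect_cells <- function(r1, r2, c1, c2, nr, nc) {
  rr <- max(1L, r1):min(nr, r2); cc <- max(1L, c1):min(nc, c2)
  as.vector(outer(rr, (cc - 1L) * nr, "+"))
}

division_names <- c("Barisal", "Chittagong", "Dhaka", "Khulna",
                    "Mymensingh", "Rajshahi", "Rangpur", "Sylhet")

#' Generate a landscape with known TOF truth
#'
#' Places tree patches from three archetypes (field-boundary lines 1-3 px
#' wide, homestead blobs of 3-10 px, sinuous riparian corridors) until the
#' target tree fraction is reached, over a smooth terrain field, a non-tree
#' cover map (agriculture / urban / water) and a rectangular 2 x 4 partition
#' into eight administrative divisions. A contiguous-forest block is rendered
#' tree-like by the imagery renderers but kept out of the TOF truth mask; its
#' polygon is returned as the forest exclusion layer.
#'
#' @param params a [scene_params()] object.
#' @return an object of class `landscape_truth` with fields `tree_mask`,
#'   `tree_height`, `terrain` (raster grids), `division_polygons`,
#'   `forest_exclusion` (polygon sets), `division_labels`, `forest_mask`,
#'   `cover_class` (1 = agriculture, 2 = urban, 3 = water), `params`, `seed`.
#' @export
generate_landscape <- function(params) {
  stopifnot(inherits(params, "scene_params"))
  nr <- params$size[1]; nc <- params$size[2]; px <- params$px
  set.seed(params$seed)
  origin <- c(0, nr * px)
  template <- raster_grid(matrix(0, nr, nc), origin, px)

  terrain_v <- params$terrain_base +
    params$terrain_amplitude * (smooth_field(nr, nc) - 0.5) * 2

  # forest block in the north-west corner (excluded from TOF truth)
  forest <- matrix(FALSE, nr, nc)
  forest_poly <- polygon_set()
  if (params$forest_fraction > 0) {
    fr <- max(1L, round(nr * sqrt(params$forest_fraction)))
    fc <- max(1L, round(nc * sqrt(params$forest_fraction)))
    forest[seq_len(fr), seq_len(fc)] <- TRUE
    forest_poly <- rect_polygon(0, fc * px, (nr - fr) * px, nr * px,
                                name = "continuous_forest")
  }

  # non-tree cover: agriculture background, urban blocks, a water corridor
  cover <- matrix(1L, nr, nc)
  n_urban <- max(1L, round(nr * nc * 0.08 / 150))
  for (k in seq_len(n_urban)) {
    r0 <- sample.int(nr, 1); c0 <- sample.int(nc, 1)
    h <- sample(8:16, 1); w <- sample(8:16, 1)
    cover[.rect_cells(r0, r0 + h, c0, c0 + w, nr, nc)] <- 2L
  }
  r <- stats::runif(1, 1, nr); c <- 1; ang <- stats::runif(1, -0.4, 0.4)
  while (c <= nc) {
    cover[.disk_cells(round(r), round(c), stats::runif(1, 2.5, 4), nr, nc)] <- 3L
    ang <- ang + stats::rnorm(1, 0, 0.25); ang <- max(-1, min(1, ang))
    r <- r + sin(ang); c <- c + cos(ang)
    if (r < 1 || r > nr) break
  }

  # TOF patches: stamp archetypes outside the forest block until the target
  # pixel count is reached (small patches, so overshoot is at most one patch)
  tree <- matrix(FALSE, nr, nc)
  target <- round(params$tree_fraction * nr * nc)
  mix <- params$archetype_mix
  guard <- 0L
  while (sum(tree) < target && guard < 50000L) {
    guard <- guard + 1L
    kind <- sample(names(mix), 1, prob = mix)
    idx <- switch(kind,
      homestead = .disk_cells(sample.int(nr, 1), sample.int(nc, 1),
                              stats::runif(1, 0.9, 1.8), nr, nc),
      boundary = {
        len <- sample(10:40, 1); wid <- sample(1:3, 1)
        r0 <- sample.int(nr, 1); c0 <- sample.int(nc, 1)
        if (stats::runif(1) < 0.5)
          .rect_cells(r0, r0 + wid - 1L, c0, c0 + len - 1L, nr, nc)
        else
          .rect_cells(r0, r0 + len - 1L, c0, c0 + wid - 1L, nr, nc)
      },
      riparian = {
        steps <- sample(60:200, 1); wid <- sample(2:3, 1)
        rr <- stats::runif(1, 1, nr); cc <- stats::runif(1, 1, nc)
        ang <- stats::runif(1, 0, 2 * pi)
        out <- vector("list", steps)
        for (s in seq_len(steps)) {
          out[[s]] <- .disk_cells(round(rr), round(cc), wid / 2 + 0.6, nr, nc)
          ang <- ang + stats::rnorm(1, 0, 0.3)
          rr <- rr + sin(ang); cc <- cc + cos(ang)
          if (rr < 1 || rr > nr || cc < 1 || cc > nc) break
        }
        unique(unlist(out))
      })
    idx <- idx[!forest[idx]]
    tree[idx] <- TRUE
  }

  # canopy height: smooth stand-scale field plus per-pixel jitter, > 0
  # exactly on tree pixels; realistic village-tree statures (~2.5-13.5 m)
  hfield <- 2.5 + 10 * smooth_field(nr, nc) +
    matrix(stats::runif(nr * nc, 0, 1), nr, nc)
  height_v <- ifelse(tree, hfield, 0)

  # eight divisions as a 2 x 4 rectangular partition of the extent
  div_feats <- list()
  k <- 0L
  for (i in 0:1) for (j in 0:3) {
    k <- k + 1L
    div_feats[[k]] <- list(
      name = division_names[k],
      ring = cbind(c(j, j + 1, j + 1, j) * nc * px / 4,
                   c(i, i, i + 1, i + 1) * nr * px / 2))
  }
  divisions <- polygon_set(div_feats)
  div_labels <- rasterize_features(divisions, template, check_overlap = TRUE)

  structure(list(
    tree_mask = raster_grid(tree * 1, origin, px),
    tree_height = raster_grid(height_v, origin, px),
    terrain = raster_grid(terrain_v, origin, px),
    division_polygons = divisions,
    division_labels = div_labels,
    forest_exclusion = forest_poly,
    forest_mask = raster_grid(forest * 1, origin, px),
    cover_class = raster_grid(cover, origin, px),
    params = params, seed = params$seed), class = "landscape_truth")
}

#' @export
print.landscape_truth <- function(x, ...) {
  d <- dim(x$tree_mask$values)
  cat(sprintf("<landscape_truth> %d x %d px @ %g m, tree fraction %.3f, seed %d\n",
              d[1], d[2], x$tree_mask$px, mean(x$tree_mask$values), x$seed))
  invisible(x)
}

# per-date seasonal greenness weight in (0, 1], peaking mid-series
.season_weights <- function(n) {
  peak <- ceiling(n / 2)
  1 - abs(seq_len(n) - peak) / n
}

# noiseless per-class NDVI trajectory parameters: trees (and forest) peak
# inside the photosynthetic window; agriculture, urban and water stay at or
# below the lower threshold at every date
.ndvi_series <- function(truth, n_dates, peak_veg) {
  s <- .season_weights(n_dates)
  tree <- truth$tree_mask$values == 1 | truth$forest_mask$values == 1
  cls <- truth$cover_class$values
  lapply(seq_len(n_dates), function(d) {
    nd <- matrix(NA_real_, nrow(cls), ncol(cls))
    nd[cls == 1L] <- 0.26 * (0.3 + 0.7 * s[d])       # agriculture
    nd[cls == 2L] <- 0.12 + 0.03 * s[d]              # urban
    nd[cls == 3L] <- -0.25 + 0.10 * s[d]             # water
    nd[tree] <- peak_veg[tree] * (0.65 + 0.35 * s[d])
    nd
  })
}

#' Render a multi-date optical collection
#'
#' Red/NIR reflectances are abstract band pairs carrying an exact NDVI
#' signal: per-date class NDVI trajectories (trees peak in 0.5-0.75 at the
#' greenest date; agriculture <= 0.26, urban ~0.12, water < 0) plus Gaussian
#' noise on the NDVI scale, then converted to bands with constant brightness
#' so that `(nir - red) / (nir + red)` reproduces the noisy NDVI exactly.
#'
#' @param truth a [generate_landscape()] result.
#' @param params the [scene_params()] used (noise, dates, clouds).
#' @return a [scene_collection()] with bands `red` and `nir`.
#' @export
render_optical_series <- function(truth, params = truth$params) {
  stopifnot(inherits(truth, "landscape_truth"))
  n <- params$optical_dates
  if (n < 1) stop("at least one optical date required")
  nr <- nrow(truth$tree_mask$values); nc <- ncol(truth$tree_mask$values)
  set.seed(params$seed + 11L)
  peak_veg <- matrix(stats::runif(nr * nc, 0.50, 0.75), nr, nc)
  series <- .ndvi_series(truth, n, peak_veg)
  L <- 0.8  # band brightness: red + nir
  grids <- lapply(series, function(nd) {
    if (params$optical_noise_sd > 0)
      nd <- nd + matrix(stats::rnorm(nr * nc, 0, params$optical_noise_sd), nr, nc)
    if (params$cloud_fraction > 0) {
      cl <- matrix(stats::runif(nr * nc) < params$cloud_fraction, nr, nc)
      nd[cl] <- stats::runif(sum(cl), -0.05, 0.10)
    }
    nd <- pmin(pmax(nd, -0.999), 0.999)  # argument order preserves dim
    list(red = grid_like(truth$tree_mask, L * (1 - nd) / 2),
         nir = grid_like(truth$tree_mask, L * (1 + nd) / 2))
  })
  scene_collection(grids, dates = sprintf("optical_%02d", seq_len(n)))
}

#' Render ascending and descending SAR collections
#'
#' Per-pixel class backscatter means (dB): trees VH in \[-13, -10\] and VV in
#' \[-7, -3\] (inside the classification windows), agriculture / urban / water
#' outside at least one window. Each date adds Gaussian speckle-like noise in
#' the dB domain. The descending pass carries full-height vertical scan-line
#' stripes of 1-3 px width at -30 dB covering the configured gap fraction;
#' the ascending pass is stripe-free at those locations.
#'
#' @inheritParams render_optical_series
#' @return list with `ascending` and `descending` [scene_collection()]s
#'   (bands `vh`, `vv`) and `stripe_columns` (integer vector).
#' @export
render_sar_series <- function(truth, params = truth$params) {
  stopifnot(inherits(truth, "landscape_truth"))
  n <- params$sar_dates
  if (n < 1) stop("at least one SAR date per pass required")
  nr <- nrow(truth$tree_mask$values); nc <- ncol(truth$tree_mask$values)
  ncell <- nr * nc
  set.seed(params$seed + 21L)
  tree <- truth$tree_mask$values == 1 | truth$forest_mask$values == 1
  cls <- truth$cover_class$values
  mean_for <- function(lo_t, hi_t, lo_a, hi_a, lo_u, hi_u, lo_w, hi_w) {
    m <- matrix(NA_real_, nr, nc)
    m[cls == 1L] <- stats::runif(sum(cls == 1L), lo_a, hi_a)
    m[cls == 2L] <- stats::runif(sum(cls == 2L), lo_u, hi_u)
    m[cls == 3L] <- stats::runif(sum(cls == 3L), lo_w, hi_w)
    m[tree] <- stats::runif(sum(tree), lo_t, hi_t)
    m
  }
  vh_mean <- mean_for(-13, -10, -19, -16, -7, -5, -24, -20)
  vv_mean <- mean_for(-7, -3, -12, -9, -1.5, 0.5, -16, -12)

  stripe <- rep(FALSE, nc)
  target <- round(params$scanline_gap_fraction * ncell)
  while (sum(stripe) * nr < target) {
    w <- sample(1:3, 1)
    w <- min(w, ceiling((target - sum(stripe) * nr) / nr))
    c0 <- sample.int(nc - w + 1L, 1)
    if (any(stripe[c0:(c0 + w - 1L)])) next
    stripe[c0:(c0 + w - 1L)] <- TRUE
  }
  stripe_cols <- which(stripe)

  render_pass <- function(striped) {
    grids <- lapply(seq_len(n), function(d) {
      noise <- function() if (params$sar_speckle_sd > 0)
        matrix(stats::rnorm(ncell, 0, params$sar_speckle_sd), nr, nc) else 0
      vh <- vh_mean + noise(); vv <- vv_mean + noise()
      if (striped && length(stripe_cols)) {
        vh[, stripe_cols] <- -30; vv[, stripe_cols] <- -30
      }
      list(vh = grid_like(truth$tree_mask, vh),
           vv = grid_like(truth$tree_mask, vv))
    })
    scene_collection(grids, dates = sprintf("sar_%02d", seq_len(n)))
  }
  asc <- render_pass(striped = FALSE)
  desc <- render_pass(striped = TRUE)
  list(ascending = asc, descending = desc, stripe_columns = stripe_cols)
}

#' Render the surface model and an independent reference surface
#'
#' `dsm = terrain + slope * height + intercept + noise` over tree pixels and
#' `terrain + noise` elsewhere; the reference surface uses its own bias and
#' an independent noise draw. A slope below 1 mimics radar penetration into
#' the canopy.
#'
#' @inheritParams render_optical_series
#' @return list with `dsm` and `reference_dsm` raster grids.
#' @export
render_dsm <- function(truth, params = truth$params) {
  stopifnot(inherits(truth, "landscape_truth"))
  if (params$dsm_bias[1] <= 0) stop("DSM bias slope must be positive")
  nr <- nrow(truth$terrain$values); nc <- ncol(truth$terrain$values)
  set.seed(params$seed + 31L)
  h <- truth$tree_height$values
  canopy <- function(bias) ifelse(h > 0, bias[1] * h + bias[2], 0)
  noise <- function() if (params$dsm_noise_sd > 0)
    matrix(stats::rnorm(nr * nc, 0, params$dsm_noise_sd), nr, nc) else 0
  list(dsm = grid_like(truth$terrain,
                       truth$terrain$values + canopy(params$dsm_bias) + noise()),
       reference_dsm = grid_like(truth$terrain,
                                 truth$terrain$values +
                                   canopy(params$reference_bias) + noise()))
}

#' Sample bare-ground control points and an independent holdout
#'
#' Points fall only on non-tree, non-forest pixels; elevations are read from
#' the noiseless terrain field. The fitting and holdout sets are disjoint.
#'
#' @param truth a [generate_landscape()] result.
#' @param n number of fitting points (default 820, a 1/10-scale version of
#'   the 8200-point national campaign).
#' @param holdout number of independent validation points (default 40).
#' @param seed integer seed.
#' @return list with data.frames `gcps` and `holdout`
#'   (columns `x`, `y`, `elevation_m`).
#' @export
sample_gcps <- function(truth, n = 820, holdout = 40, seed = truth$seed + 41L) {
  stopifnot(inherits(truth, "landscape_truth"))
  bare <- which(truth$tree_mask$values == 0 & truth$forest_mask$values == 0)
  if (n + holdout > length(bare))
    stop(sprintf("insufficient bare-ground pixels: need %d, have %d",
                 n + holdout, length(bare)))
  set.seed(seed)
  idx <- sample(bare, n + holdout)
  nr <- nrow(truth$terrain$values)
  row <- ((idx - 1L) %% nr) + 1L
  col <- ((idx - 1L) %/% nr) + 1L
  g <- truth$terrain
  pts <- data.frame(x = g$origin[1] + (col - 0.5) * g$px,
                    y = g$origin[2] - (row - 0.5) * g$px,
                    elevation_m = g$values[cbind(row, col)])
  list(gcps = pts[seq_len(n), ], holdout = pts[n + seq_len(holdout), ])
}
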