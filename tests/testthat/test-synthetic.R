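test_that("landscape generation is deterministic and honors the empty case", {
  p0 <- scene_params(size = c(64, 64), tree_fraction = 0, seed = 3)
  expect_equal(sum(generate_landscape(p0)$tree_mask$values), 0)

  p <- scene_params(size = c(96, 96), seed = 7)
  a <- generate_landscape(p); b <- generate_landscape(p)
  expect_identical(a$tree_mask$values, b$tree_mask$values)
  expect_identical(a$terrain$values, b$terrain$values)
  expect_identical(a$tree_height$values, b$tree_height$values)
})

test_that("parameter validation rejects degenerate scenes", {
  expect_error(scene_params(size = c(0, 64)), "positive")
  expect_error(scene_params(size = c(32, 64)), "64 x 64")
  expect_error(scene_params(px = -1), "positive")
  expect_error(scene_params(tree_fraction = 1.2), "\\[0, 1\\]")
  expect_error(scene_params(optical_noise_sd = -0.1), ">= 0")
})

test_that("realized tree fraction tracks the request on 256^2 grids", {
  fr <- vapply(1:20, function(s) {
    t <- generate_landscape(scene_params(tree_fraction = 0.15, seed = s,
                                         sar_dates = 1, optical_dates = 1))
    mean(t$tree_mask$values)
  }, numeric(1))
  expect_true(all(fr >= 0.12 & fr <= 0.18))
})

test_that("truth invariants hold: heights, divisions, forest exclusion", {
  truth <- generate_landscape(scene_params(size = c(128, 128), seed = 11))
  h <- truth$tree_height$values; m <- truth$tree_mask$values
  expect_true(all((h > 0) == (m == 1)))
  # divisions partition: every cell claimed exactly once
  expect_true(all(truth$division_labels > 0))
  expect_equal(length(truth$division_polygons), 8L)
  # terrain is smooth: cellwise gradient bounded well below the relief
  g <- truth$terrain$values
  expect_lt(max(abs(diff(g))), 1)
  expect_lt(max(abs(t(diff(t(g))))), 1)
  # forest block is excluded from TOF truth
  expect_equal(sum(m == 1 & truth$forest_mask$values == 1), 0)
})

test_that("noiseless optical rendering puts classes in their NDVI windows", {
  p <- scene_params(size = c(64, 64), optical_noise_sd = 0, seed = 5,
                    optical_dates = 4)
  truth <- generate_landscape(p)
  opt <- render_optical_series(truth, p)
  nd <- lapply(opt$grids, function(sc) compute_ndvi(sc$red, sc$nir)$values)
  greenest <- Reduce(pmax, nd)
  tree <- truth$tree_mask$values == 1
  expect_true(all(greenest[tree] > 0.35 & greenest[tree] < 0.85))
  nontree <- truth$tree_mask$values == 0 & truth$forest_mask$values == 0
  for (d in nd) expect_true(all(d[nontree] <= 0.3 | d[nontree] >= 0.9))
  # determinism of the renderer
  opt2 <- render_optical_series(truth, p)
  expect_identical(opt$grids[[2]]$nir$values, opt2$grids[[2]]$nir$values)
})

test_that("noiseless SAR means sit inside (trees) or outside (other) windows", {
  p <- scene_params(size = c(64, 64), sar_speckle_sd = 0,
                    scanline_gap_fraction = 0, seed = 5, sar_dates = 3)
  truth <- generate_landscape(p)
  sar <- render_sar_series(truth, p)
  vh <- temporal_average_sar(sar$ascending, "vh")$values
  vv <- temporal_average_sar(sar$ascending, "vv")$values
  tree <- truth$tree_mask$values == 1
  expect_true(all(vh[tree] >= -14 & vh[tree] <= -9))
  expect_true(all(vv[tree] >= -8 & vv[tree] <= -2))
  nontree <- truth$tree_mask$values == 0 & truth$forest_mask$values == 0
  outside <- vh[nontree] < -14 | vh[nontree] > -9 |
    vv[nontree] < -8 | vv[nontree] > -2
  expect_true(all(outside))
  # no stripes requested: descending equals its own mean everywhere valid
  expect_equal(length(sar$stripe_columns), 0L)
})

test_that("scan-line stripes cover the configured gap fraction", {
  counts <- vapply(1:20, function(s) {
    p <- scene_params(scanline_gap_fraction = 0.05, sar_speckle_sd = 0,
                      sar_dates = 1, optical_dates = 1, seed = s)
    truth <- generate_landscape(p)
    sar <- render_sar_series(truth, p)
    sum(sar$descending$grids[[1]]$vh$values == -30)
  }, numeric(1))
  target <- 0.05 * 256^2
  expect_true(all(abs(counts - target) / target <= 0.10))
  # stripes are vertical and far below the VH window
  p <- scene_params(scanline_gap_fraction = 0.05, sar_dates = 1,
                    optical_dates = 1, seed = 1)
  truth <- generate_landscape(p)
  sar <- render_sar_series(truth, p)
  stripe_v <- sar$descending$grids[[1]]$vh$values[, sar$stripe_columns]
  expect_true(all(stripe_v == -30))
})

test_that("surface model encodes terrain plus biased canopy height", {
  p <- scene_params(size = c(64, 64), dsm_noise_sd = 0, seed = 9,
                    dsm_bias = c(0.8, 0), reference_bias = c(1, 0))
  truth <- generate_landscape(p)
  s <- render_dsm(truth, p)
  h <- truth$tree_height$values; t <- truth$terrain$values
  expect_equal(s$dsm$values, t + 0.8 * h)
  # identity reference bias: reference minus terrain is the true height
  expect_equal(s$reference_dsm$values - t, h)
  expect_error(render_dsm(truth, scene_params(dsm_bias = c(-1, 0))),
               "slope must be positive")
})

test_that("GCP sampling stays on bare ground and is reproducible", {
  truth <- generate_landscape(scene_params(size = c(96, 96), seed = 2))
  pts <- sample_gcps(truth, n = 50, holdout = 10, seed = 4)
  expect_equal(nrow(pts$gcps), 50L)
  expect_equal(nrow(pts$holdout), 10L)
  all_pts <- rbind(pts$gcps, pts$holdout)
  expect_equal(extract_at(truth$tree_mask, all_pts$x, all_pts$y),
               rep(0, 60))
  expect_equal(extract_at(truth$terrain, all_pts$x, all_pts$y),
               all_pts$elevation_m)
  expect_equal(nrow(merge(pts$gcps, pts$holdout, by = c("x", "y"))), 0L)
  pts2 <- sample_gcps(truth, n = 50, holdout = 10, seed = 4)
  expect_identical(pts, pts2)
  expect_error(sample_gcps(truth, n = 1e6, holdout = 0), "insufficient")
})
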