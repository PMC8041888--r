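test_that("plot aggregation averages masked pixels per origin-anchored tile", {
  chm <- rg(matrix(8, 30, 30))
  ref <- rg(matrix(10, 30, 30))
  mask <- rg(matrix(1, 30, 30))
  pl <- aggregate_plots(chm, ref, mask, plot_m = 100)
  expect_equal(nrow(pl), 9L)   # 3 x 3 complete 10-px tiles
  expect_true(all(pl$mean_raw == 8 & pl$mean_reference == 10))
  expect_true(all(pl$n_tree_pixels == 100))

  # a tile with no tree pixels is absent
  m2 <- matrix(1, 30, 30); m2[1:10, 1:10] <- 0
  pl2 <- aggregate_plots(chm, ref, rg(m2), plot_m = 100)
  expect_equal(nrow(pl2), 8L)

  # masked-out pixels never contribute to the mean
  v <- matrix(99, 20, 20)
  keep <- outer(1:20, 1:20, function(i, j) (i + j) %% 2 == 0)
  v[keep] <- 4
  pl3 <- aggregate_plots(rg(v), rg(v), rg(keep * 1), plot_m = 100)
  expect_true(all(pl3$mean_raw == 4))
  expect_error(aggregate_plots(rg(matrix(1, 5, 5)), rg(matrix(1, 5, 5)),
                               rg(matrix(1, 5, 5)), plot_m = 100),
               "smaller than one full plot")
})

test_that("outlier exclusion removes only gross raw-vs-reference disagreements", {
  same <- data.frame(plot_id = 1:10, mean_raw = 1:10, mean_reference = 1:10)
  kept <- exclude_outliers(same)
  expect_equal(nrow(kept), 10L)
  expect_equal(attr(kept, "n_excluded"), 0L)

  # 1000 plots differing by 1 m plus one differing by 50 m: P99 of the
  # absolute differences is 1, twice that is 2, so exactly one plot drops
  pl <- data.frame(plot_id = 1:1001, mean_raw = rep(10, 1001),
                   mean_reference = c(rep(11, 1000), 60))
  kept <- exclude_outliers(pl)
  expect_equal(nrow(kept), 1000L)
  expect_equal(attr(kept, "n_excluded"), 1L)
  expect_false(1001 %in% kept$plot_id)
})

test_that("calibration fitting recovers exact linear relationships", {
  ident <- data.frame(mean_raw = c(2, 5, 9, 14), mean_reference = c(2, 5, 9, 14))
  m <- fit_calibration(ident)
  expect_equal(m$slope, 1, tolerance = 1e-12)
  expect_equal(m$intercept, 0, tolerance = 1e-12)
  expect_equal(m$mae_before, 0)
  expect_equal(m$mae_after, 0, tolerance = 1e-12)

  line <- data.frame(mean_raw = c(1, 3, 6, 10),
                     mean_reference = 2 * c(1, 3, 6, 10) + 1)
  m2 <- fit_calibration(line)
  expect_equal(m2$slope, 2, tolerance = 1e-12)
  expect_equal(m2$intercept, 1, tolerance = 1e-12)
  expect_equal(m2$mae_after, 0, tolerance = 1e-12)
  expect_gt(m2$mae_before, 0)

  expect_error(fit_calibration(data.frame(mean_raw = c(3, 3, 3),
                                          mean_reference = c(1, 2, 3))),
               "degenerate")
})

test_that("least-squares correction never raises the MAE above the raw MAE by much", {
  # OLS minimizes squared error; across random linear-plus-noise plots the
  # fitted line should beat the identity line on MAE in practice
  set.seed(5)
  for (k in 1:10) {
    raw <- runif(200, 2, 12)
    ref <- runif(1, 0.9, 1.4) * raw + runif(1, -1, 1) + rnorm(200, 0, 0.3)
    m <- fit_calibration(data.frame(mean_raw = raw, mean_reference = ref))
    expect_lte(m$mae_after, m$mae_before + 1e-9)
  }
})

test_that("applying the calibration enforces the screening rules in order", {
  model <- structure(list(slope = 1, intercept = 0, mae_before = 0,
                          mae_after = 0, n_plots_used = 10L,
                          n_outliers_excluded = 0L, min_height = 2.19,
                          cap_percentile = 99), class = "calibration_model")
  v <- matrix(c(0, -3, 2.0, 2.19, 7, 10), 2, 3)
  out <- apply_calibration(rg(v), model)$values
  expect_true(is.na(out[1, 1]))   # raw 0 m removed before the transform
  expect_true(is.na(out[2, 1]))   # negative raw removed
  expect_true(is.na(out[1, 2]))   # calibrated 2.0 m < minimum height
  expect_equal(out[2, 2], 2.19)   # at the minimum: kept
  expect_equal(out[1, 3], 7)

  # uniform field: P99 equals the value, nothing clipped
  u <- apply_calibration(rg(matrix(10, 6, 6)), model)$values
  expect_true(all(u == 10))

  # per-division cap clips the top of each division independently
  lab <- cbind(matrix(1L, 10, 5), matrix(2L, 10, 5))
  v2 <- matrix(5, 10, 10); v2[1, 1] <- 100; v2[1, 10] <- 40
  capped <- apply_calibration(rg(v2), model, lab)$values
  expect_lt(capped[1, 1], 100)
  expect_lt(capped[1, 10], 40)
  expect_equal(capped[5, 5], 5)

  # monotone within a division for surviving pixels
  set.seed(9)
  v3 <- matrix(runif(400, 1, 30), 20, 20)
  cal <- apply_calibration(rg(v3), model, matrix(1L, 20, 20))$values
  ok <- !is.na(cal)
  expect_true(all(diff(cal[ok][order(v3[ok])]) >= -1e-12))
})

test_that("height summaries report division means, maxima and tall-tree means", {
  lab <- cbind(matrix(1L, 10, 5), matrix(2L, 10, 5))
  v <- matrix(7, 10, 10)
  v[, 6:10] <- rep(c(3, 9), length.out = 50)
  s <- height_summary(rg(v), lab, fra_threshold = 5)
  expect_equal(s$mean_height_m[1], 7)
  expect_equal(s$max_height_m[1], 7)
  expect_equal(s$mean_height_above_threshold_m[1], 7)
  expect_equal(s$mean_height_m[2], 6)    # equal counts of 3 and 9
  expect_equal(s$mean_height_above_threshold_m[2], 9)
  expect_equal(s$division[3], "Total")

  # tall-tree mean dominates the overall mean when short trees exist
  set.seed(13)
  for (k in 1:8) {
    v <- matrix(runif(100, 2.2, 12), 10, 10)
    s <- height_summary(rg(v), matrix(1L, 10, 10))
    if (any(v <= 5))
      expect_gte(s$mean_height_above_threshold_m[1], s$mean_height_m[1])
  }
})

test_that("the full height pipeline recovers a known DSM bias", {
  # one compact check here; the multi-seed recovery lives in the acceptance suite
  res <- run_pipeline(pipeline_config(seed = 3, out_dir = tempfile(),
                                      stages = "calibrate"))
  m <- res$calibration$model
  expect_lt(abs(m$slope - 1 / 0.8) / (1 / 0.8), 0.05)
  expect_lte(m$mae_after, 0.6)
  expect_lte(m$mae_after, m$mae_before)
})
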