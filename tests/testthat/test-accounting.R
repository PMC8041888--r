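test_that("division summaries conserve area and percentages", {
  m <- matrix(0, 20, 20)
  m[1:5, 1:10] <- 1          # 50 px in the west half
  m[11:12, 11:20] <- 1       # 20 px in the east half
  mask <- rg(m)
  divs <- c_polygons(rect_polygon(0, 100, 0, 200, "West"),
                     rect_polygon(100, 200, 0, 200, "East"))
  s <- division_summary(mask, divs)
  expect_equal(s$tof_ha, c(50, 20, 70) * 0.01)
  expect_equal(s$division_area_ha, c(2, 2, 4))
  expect_equal(s$pct_tof, c(25, 10, 17.5))
  expect_equal(s$tof_ha[3], sum(s$tof_ha[1:2]))

  overlapping <- c_polygons(rect_polygon(0, 150, 0, 200, "a"),
                            rect_polygon(50, 200, 0, 200, "b"))
  expect_error(division_summary(mask, overlapping), "overlapping")

  empty <- division_summary(rg(matrix(0, 20, 20)), divs)
  expect_true(all(empty$tof_ha == 0))
})

test_that("printed division areas reproduce their percentages and totals", {
  tabs <- tof_reference_tables()
  s <- summarize_division_areas(tabs$table1)
  expect_equal(round(s$pct_tof[s$division == "Barisal"], 1), 22.8)
  expect_equal(s$tof_ha[s$division == "Total"], 2233578)
  expect_equal(round(s$pct_tof[s$division == "Total"], 1), 15.1)
})

test_that("cover maps convert to extent with a strictly-greater rule", {
  cov <- rg(matrix(c(0, 0.5, 12, NA), 2, 2))
  m <- cover_to_extent(cov)$values
  expect_equal(m[1, 1], 0)
  expect_equal(m[2, 1], 1)
  expect_equal(m[1, 2], 1)
  expect_true(is.na(m[2, 2]))
  expect_equal(cover_to_extent(cov, threshold_pct = 10)$values[2, 1], 0)
  expect_error(cover_to_extent(rg(matrix(120, 1, 1))), "\\[0, 100\\]")
})

test_that("map comparisons difference per division with the b-denominator", {
  a <- data.frame(division = c("X", "Y"), tof_ha = c(300, 100))
  b <- data.frame(division = c("Y", "X"), area_ha = c(50, 200))
  cmp <- compare_maps(a, b)
  expect_equal(cmp$diff_ha, c(100, 50, 150))
  expect_equal(cmp$pct_diff[1], 100 * 100 / 200)
  expect_equal(compare_maps(a, a)$diff_ha, c(0, 0, 0))
  expect_error(compare_maps(a, data.frame(division = "Z", tof_ha = 1)),
               "do not match")
})

test_that("per-capita area follows the definition at 3 decimals", {
  expect_equal(per_capita(1, 1), 1.000)
  expect_equal(per_capita(0, 1e6), 0.000)
  expect_equal(per_capita(2233578, 161356039), 0.014)
  expect_error(per_capita(1, 0), "positive")
})

test_that("stratified accuracy collapses to known closed forms", {
  # single stratum: a simple proportion
  counts <- data.frame(stratum = "s1",
                       map_label = c(1, 1, 0, 0),
                       ref_label = c(1, 0, 0, 1),
                       n = c(45, 5, 45, 5))
  rep1 <- stratified_accuracy(counts, c(s1 = 1000))
  expect_equal(rep1$overall_accuracy, 0.90)
  # binomial normal-approximation CI in the one-stratum limit
  q <- 50 / 100   # reference class 1 proportion
  se <- sqrt(q * (1 - q) / 99)
  expect_equal(rep1$area_estimates$ci95_ha[rep1$area_estimates$class == 1],
               1.96 * se * 1000, tolerance = 1e-12)

  # two equal-weight strata with accuracies 0.8 and 1.0 average to 0.9
  counts2 <- data.frame(stratum = c("a", "a", "b"),
                        map_label = c(1, 1, 0),
                        ref_label = c(1, 0, 0),
                        n = c(80, 20, 50))
  rep2 <- stratified_accuracy(counts2, c(a = 500, b = 500))
  expect_equal(rep2$overall_accuracy, 0.9)

  # perfect agreement: accuracy 1, all CIs zero
  counts3 <- data.frame(stratum = c("a", "b"), map_label = c(1, 0),
                        ref_label = c(1, 0), n = c(30, 70))
  rep3 <- stratified_accuracy(counts3, c(a = 300, b = 700))
  expect_equal(rep3$overall_accuracy, 1)
  expect_true(all(rep3$area_estimates$ci95_ha == 0))
  expect_equal(rep3$area_estimates$area_ha[rep3$area_estimates$class == 1],
               300)

  expect_error(stratified_accuracy(counts, c(s2 = 100)), "stratum")
})

test_that("validation points use the mask label with a geolocation buffer", {
  m <- matrix(0, 10, 10); m[5, 5] <- 1
  mask <- rg(m)
  # cell (5,5) center: x 45, y 55
  on <- data.frame(x = 45, y = 55, ref_label = 1, stratum = "s")
  expect_equal(validate_points(mask, on, buffer_m = 0)$map_label, 1)
  # one pixel off: miss with no buffer, hit with a 10 m buffer
  off <- data.frame(x = 55, y = 55, ref_label = 1, stratum = "s")
  expect_equal(validate_points(mask, off, buffer_m = 0)$map_label, 0)
  expect_equal(validate_points(mask, off, buffer_m = 10)$map_label, 1)
  # outside the raster: excluded and counted
  out <- data.frame(x = -50, y = 55, ref_label = 1, stratum = "s")
  tal <- validate_points(mask, rbind(on, out), buffer_m = 0)
  expect_equal(attr(tal, "n_excluded"), 1L)
  expect_equal(sum(tal$n), 1L)
})

test_that("the stratified sampler draws the design from each division-class", {
  truth <- generate_landscape(scene_params(size = c(128, 128), seed = 19,
                                           optical_dates = 1, sar_dates = 1))
  pts <- sample_validation_points(truth$tree_mask, truth$division_polygons,
                                  n_per_class = 20, seed = 2)
  expect_true(all(table(pts$stratum) <= 20))
  expect_equal(extract_at(truth$tree_mask, pts$x, pts$y), pts$map_class)
  pts2 <- sample_validation_points(truth$tree_mask, truth$division_polygons,
                                   n_per_class = 20, seed = 2)
  expect_identical(pts, pts2)
})

test_that("stratified CI half-widths match a bootstrap oracle", {
  counts <- data.frame(stratum = c("a", "a", "b", "b"),
                       map_label = c(1, 1, 0, 0),
                       ref_label = c(1, 0, 0, 1),
                       n = c(82, 18, 120, 30))
  areas <- c(a = 60000, b = 40000)
  rep_ <- stratified_accuracy(counts, areas)
  ci <- rep_$area_estimates$ci95_ha[rep_$area_estimates$class == 1]

  set.seed(101)
  B <- 10000
  pa <- rbinom(B, 100, 82 / 100) / 100
  pb <- rbinom(B, 150, 30 / 150) / 150
  boot_area <- 100000 * (0.6 * pa + 0.4 * pb)
  boot_ci <- 1.96 * stats::sd(boot_area)
  expect_lt(abs(ci - boot_ci) / boot_ci, 0.10)
})
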