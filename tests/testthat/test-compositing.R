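test_that("NDVI follows its definition and handles degenerate inputs", {
  red <- rg(matrix(c(0.1, 0.3, 0, NA), 2, 2))
  nir <- rg(matrix(c(0.5, 0.3, 0, 0.4), 2, 2))
  nd <- compute_ndvi(red, nir)$values
  expect_equal(nd[1, 1], (0.5 - 0.1) / (0.5 + 0.1), tolerance = 1e-12)
  expect_equal(nd[1, 1], 0.6667, tolerance = 1e-4)
  expect_equal(nd[2, 1], 0)            # red = nir > 0
  expect_true(is.na(nd[1, 2]))         # 0/0 denominator
  expect_true(is.na(nd[2, 2]))         # nodata propagates
  expect_error(compute_ndvi(rg(matrix(-0.1, 2, 2)), rg(matrix(0.5, 2, 2))),
               "non-negative")
  expect_error(compute_ndvi(red, rg(matrix(0.5, 3, 3))), "not co-registered")
})

make_two_date <- function() {
  # pixel (1,1): NDVI 0.2 then 0.7; pixel (1,2): nodata at all dates
  red1 <- rg(matrix(c(0.4, NA), 1, 2)); nir1 <- rg(matrix(c(0.6, NA), 1, 2))
  red2 <- rg(matrix(c(0.15, NA), 1, 2)); nir2 <- rg(matrix(c(0.85, NA), 1, 2))
  scene_collection(list(list(red = red1, nir = nir1),
                        list(red = red2, nir = nir2)),
                   dates = c("d1", "d2"))
}

test_that("greenest composite selects the argmax-NDVI date per pixel", {
  oc <- greenest_composite(make_two_date())
  expect_equal(oc$ndvi$values[1, 1], 0.7)
  expect_equal(oc$bands$red$values[1, 1], 0.15)   # bands come from date 2
  expect_equal(oc$greenest_date$values[1, 1], 2)
  expect_true(is.na(oc$ndvi$values[1, 2]))        # nodata at all dates
  expect_true(is.na(oc$greenest_date$values[1, 2]))

  # single-image collection: identity
  single <- scene_collection(list(make_two_date()$grids[[1]]), dates = "d1")
  oc1 <- greenest_composite(single)
  expect_equal(oc1$bands$red$values, single$grids[[1]]$red$values)

  # idempotence: compositing a composite returns itself
  again <- scene_collection(list(list(red = oc$bands$red, nir = oc$bands$nir)),
                            dates = "composite")
  oc2 <- greenest_composite(again)
  expect_equal(oc2$ndvi$values, oc$ndvi$values)
  expect_equal(oc2$bands$nir$values, oc$bands$nir$values)

  # NDVI ties are broken by the earliest date
  tie <- scene_collection(list(list(red = rg(matrix(0.2)), nir = rg(matrix(0.6))),
                               list(red = rg(matrix(0.1)), nir = rg(matrix(0.3)))),
                          dates = c("d1", "d2"))
  expect_equal(greenest_composite(tie)$greenest_date$values[1, 1], 1)
})

test_that("SAR temporal averaging happens in the linear power domain", {
  mk <- function(...) {
    vals <- list(...)
    scene_collection(lapply(vals, function(v) list(vh = rg(matrix(v)))),
                     dates = as.character(seq_along(vals)))
  }
  expect_equal(temporal_average_sar(mk(-10, -10, -10), "vh")$values[1, 1], -10)
  # hand-evaluated linear mean of -10 and -20 dB
  expect_equal(temporal_average_sar(mk(-10, -20), "vh")$values[1, 1],
               10 * log10((0.1 + 0.01) / 2), tolerance = 1e-12)
  expect_equal(temporal_average_sar(mk(-10, -20), "vh")$values[1, 1],
               -12.60, tolerance = 1e-2)
  # must differ from the naive dB-domain mean (-15)
  expect_gt(temporal_average_sar(mk(-10, -20), "vh")$values[1, 1], -15 + 1)
  # single date: identity
  expect_equal(temporal_average_sar(mk(-7.3), "vh")$values[1, 1], -7.3)
  expect_error(temporal_average_sar(mk(-10), "vv"), "not present")
})

test_that("linear-domain mean dominates the dB-domain mean (Jensen)", {
  set.seed(42)
  for (k in 1:25) {
    db <- stats::runif(sample(2:8, 1), -30, 0)
    col <- scene_collection(lapply(db, function(v) list(vh = rg(matrix(v)))),
                            dates = as.character(seq_along(db)))
    lin <- temporal_average_sar(col, "vh")$values[1, 1]
    expect_gte(lin, mean(db) - 1e-12)
  }
})

test_that("scan-line filling takes the ascending donor below the threshold", {
  desc <- rg(matrix(c(-30, -11, NA, -26), 2, 2))
  asc <- rg(matrix(c(-11, -12, -13, -27), 2, 2))
  f <- fill_scan_lines(desc, asc, low_db_threshold = -25)
  expect_equal(f$filled$values[1, 1], -11)  # filled, flagged
  expect_equal(f$fill_flag$values[1, 1], 1)
  expect_equal(f$filled$values[2, 1], -11)  # above threshold: untouched
  expect_equal(f$fill_flag$values[2, 1], 0)
  expect_equal(f$filled$values[1, 2], -13)  # nodata also takes the donor
  # both low: ascending value retained, still flagged (single donor rule)
  expect_equal(f$filled$values[2, 2], -27)
  expect_equal(f$fill_flag$values[2, 2], 1)
})
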