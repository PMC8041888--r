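#' Per-division TOF area summary from a mask
#'
#' Counts tree pixels per administrative division, converts to hectares with
#' the geotransform-derived pixel area, and appends a national total row.
#' Division areas come from the rasterized polygon coverage, so the national
#' TOF area is exactly the sum of the division areas (integer pixel counts).
#'
#' @param mask binary TOF `raster_grid`.
#' @param divisions `polygon_set` of divisions; they must partition the
#'   extent (overlapping divisions are rejected).
#' @param ci optional 95% confidence intervals on the mapped area, either a
#'   named numeric vector (± ha per division) or an [stratified_accuracy()]
#'   report per division in a named list (the TOF-class `ci95_ha` is taken).
#' @return data.frame with `division`, `tof_ha`, `ci95_ha`,
#'   `division_area_ha`, `pct_tof`.
#' @export
division_summary <- function(mask, divisions, ci = NULL) {
  lab <- rasterize_features(divisions, mask, check_overlap = TRUE)
  pa <- pixel_area_ha(mask)
  nms <- divisions$names
  tof <- vapply(seq_along(nms), function(k)
    sum(mask$values[lab == k] == 1, na.rm = TRUE) * pa, numeric(1))
  darea <- vapply(seq_along(nms), function(k) sum(lab == k) * pa, numeric(1))
  civ <- rep(NA_real_, length(nms))
  if (!is.null(ci)) {
    if (is.numeric(ci)) {
      civ <- unname(ci[nms])
    } else if (is.list(ci)) {
      civ <- vapply(nms, function(nm) {
        rep_ <- ci[[nm]]
        if (is.null(rep_)) return(NA_real_)
        ae <- rep_$area_estimates
        out <- ae$ci95_ha[ae$class == "TOF"]
        if (length(out)) out else NA_real_
      }, numeric(1))
    }
  }
  out <- data.frame(division = nms, tof_ha = tof, ci95_ha = civ,
                    division_area_ha = darea, pct_tof = 100 * tof / darea)
  tot <- data.frame(division = "Total", tof_ha = sum(tof), ci95_ha = NA_real_,
                    division_area_ha = sum(darea),
                    pct_tof = 100 * sum(tof) / sum(darea))
  rbind(out, tot)
}

#' Percentages and totals from printed per-division areas
#'
#' The accounting arithmetic of [division_summary()] applied to a table of
#' areas (e.g. a published division table): per-division percent cover and a
#' national total row. A national CI is not derivable from per-division CIs,
#' so the total CI is left blank unless supplied.
#'
#' @param df data.frame with `division`, `tof_ha`, `division_area_ha` and
#'   optionally `ci95_ha`.
#' @param total_ci optional national 95% CI (± ha).
#' @return data.frame like [division_summary()]'s.
#' @export
summarize_division_areas <- function(df, total_ci = NA_real_) {
  stopifnot(all(c("division", "tof_ha", "division_area_ha") %in% names(df)))
  ci <- if ("ci95_ha" %in% names(df)) df$ci95_ha else rep(NA_real_, nrow(df))
  out <- data.frame(division = df$division, tof_ha = df$tof_ha, ci95_ha = ci,
                    division_area_ha = df$division_area_ha,
                    pct_tof = 100 * df$tof_ha / df$division_area_ha)
  rbind(out, data.frame(division = "Total", tof_ha = sum(df$tof_ha),
                        ci95_ha = total_ci,
                        division_area_ha = sum(df$division_area_ha),
                        pct_tof = 100 * sum(df$tof_ha) /
                          sum(df$division_area_ha)))
}

#' Convert a percent-cover map to a binary extent mask
#'
#' Cover maps report canopy cover per pixel rather than tree extent; for a
#' like-for-like comparison all pixels with cover above the threshold
#' (default: over 0%) become tree pixels.
#'
#' @param percent_cover `raster_grid` with values in \[0, 100\] or nodata.
#' @param threshold_pct cover threshold; strictly-greater rule.
#' @return binary `raster_grid`.
#' @export
cover_to_extent <- function(percent_cover, threshold_pct = 0) {
  v <- percent_cover$values
  if (any(v < 0 | v > 100, na.rm = TRUE))
    stop("percent cover must lie in [0, 100]")
  grid_like(percent_cover, (v > threshold_pct) * 1)
}

#' Per-division differences between two area tables
#'
#' `diff_ha = a - b` and `pct_diff = 100 * (a - b) / b` per division, with a
#' national row. The denominator is the comparison map `b`.
#'
#' @param summary_a,summary_b data.frames with `division` and an area column
#'   (`tof_ha` or `area_ha`); the division sets must match.
#' @return data.frame with `division`, `area_a_ha`, `area_b_ha`, `diff_ha`,
#'   `pct_diff`.
#' @export
compare_maps <- function(summary_a, summary_b) {
  area_col <- function(df) {
    nm <- intersect(c("tof_ha", "area_ha"), names(df))[1L]
    if (is.na(nm)) stop("no area column (tof_ha / area_ha) found")
    df[[nm]]
  }
  a <- summary_a[summary_a$division != "Total", , drop = FALSE]
  b <- summary_b[summary_b$division != "Total", , drop = FALSE]
  if (!setequal(a$division, b$division))
    stop("division sets do not match")
  b <- b[match(a$division, b$division), , drop = FALSE]
  va <- area_col(a); vb <- area_col(b)
  out <- data.frame(division = a$division, area_a_ha = va, area_b_ha = vb,
                    diff_ha = va - vb, pct_diff = 100 * (va - vb) / vb)
  rbind(out, data.frame(division = "Total", area_a_ha = sum(va),
                        area_b_ha = sum(vb), diff_ha = sum(va) - sum(vb),
                        pct_diff = 100 * (sum(va) - sum(vb)) / sum(vb)))
}

#' Tree area per person
#'
#' @param total_ha national tree area in hectares.
#' @param population head count (> 0).
#' @return hectares per person, rounded to 3 decimals.
#' @export
per_capita <- function(total_ha, population) {
  if (population <= 0) stop("population must be positive")
  round(total_ha / population, 3)
}

#' Stratified accuracy assessment and unbiased area estimation
#'
#' Standard good-practice estimators for a stratified validation sample.
#' With strata `h` of weight `W_h` (mapped-area proportions) and `n_h`
#' points of which `n_h(m, r)` carry map label `m` and reference label `r`:
#' cell proportions `p(m, r) = sum_h W_h n_h(m, r) / n_h`; overall accuracy
#' is the diagonal sum; the unbiased area of class `c` is
#' `A_total * p(., c)`; its standard error follows the stratified variance
#' formula `V = sum_h W_h^2 q_h (1 - q_h) / (n_h - 1)` with `q_h` the
#' within-stratum proportion of reference class `c`; the 95% CI half-width
#' is `1.96 * SE * A_total`. With a single stratum this collapses to the
#' binomial normal-approximation interval.
#'
#' @param counts data.frame with columns `stratum`, `map_label`,
#'   `ref_label`, `n` — tallies of validation points, e.g. from
#'   [validate_points()]. Every sampled stratum needs `sum(n) > 0`.
#' @param mapped_areas named numeric: mapped area (ha) per stratum; defines
#'   the stratum weights `W_h` and the total area.
#' @return object of class `accuracy_report`: `strata` (weights and sizes),
#'   `overall_accuracy`, `users_accuracy`, `producers_accuracy` (named by
#'   class), `area_estimates` (data.frame with `class`, `proportion`,
#'   `area_ha`, `se_ha`, `ci95_ha`), `total_area_ha`.
#' @export
stratified_accuracy <- function(counts, mapped_areas) {
  stopifnot(all(c("stratum", "map_label", "ref_label", "n") %in% names(counts)))
  if (any(counts$n < 0)) stop("counts must be non-negative")
  strata <- names(mapped_areas)
  if (is.null(strata)) stop("mapped_areas must be named by stratum")
  if (any(mapped_areas <= 0)) stop("mapped areas must be positive")
  n_h <- vapply(strata, function(s) sum(counts$n[counts$stratum == s]),
                numeric(1))
  if (any(n_h == 0)) stop("every stratum needs at least one sampled point")
  A_tot <- sum(mapped_areas)
  W <- mapped_areas / A_tot
  classes <- sort(unique(c(counts$map_label, counts$ref_label)))
  # cell proportions p(m, r)
  p <- matrix(0, length(classes), length(classes),
              dimnames = list(map = classes, ref = classes))
  for (i in seq_len(nrow(counts))) {
    s <- counts$stratum[i]
    p[as.character(counts$map_label[i]), as.character(counts$ref_label[i])] <-
      p[as.character(counts$map_label[i]), as.character(counts$ref_label[i])] +
      W[[s]] * counts$n[i] / n_h[[s]]
  }
  overall <- sum(diag(p))
  users <- diag(p) / rowSums(p)
  producers <- diag(p) / colSums(p)
  area_rows <- lapply(classes, function(cl) {
    q_h <- vapply(strata, function(s) {
      sel <- counts$stratum == s
      sum(counts$n[sel & counts$ref_label == cl]) / n_h[[s]]
    }, numeric(1))
    V <- sum(W^2 * q_h * (1 - q_h) / pmax(n_h - 1, 1))
    se <- sqrt(V)
    data.frame(class = cl, proportion = sum(p[, as.character(cl)]),
               area_ha = A_tot * sum(p[, as.character(cl)]),
               se_ha = se * A_tot, ci95_ha = 1.96 * se * A_tot)
  })
  structure(list(strata = data.frame(stratum = strata, W = unname(W),
                                     n = unname(n_h),
                                     mapped_area_ha = unname(mapped_areas)),
                 confusion_proportions = p,
                 overall_accuracy = overall,
                 users_accuracy = users, producers_accuracy = producers,
                 area_estimates = do.call(rbind, area_rows),
                 total_area_ha = A_tot),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf("<accuracy_report> %d strata, overall accuracy %.3f\n",
              nrow(x$strata), x$overall_accuracy))
  print(x$area_estimates, row.names = FALSE)
  invisible(x)
}

#' Tally validation points against the map with a geolocation buffer
#'
#' The mapped label of a point is the mask value at its cell; to absorb
#' geolocation error, a point whose reference label disagrees with the map
#' counts as agreeing if any cell within `buffer_m` of the point carries the
#' reference label. Points outside the raster (or on nodata) are excluded
#' and counted in the `n_excluded` attribute.
#'
#' @param mask binary TOF `raster_grid` (1 = TOF, 0 = non-TOF).
#' @param points data.frame with `x`, `y`, `ref_label` (0/1) and `stratum`.
#' @param buffer_m buffer radius in meters (0 disables the rule).
#' @return data.frame of per-stratum confusion counts (`stratum`,
#'   `map_label`, `ref_label`, `n`) for [stratified_accuracy()].
#' @export
validate_points <- function(mask, points, buffer_m = 10) {
  stopifnot(all(c("x", "y", "ref_label", "stratum") %in% names(points)))
  rc <- locate_cells(mask, points$x, points$y)
  v <- mask$values
  d <- dim(v)
  mlab <- rep(NA_real_, nrow(points))
  ok <- !is.na(rc$row)
  mlab[ok] <- v[cbind(rc$row[ok], rc$col[ok])]
  excluded <- sum(!ok | is.na(mlab))
  rpx <- floor(buffer_m / mask$px)
  if (rpx > 0) {
    off <- expand.grid(dr = -rpx:rpx, dc = -rpx:rpx)
    off <- off[(off$dr^2 + off$dc^2) * mask$px^2 <= buffer_m^2, , drop = FALSE]
    for (i in which(ok & !is.na(mlab))) {
      if (mlab[i] == points$ref_label[i]) next
      rr <- rc$row[i] + off$dr; cc <- rc$col[i] + off$dc
      keep <- rr >= 1 & rr <= d[1] & cc >= 1 & cc <= d[2]
      if (any(v[cbind(rr[keep], cc[keep])] == points$ref_label[i],
              na.rm = TRUE))
        mlab[i] <- points$ref_label[i]
    }
  }
  use <- ok & !is.na(mlab)
  tal <- stats::aggregate(
    list(n = rep(1L, sum(use))),
    by = list(stratum = points$stratum[use], map_label = mlab[use],
              ref_label = points$ref_label[use]),
    FUN = sum)
  structure(tal[, c("stratum", "map_label", "ref_label", "n")],
            n_excluded = excluded)
}

#' Stratified validation sample from a map
#'
#' Sampling design mirrored on national practice: a fixed number of points
#' per mapped class per division, drawn uniformly without replacement from
#' the cells of that class, strata labeled `division:class`.
#'
#' @param mask binary TOF `raster_grid`.
#' @param divisions `polygon_set` of divisions (or integer label matrix with
#'   names attribute).
#' @param n_per_class points per class per division (default 500).
#' @param seed integer seed.
#' @return data.frame with `x`, `y`, `stratum`, `map_class`; reference
#'   labels are attached by the caller (e.g. from truth or photo
#'   interpretation).
#' @export
sample_validation_points <- function(mask, divisions, n_per_class = 500,
                                     seed = 1L) {
  if (is.matrix(divisions)) {
    lab <- divisions
    nms <- attr(divisions, "names_") %||% as.character(seq_len(max(lab)))
  } else {
    lab <- rasterize_features(divisions, mask)
    nms <- divisions$names
  }
  set.seed(seed)
  nr <- nrow(mask$values)
  out <- list()
  for (k in seq_along(nms)) for (cl in c(0, 1)) {
    cells <- which(lab == k & mask$values == cl)
    if (!length(cells)) next
    take <- sample(cells, min(n_per_class, length(cells)))
    row <- ((take - 1L) %% nr) + 1L
    col <- ((take - 1L) %/% nr) + 1L
    out[[length(out) + 1L]] <- data.frame(
      x = mask$origin[1] + (col - 0.5) * mask$px,
      y = mask$origin[2] - (row - 0.5) * mask$px,
      stratum = paste0(nms[k], ":", ifelse(cl == 1, "TOF", "NonTOF")),
      map_class = cl)
  }
  do.call(rbind, out)
}

#' Mapped area per stratum for a stratified design
#'
#' Companion to [sample_validation_points()]: hectares of each
#' `division:class` stratum, used as the stratum weights.
#'
#' @inheritParams sample_validation_points
#' @return named numeric vector of hectares.
#' @export
stratum_areas <- function(mask, divisions) {
  if (is.matrix(divisions)) {
    lab <- divisions
    nms <- attr(divisions, "names_") %||% as.character(seq_len(max(lab)))
  } else {
    lab <- rasterize_features(divisions, mask)
    nms <- divisions$names
  }
  pa <- pixel_area_ha(mask)
  out <- c()
  for (k in seq_along(nms)) for (cl in c(0, 1)) {
    n <- sum(lab == k & mask$values == cl, na.rm = TRUE)
    if (n > 0)
      out[paste0(nms[k], ":", ifelse(cl == 1, "TOF", "NonTOF"))] <- n * pa
  }
  out
}
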