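# connected-component labeling on a 0/1/NA matrix via the adjacency graph;
# labels are assigned in column-major order of first occurrence, background
# stays 0 and NA propagates
label_components <- function(values, connectivity = 4L) {
  stopifnot(connectivity %in% c(4L, 8L))
  nr <- nrow(values); nc <- ncol(values)
  fg <- which(values == 1)  # NA drops out
  out <- matrix(0L, nr, nc)
  out[is.na(values)] <- NA_integer_
  n1 <- length(fg)
  if (n1 == 0L) return(out)
  id <- integer(nr * nc)
  id[fg] <- seq_len(n1)
  is_fg <- logical(nr * nc); is_fg[fg] <- TRUE
  edge_pairs <- function(dr, dc) {
    r <- ((fg - 1L) %% nr) + 1L
    c <- ((fg - 1L) %/% nr) + 1L
    ok <- r + dr >= 1L & r + dr <= nr & c + dc >= 1L & c + dc <= nc
    nb <- fg[ok] + dr + dc * nr
    keep <- is_fg[nb]
    cbind(id[fg[ok][keep]], id[nb[keep]])
  }
  edges <- rbind(edge_pairs(1L, 0L), edge_pairs(0L, 1L))
  if (connectivity == 8L)
    edges <- rbind(edges, edge_pairs(1L, 1L), edge_pairs(1L, -1L))
  g <- igraph::make_empty_graph(n = n1, directed = FALSE)
  if (nrow(edges) > 0L) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)$membership
  # relabel by order of first occurrence for deterministic output
  first <- match(unique(comp), comp)
  relab <- integer(max(comp))
  relab[comp[sort(first)]] <- seq_along(first)
  out[fg] <- relab[comp]
  out
}

#' Label TOF patches by edge connectivity
#'
#' Clumps tree pixels that share at least one pixel edge (4-connectivity) and
#' labels the components 1..K in scan order; background is 0 and nodata
#' propagates. Note the deliberate contrast with the classification sieve,
#' which clumps with 8-connectivity.
#'
#' @param mask binary `raster_grid`.
#' @param connectivity 4 (default, edge only) or 8 (edge or corner).
#' @return `raster_grid` of integer patch labels.
#' @export
label_patches <- function(mask, connectivity = 4L) {
  grid_like(mask, label_components(mask$values, connectivity) + 0)
}

.size_class_breaks <- c(0, 1, 5, 10, 100, 1000, 10000, 100000)
.size_class_names <- c("<=1 ha", "1-5 ha", "5-10 ha", "10-100 ha",
                       "100-1000 ha", "1000-10000 ha", "10000-100000 ha")

#' Assign patch areas to size classes
#'
#' Bin edges at 1, 5, 10, 100, 1000, 10000, 100000 ha; each bin is
#' lower-exclusive / upper-inclusive, with the first bin (0, 1\].
#'
#' @param area_ha numeric areas in hectares.
#' @return factor with the seven size-class levels.
#' @export
size_class <- function(area_ha) {
  cut(area_ha, breaks = .size_class_breaks, labels = .size_class_names,
      right = TRUE, include.lowest = FALSE)
}

#' Per-patch area table
#'
#' One record per labeled patch with its pixel count, area in hectares and
#' size class. Pixel area defaults to the geotransform-derived value
#' (`px^2 / 1e4`, so 0.01 ha at 10 m): synthetic grids are planar, and
#' real-data users must supply an equal-area grid.
#'
#' @param labels a [label_patches()] result.
#' @param pixel_area hectares per pixel.
#' @return data.frame with `patch_id`, `pixel_count`, `area_ha`,
#'   `size_class`.
#' @export
patch_table <- function(labels, pixel_area = pixel_area_ha(labels)) {
  if (pixel_area <= 0) stop("pixel_area must be positive")
  lab <- labels$values
  k <- suppressWarnings(max(lab, na.rm = TRUE))
  if (!is.finite(k) || k == 0)
    return(data.frame(patch_id = integer(), pixel_count = integer(),
                      area_ha = numeric(),
                      size_class = size_class(numeric())))
  counts <- tabulate(lab[lab > 0], nbins = k)
  data.frame(patch_id = seq_len(k), pixel_count = counts,
             area_ha = counts * pixel_area,
             size_class = size_class(counts * pixel_area))
}

#' Patch-count and area percentages per size class
#'
#' For each size class: number of patches, percentage of all patches and
#' percentage of total TOF area. Each percentage column sums to 100 up to
#' rounding.
#'
#' @param table a [patch_table()] result, or a pre-tabulated data.frame with
#'   columns `size_class`, `n_patches` and optionally `area_ha` (as printed
#'   in a patch-size report).
#' @return data.frame with `size_class`, `n_patches`, `pct_patches`,
#'   `area_ha`, `pct_area`.
#' @export
size_class_summary <- function(table) {
  if (all(c("size_class", "n_patches") %in% names(table))) {
    n <- table$n_patches
    cls <- factor(table$size_class, levels = levels(size_class(numeric()))
                  [levels(size_class(numeric())) %in% as.character(table$size_class)])
    area <- if ("area_ha" %in% names(table)) table$area_ha else rep(NA_real_, length(n))
    out <- data.frame(size_class = as.character(table$size_class),
                      n_patches = n, area_ha = area)
  } else {
    if (nrow(table) == 0L) {
      warning("empty patch table: empty summary")
      return(data.frame(size_class = character(), n_patches = integer(),
                        pct_patches = numeric(), area_ha = numeric(),
                        pct_area = numeric()))
    }
    agg_n <- tapply(table$patch_id, table$size_class, length, default = 0L)
    agg_a <- tapply(table$area_ha, table$size_class, sum, default = 0)
    out <- data.frame(size_class = names(agg_n),
                      n_patches = as.integer(agg_n),
                      area_ha = as.numeric(agg_a))
    out <- out[out$n_patches > 0L, , drop = FALSE]
  }
  out$pct_patches <- 100 * out$n_patches / sum(out$n_patches)
  out$pct_area <- if (all(is.na(out$area_ha))) NA_real_ else
    100 * out$area_ha / sum(out$area_ha)
  rownames(out) <- NULL
  out[, c("size_class", "n_patches", "pct_patches", "area_ha", "pct_area")]
}
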