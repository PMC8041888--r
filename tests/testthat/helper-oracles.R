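# Independent oracles and small fixture builders used across the suite.

# wrap a matrix as a 10 m raster grid with origin at (0, nrow*10)
rg <- function(values, px = 10) {
  values <- as.matrix(values)
  raster_grid(values, origin = c(0, nrow(values) * px), px = px)
}

# brute-force flood-fill connected-component labeling (queue-based),
# independent of the package's graph-based implementation
flood_fill_label <- function(values, connectivity = 4L) {
  nr <- nrow(values); nc <- ncol(values)
  lab <- matrix(0L, nr, nc)
  lab[is.na(values)] <- NA_integer_
  nbr <- if (connectivity == 4L)
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  else
    cbind(c(-1, 1, 0, 0, -1, -1, 1, 1), c(0, 0, -1, 1, -1, 1, -1, 1))
  k <- 0L
  for (c0 in seq_len(nc)) for (r0 in seq_len(nr)) {
    if (is.na(values[r0, c0]) || values[r0, c0] != 1 || lab[r0, c0] != 0L) next
    k <- k + 1L
    queue <- list(c(r0, c0)); lab[r0, c0] <- k
    while (length(queue)) {
      p <- queue[[1L]]; queue <- queue[-1L]
      for (j in seq_len(nrow(nbr))) {
        r <- p[1] + nbr[j, 1]; c <- p[2] + nbr[j, 2]
        if (r < 1 || r > nr || c < 1 || c > nc) next
        if (!is.na(values[r, c]) && values[r, c] == 1 && lab[r, c] == 0L) {
          lab[r, c] <- k
          queue[[length(queue) + 1L]] <- c(r, c)
        }
      }
    }
  }
  lab
}

# direct-sum IDW at each cell center: plain loops, no chunking, no shortcuts
brute_idw <- function(gcps, like, power = 2) {
  cc <- cell_centers(like)
  d <- dim(like$values)
  out <- matrix(NA_real_, d[1], d[2])
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    dist <- sqrt((gcps$x - cc$x[j])^2 + (gcps$y - cc$y[i])^2)
    if (any(dist < 1e-6 * like$px)) {
      out[i, j] <- gcps$elevation_m[which.min(dist)]
    } else {
      w <- dist^(-power)
      out[i, j] <- sum(w * gcps$elevation_m) / sum(w)
    }
  }
  out
}

# precision/recall of a predicted mask against truth
mask_pr <- function(pred, truth) {
  p <- pred$values; t <- truth$values
  tp <- sum(p == 1 & t == 1, na.rm = TRUE)
  c(precision = tp / sum(p == 1, na.rm = TRUE),
    recall = tp / sum(t == 1, na.rm = TRUE))
}

# classify a rendered scene end to end (composites -> thresholds -> sieve)
classify_scene <- function(truth, cfg = threshold_config()) {
  oc <- greenest_composite(render_optical_series(truth))
  sar <- render_sar_series(truth)
  sc <- sar_composite(sar$ascending, sar$descending)
  classify_tof(oc$ndvi, sc$vh_db, sc$vv_db, truth$forest_exclusion, cfg)
}

# truth restricted to clumps at or above the sieve size (expected recovery)
sieved_truth <- function(truth, cfg = threshold_config()) {
  sieve_mask(truth$tree_mask, cfg)
}
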