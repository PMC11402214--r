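# Independent brute-force oracles used to validate the package's operators.
# These deliberately recompute every criterion by plain direct summation /
# graph search and share no code with the implementation.

# Huang-Wang fuzziness by direct summation for every candidate threshold.
huang_oracle <- function(counts) {
  occ <- which(counts > 0) - 1
  gmin <- min(occ); gmax <- max(occ)
  C <- gmax - gmin
  best_t <- NA_integer_; best_e <- Inf
  for (t in gmin:(gmax - 1)) {
    num0 <- 0; den0 <- 0; num1 <- 0; den1 <- 0
    for (g in 0:255) {
      if (counts[g + 1] == 0) next
      if (g <= t) { num0 <- num0 + g * counts[g + 1]; den0 <- den0 + counts[g + 1] }
      else { num1 <- num1 + g * counts[g + 1]; den1 <- den1 + counts[g + 1] }
    }
    m0 <- num0 / den0; m1 <- num1 / den1
    E <- 0
    for (g in 0:255) {
      if (counts[g + 1] == 0) next
      m <- if (g <= t) m0 else m1
      u <- 1 / (1 + abs(g - m) / C)
      s <- if (u <= 0 || u >= 1) 0 else -u * log(u) - (1 - u) * log(1 - u)
      E <- E + counts[g + 1] * s
    }
    if (E < best_e) { best_e <- E; best_t <- t }
  }
  best_t
}

# Li-Lee cross-entropy (levels shifted by +1) by direct summation.
mce_oracle <- function(counts) {
  occ <- which(counts > 0) - 1
  gmin <- min(occ); gmax <- max(occ)
  best_t <- NA_integer_; best_ce <- Inf
  for (t in gmin:(gmax - 1)) {
    m0 <- 0; w0 <- 0; m1 <- 0; w1 <- 0
    for (g in 0:255) {
      if (counts[g + 1] == 0) next
      if (g <= t) { m0 <- m0 + (g + 1) * counts[g + 1]; w0 <- w0 + counts[g + 1] }
      else { m1 <- m1 + (g + 1) * counts[g + 1]; w1 <- w1 + counts[g + 1] }
    }
    ce <- -m0 * log(m0 / w0) - m1 * log(m1 / w1)
    if (ce < best_ce) { best_ce <- ce; best_t <- t }
  }
  best_t
}

# Per-label Dijkstra over an explicit growth region; pixels outside the
# region stay 0, foreign seed pixels are not traversed, and the final label
# is the lexicographic argmin of (path cost, label id).
dijkstra_oracle <- function(seeds, guide, region, lambda, connectivity = 8) {
  nr <- nrow(seeds); nc <- ncol(seeds)
  labels <- sort(unique(seeds[seeds > 0]))
  offs <- if (connectivity == 8) {
    cbind(di = c(-1, 1, 0, 0, -1, -1, 1, 1), dj = c(0, 0, -1, 1, -1, 1, -1, 1))
  } else {
    cbind(di = c(-1, 1, 0, 0), dj = c(0, 0, -1, 1))
  }
  dists <- list()
  for (L in labels) {
    allowed <- (region | seeds > 0) & (seeds == 0 | seeds == L)
    dist <- matrix(Inf, nr, nc)
    dist[seeds == L] <- 0
    visited <- matrix(FALSE, nr, nc)
    visited[!allowed] <- TRUE
    repeat {
      d <- dist; d[visited] <- Inf
      u <- which.min(d)
      if (!is.finite(d[u])) break
      visited[u] <- TRUE
      ui <- (u - 1) %% nr + 1; uj <- (u - 1) %/% nr + 1
      for (k in seq_len(nrow(offs))) {
        vi <- ui + offs[k, 1]; vj <- uj + offs[k, 2]
        if (vi < 1 || vi > nr || vj < 1 || vj > nc) next
        if (!allowed[vi, vj]) next
        w <- sqrt((guide[ui, uj] - guide[vi, vj])^2 +
                  lambda * (offs[k, 1]^2 + offs[k, 2]^2))
        nd <- dist[ui, uj] + w
        if (nd < dist[vi, vj]) dist[vi, vj] <- nd
      }
    }
    dists[[as.character(L)]] <- dist
  }
  out <- matrix(0L, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (seeds[i, j] > 0) { out[i, j] <- seeds[i, j]; next }
    if (!region[i, j]) next
    best_d <- Inf; best_l <- 0L
    for (L in labels) {
      d <- dists[[as.character(L)]][i, j]
      if (d < best_d || (d == best_d && L < best_l)) { best_d <- d; best_l <- L }
    }
    if (is.finite(best_d)) out[i, j] <- best_l
  }
  out
}

# Disk IoU by direct rasterisation on a fine pixel grid.
disk_iou_raster <- function(r1, c1, rad1, r2, c2, rad2, pad = 2) {
  lo_r <- floor(min(r1 - rad1, r2 - rad2)) - pad
  hi_r <- ceiling(max(r1 + rad1, r2 + rad2)) + pad
  lo_c <- floor(min(c1 - rad1, c2 - rad2)) - pad
  hi_c <- ceiling(max(c1 + rad1, c2 + rad2)) + pad
  step <- 0.1
  rr <- seq(lo_r, hi_r, by = step)
  cc <- seq(lo_c, hi_c, by = step)
  in1 <- outer((rr - r1)^2, (cc - c1)^2, `+`) <= rad1^2
  in2 <- outer((rr - r2)^2, (cc - c2)^2, `+`) <= rad2^2
  sum(in1 & in2) / sum(in1 | in2)
}

# Exact two-sided Mann-Whitney p by enumeration of all rank assignments
# (no ties assumed). Returns the p for the observed U of x.
mw_enum_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  U_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combs <- utils::combn(nx + ny, nx)
  Us <- apply(combs, 2, function(ix) sum(seq_len(nx + ny)[ix]) - nx * (nx + 1) / 2)
  p <- 2 * min(mean(Us <= U_obs), mean(Us >= U_obs))
  min(1, p)
}

# Compact geometry/model fixtures for fast tests.
small_geometry <- function(n_cells = 10, ...) {
  args <- list(field_shape = c(160, 160), islet_radius_px = 60,
               n_cells = n_cells, min_center_spacing_px = 22)
  over <- list(...)
  args[names(over)] <- over
  do.call(geometry_params, args)
}

noiseless_model <- function(background_level = 0) {
  intensity_model(cell_level_cv = 0, gaussian_noise_sd = 0,
                  background_level = background_level)
}

# Greedy matching of detections to true centroids: a true nucleus counts as
# recovered when some detection lies within its radius; a detection with no
# true nucleus within that nucleus' radius is a false positive.
match_detections <- function(truth, dets) {
  if (nrow(dets) == 0) {
    return(list(recall = 0, false_positives = 0))
  }
  d <- sqrt(outer(truth$nucleus_centroids$row, dets$row, `-`)^2 +
            outer(truth$nucleus_centroids$col, dets$col, `-`)^2)
  hit <- apply(d, 1, min) <= truth$nucleus_radii
  fp <- sum(apply(d, 2, function(col) all(col > truth$nucleus_radii)))
  list(recall = mean(hit), false_positives = fp)
}
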