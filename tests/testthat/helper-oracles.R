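# Independent oracles used across the suite. These deliberately take the
# naive route (flood fill, exhaustive enumeration, direct quadrature) so they
# share no code path with the implementation they check.

# Stack-based flood fill connected-component labelling.
flood_fill_label <- function(mask, connectivity = 8) {
  nx <- nrow(mask); ny <- ncol(mask)
  lab <- matrix(0L, nx, ny)
  nb <- if (connectivity == 8) {
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  }
  cur <- 0L
  for (j in seq_len(ny)) for (i in seq_len(nx)) {
    if (!mask[i, j] || lab[i, j] != 0L) next
    cur <- cur + 1L
    stack <- list(c(i, j))
    lab[i, j] <- cur
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (k in seq_len(nrow(nb))) {
        x <- p[1] + nb[k, 1]; y <- p[2] + nb[k, 2]
        if (x >= 1 && x <= nx && y >= 1 && y <= ny &&
            mask[x, y] && lab[x, y] == 0L) {
          lab[x, y] <- cur
          stack[[length(stack) + 1L]] <- c(x, y)
        }
      }
    }
  }
  lab
}

# Canonical form of a labelling: remap labels to first-appearance order so
# two labelings can be compared regardless of label numbering.
canonical_labels <- function(lab) {
  ids <- unique(lab[lab > 0])
  out <- lab
  out[lab > 0] <- match(lab[lab > 0], ids)
  out
}

# Exhaustive minimizer of sum RSS + beta * (#changepoints) over all
# changepoint sets of size <= max_cp (for short traces).
exhaustive_segment_cost <- function(x, beta, max_cp = 3) {
  n <- length(x)
  cs <- c(0, cumsum(x)); cs2 <- c(0, cumsum(x^2))
  seg_rss <- function(i, j) {
    s <- cs[j + 1] - cs[i]
    (cs2[j + 1] - cs2[i]) - s^2 / (j - i + 1)
  }
  best <- seg_rss(1, n)
  best_cps <- integer(0)
  for (k in seq_len(max_cp)) {
    combos <- utils::combn(n - 1, k)
    for (c_i in seq_len(ncol(combos))) {
      cps <- combos[, c_i]
      bounds <- c(0, cps, n)
      cost <- k * beta
      for (s in seq_len(length(bounds) - 1))
        cost <- cost + seg_rss(bounds[s] + 1, bounds[s + 1])
      if (cost < best - 1e-12) { best <- cost; best_cps <- cps }
    }
  }
  list(cost = best, changepoints = best_cps)
}

# Cost of a segmentation returned by count_steps, on the same penalized
# objective.
segmentation_cost <- function(x, seg, beta) {
  cost <- beta * (nrow(seg) - 1)
  for (s in seq_len(nrow(seg))) {
    xs <- x[seg$start[s]:seg$end[s]]
    cost <- cost + sum((xs - mean(xs))^2)
  }
  cost
}

# Single-linkage count of resolvable clusters: true centres closer than
# r_px are one resolvable object.
resolvable_count <- function(centers, r_px) {
  n <- nrow(centers)
  if (n < 2) return(n)
  d <- as.matrix(stats::dist(centers[, c("x_px", "y_px")]))
  g <- d <= r_px
  lab <- seq_len(n)
  repeat {
    new <- vapply(seq_len(n), function(i) min(lab[g[i, ]]), numeric(1))
    if (identical(new, lab)) break
    lab <- new
  }
  length(unique(lab))
}
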