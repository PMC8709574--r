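# Independent brute-force oracles used across the suite. These deliberately
# re-derive each quantity by the dumbest available route so they share no
# code with the implementation under test.

# established-block timeline by explicit run scanning
oracle_blocks <- function(labels, m) {
  cat_ <- strategy_block(labels)
  n <- length(cat_)
  ev_start <- integer(0)
  ev_val <- integer(0)
  for (j in seq_len(n)) {
    v <- cat_[j]
    if (is.na(v)) next
    if (j > 1 && !is.na(cat_[j - 1]) && cat_[j - 1] == v) next # not a run start
    len <- 0L
    k <- j
    while (k <= n && !is.na(cat_[k]) && cat_[k] == v) {
      len <- len + 1L
      k <- k + 1L
    }
    if (len >= m) {
      ev_start <- c(ev_start, j)
      ev_val <- c(ev_val, v)
    }
  }
  est <- rep(NA_integer_, n)
  for (t in seq_len(n)) {
    w <- which(ev_start <= t)
    if (length(w)) est[t] <- ev_val[max(w)]
  }
  est
}

# Sholl counts by dense sampling along each segment (sign changes of d - r)
oracle_sholl_counts <- function(tree, radii, spacing = 0.01) {
  nd <- tree$nodes
  ctr <- as.numeric(nd[match(tree$soma_id, nd$id), c("x", "y", "z")])
  child <- which(nd$parent != -1)
  pidx <- match(nd$parent[child], nd$id)
  vapply(radii, function(r) {
    total <- 0L
    for (i in seq_along(child)) {
      p1 <- as.numeric(nd[pidx[i], c("x", "y", "z")])
      p2 <- as.numeric(nd[child[i], c("x", "y", "z")])
      len <- sqrt(sum((p2 - p1)^2))
      if (len == 0) next
      ts <- seq(0, 1, length.out = max(3L, ceiling(len / spacing)))
      d <- sqrt(colSums((outer(p2 - p1, ts) + (p1 - ctr))^2))
      s <- sign(d - r)
      total <- total + sum(s[-1] * s[-length(s)] < 0)
    }
    total
  }, integer(1))
}

# U statistic by O(n^2) pair counting
oracle_u <- function(a, b) {
  less <- sum(outer(a, b, "<")) + sum(outer(a, b, "==")) / 2
  min(less, length(a) * length(b) - less)
}

# maturity day by scanning every window
oracle_mature_day <- function(days, scores, criterion, len, final = TRUE) {
  o <- order(days)
  days <- days[o]
  scores <- scores[o]
  n <- length(days)
  if (n >= len) {
    for (i in seq_len(n - len + 1L)) {
      if (all(scores[i:(i + len - 1L)] >= criterion)) {
        return(if (final) days[i + len - 1L] else days[i])
      }
    }
  }
  NA_integer_
}

# arbitrary (not generator-shaped) random reconstruction
random_tree <- function(n_nodes = 30, step = 25, seed = 1) {
  set.seed(seed)
  nodes <- data.frame(id = 1L, type = 1L, x = 0, y = 0, z = 0,
                      radius = 2, parent = -1L)
  for (i in 2:n_nodes) {
    p <- sample.int(i - 1L, 1L)
    pos <- as.numeric(nodes[p, c("x", "y", "z")]) + rnorm(3, 0, step)
    nodes <- rbind(nodes, data.frame(id = i, type = 3L, x = pos[1],
                                     y = pos[2], z = pos[3], radius = 0.5,
                                     parent = nodes$id[p]))
  }
  neuron_tree(nodes)
}

# hand-assembled feature vector for classifier rule tests
make_features <- function(frac_outer_ring = 0, frac_corridor = 0,
                          frac_focal_zone = 0, frac_central = 0,
                          frac_per_quadrant = rep(0.25, 4),
                          heading_efficiency = 0, circularity = 0,
                          mean_radius = 50, path_length = 500, latency = 30) {
  structure(
    list(frac_outer_ring = frac_outer_ring,
         frac_inner_area = 1 - frac_outer_ring,
         frac_corridor = frac_corridor,
         frac_focal_zone = frac_focal_zone,
         frac_central = frac_central,
         frac_per_quadrant = frac_per_quadrant,
         heading_efficiency = heading_efficiency,
         circularity = circularity, mean_radius = mean_radius,
         path_length = path_length, latency = latency),
    class = "trial_features"
  )
}

# straight-line trial sampled densely between waypoints
line_trial <- function(pts, geometry, n_per_cm = 10, duration = 10) {
  seg <- sqrt(rowSums(diff(pts)^2))
  arc <- c(0, cumsum(seg))
  grid <- seq(0, arc[length(arc)], length.out = max(50, round(arc[length(arc)] * n_per_cm)))
  swim_trial(data.frame(
    t = seq(0, duration, length.out = length(grid)),
    x = approx(arc, pts[, 1], xout = grid)$y,
    y = approx(arc, pts[, 2], xout = grid)$y
  ), geometry)
}
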