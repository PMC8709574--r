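radial_cable <- function(tip = 95) {
  neuron_tree(data.frame(id = 1:2, type = c(1L, 3L),
                         x = c(0, tip), y = 0, z = 0,
                         radius = c(2, 0.5), parent = c(-1L, 1L)))
}

test_that("total dendritic length is an exact segment sum", {
  expect_equal(total_length(radial_cable(30)), 30)

  g <- gen_neuron_tree(n_branches = 2, trunk_length = 50, branch_length = 40,
                       seed = 3)
  expect_equal(total_length(g$tree), 130)

  # random tree equals an independent brute-force sum
  tr <- random_tree(50, seed = 8)
  nd <- tr$nodes
  acc <- 0
  for (i in seq_len(nrow(nd))) {
    if (nd$parent[i] == -1) next
    p <- nd[match(nd$parent[i], nd$id), ]
    acc <- acc + sqrt((nd$x[i] - p$x)^2 + (nd$y[i] - p$y)^2 + (nd$z[i] - p$z)^2)
  }
  expect_equal(total_length(tr), acc, tolerance = 1e-12)

  # soma-internal segments excluded unless requested
  soma2 <- neuron_tree(data.frame(id = 1:3, type = c(1L, 1L, 3L),
                                  x = c(0, 5, 5), y = c(0, 0, 40), z = 0,
                                  radius = c(2, 2, 0.5), parent = c(-1L, 1L, 2L)))
  expect_equal(total_length(soma2), 40)
  expect_equal(total_length(soma2, include_soma = TRUE), 45)

  # invariant under node reindexing
  perm <- sample(nrow(tr$nodes))
  nd2 <- tr$nodes[perm, ]
  relabel <- setNames(seq_along(perm), tr$nodes$id[perm])
  nd2$id <- relabel[as.character(nd2$id)]
  nd2$parent <- ifelse(nd2$parent == -1, -1L,
                       relabel[as.character(nd2$parent)])
  expect_equal(total_length(neuron_tree(nd2)), total_length(tr),
               tolerance = 1e-12)
})

test_that("Sholl profiles are exact on geometry-forced cases", {
  p <- sholl_profile(radial_cable(95))$profile
  expect_equal(p$radius, c(20, 40, 60, 80, 100))
  expect_equal(p$intersections, c(1L, 1L, 1L, 1L, 0L))

  # trunk to 50 then two branches reaching past 80
  tr <- neuron_tree(data.frame(
    id = 1:4, type = c(1L, 3L, 3L, 3L),
    x = c(0, 50, 90, 90), y = c(0, 0, 20, -20), z = 0,
    radius = c(2, rep(0.5, 3)), parent = c(-1L, 1L, 2L, 2L)
  ))
  p <- sholl_profile(tr)$profile
  expect_equal(p$intersections[p$radius %in% c(20, 40, 60, 80)],
               c(1L, 1L, 2L, 2L))

  # node exactly on a sphere: counted once, with the outward segment
  split_at_60 <- neuron_tree(data.frame(
    id = 1:3, type = c(1L, 3L, 3L), x = c(0, 60, 95), y = 0, z = 0,
    radius = c(2, 0.5, 0.5), parent = c(-1L, 1L, 2L)
  ))
  p <- sholl_profile(split_at_60)$profile
  expect_equal(p$intersections[p$radius == 60], 1L)

  # a chord dipping inside a sphere and out again counts twice
  chord <- neuron_tree(data.frame(
    id = 1:3, type = c(1L, 3L, 3L), x = c(0, 30, 30), y = c(0, 10, -10),
    z = 0, radius = c(2, 0.5, 0.5), parent = c(-1L, 1L, 2L)
  ))
  # the (30,10)->(30,-10) chord dips to distance 30 and back out (2 hits),
  # plus one crossing on the soma->(30,10) segment
  expect_equal(sholl_profile(chord, increment = 31)$profile$intersections[1], 3L)

  expect_error(sholl_profile(radial_cable(), increment = 0), "positive")
})

test_that("Sholl profiles match the dense-sampling oracle on random trees", {
  for (seed in 1:30) {
    tr <- random_tree(n_nodes = sample(5:40, 1), step = 30, seed = seed)
    p <- sholl_profile(tr)
    expect_identical(p$profile$intersections,
                     oracle_sholl_counts(tr, p$profile$radius))
  }
})

test_that("Sholl profiles are invariant under rigid isometries", {
  set.seed(17)
  for (i in 1:5) {
    tr <- random_tree(25, seed = 40 + i)
    q <- qr.Q(qr(matrix(rnorm(9), 3)))
    if (det(q) < 0) q[, 1] <- -q[, 1]
    shift <- rnorm(3, 0, 100)
    xyz <- as.matrix(tr$nodes[, c("x", "y", "z")]) %*% t(q)
    xyz <- sweep(xyz, 2, -shift)
    nd <- tr$nodes
    nd[, c("x", "y", "z")] <- xyz
    expect_identical(sholl_profile(neuron_tree(nd))$profile,
                     sholl_profile(tr)$profile)
  }
})

test_that("branching complexity counts points, tips and order", {
  cable <- neuron_tree(data.frame(id = 1:3, type = c(1L, 3L, 3L),
                                  x = c(0, 10, 20), y = 0, z = 0,
                                  radius = 1, parent = c(-1L, 1L, 2L)))
  expect_equal(unname(branching_complexity(cable)), c(0L, 1L, 0L))

  bif <- neuron_tree(data.frame(id = 1:4, type = c(1L, 3L, 3L, 3L),
                                x = c(0, 10, 20, 20), y = c(0, 0, 5, -5),
                                z = 0, radius = 1,
                                parent = c(-1L, 1L, 2L, 2L)))
  expect_equal(unname(branching_complexity(bif)), c(1L, 2L, 1L))

  # random binary trees: tips = bifurcations + 1
  set.seed(3)
  for (i in 1:10) {
    nd <- data.frame(id = 1:2, type = c(1L, 3L), x = c(0, 10), y = 0, z = 0,
                     radius = 1, parent = c(-1L, 1L))
    leaves <- 2L
    for (b in seq_len(sample(1:8, 1))) {
      kids <- nd$id[!nd$id %in% nd$parent & nd$id != 1L]
      at <- kids[sample.int(length(kids), 1)]
      base <- as.numeric(nd[match(at, nd$id), c("x", "y", "z")])
      for (k in 1:2) {
        nid <- max(nd$id) + 1L
        nd <- rbind(nd, data.frame(id = nid, type = 3L,
                                   x = base[1] + rnorm(1, 0, 10),
                                   y = base[2] + rnorm(1, 0, 10),
                                   z = base[3] + rnorm(1, 0, 10),
                                   radius = 1, parent = at))
      }
    }
    bc <- branching_complexity(neuron_tree(nd))
    expect_equal(bc[["n_tips"]], bc[["n_branch_points"]] + 1L)
  }
})

test_that("laminar-reach classification uses strict boundary rules", {
  b <- laminar_bounds(50, 100)
  expect_equal(classify_dcx_extent(radial_cable(60), b), "short")
  expect_equal(classify_dcx_extent(radial_cable(120), b), "long")
  expect_equal(classify_dcx_extent(radial_cable(100), b), "short") # tie: strict
  expect_equal(classify_dcx_extent(radial_cable(40), b), "unclassifiable")
  expect_error(laminar_bounds(100, 50), "gcl_iml_boundary")
})

test_that("cell density is counts over area", {
  expect_equal(cell_density(10, 0.5), 20)
  expect_equal(cell_density(0, 0.8), 0)
  expect_equal(cell_density(7, 0.35), 20)
  expect_equal(cell_density(c(10, 7), c(0.5, 0.35)), c(20, 20))
  expect_error(cell_density(5, 0), "positive")
  expect_error(cell_density(-1, 1), "non-negative")
})

test_that("generated trees verify their attached ground truth", {
  for (seed in 1:10) {
    nb <- sample(0:5, 1)
    g <- gen_neuron_tree(n_branches = nb, trunk_length = runif(1, 30, 80),
                         branch_length = runif(nb + 1, 20, 60), seed = seed)
    expect_equal(total_length(g$tree), g$ground_truth$total_length,
                 tolerance = 1e-9)
    p <- sholl_profile(g$tree)$profile
    expect_equal(p$radius, g$ground_truth$sholl$radius)
    expect_equal(p$intersections, g$ground_truth$sholl$intersections)
  }
})
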