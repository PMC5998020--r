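test_that("graph construction honors the distance threshold and weights", {
  # equilateral triangle, side 50 nm
  tri <- cbind(c(0, 50, 25), c(0, 0, 25 * sqrt(3)), 0)
  g <- build_graph(tri, T = 80)
  expect_equal(nrow(g$edges), 3)
  expect_equal(node_measures(g)$degree, rep(2, 3))
  # no edge beyond T
  g2 <- build_graph(cbind(c(0, 100), 0, 0), T = 80)
  expect_equal(nrow(g2$edges), 0)
  # w = 1/d
  g3 <- build_graph(cbind(c(0, 50), 0, 0), T = 80, mode = "weighted")
  expect_equal(g3$edges$w, 0.02)
  # coincident points never get infinite weight (capped at 1/1 nm)
  g4 <- build_graph(rbind(c(0, 0, 0), c(0, 0, 0)), T = 80, mode = "weighted")
  expect_equal(g4$edges$w, 1)
})

test_that("node measures match hand calculations", {
  tri <- cbind(c(0, 50, 25), c(0, 0, 25 * sqrt(3)), 0)
  nm <- node_measures(build_graph(tri, T = 80))
  expect_equal(nm$degree, rep(2, 3))
  expect_equal(nm$ndeg, rep(2, 3))
  expect_equal(nm$cc, rep(1, 3))
  expect_equal(nm$wdegree, rep(0.04, 3), tolerance = 1e-9)
  # path a-b-c
  path <- cbind(c(0, 50, 100), 0, 0)
  nmp <- node_measures(build_graph(path, T = 60))
  expect_equal(nmp$degree, c(1, 2, 1))
  expect_equal(nmp$cc[2], 0)
  expect_equal(nmp$ndeg[1], 2)   # a's only neighbor is b with degree 2
})

test_that("graph measures cover paths, components and degeneracy", {
  tri <- cbind(c(0, 50, 25), c(0, 0, 25 * sqrt(3)), 0)
  gm <- graph_measures(build_graph(tri, T = 80))
  expect_equal(gm$char_path, 1)
  expect_equal(gm$n_components, 1)
  # two disjoint triangles: 2 components, path over connected pairs only
  two <- rbind(tri, sweep(tri, 2, c(5000, 0, 0), "+"))
  gm2 <- graph_measures(build_graph(two, T = 80))
  expect_equal(gm2$n_components, 2)
  expect_equal(gm2$char_path, 1)
  # single node flagged degenerate with path 0
  gm1 <- graph_measures(build_graph(matrix(0, 1, 3), T = 80))
  expect_true(gm1$degenerate)
  expect_equal(gm1$char_path, 0)
})

test_that("edges and degrees are monotone in the threshold", {
  set.seed(31)
  pts <- matrix(runif(150, 0, 500), ncol = 3)
  thresholds <- c(40, 80, 120, 200)
  prev_edges <- data.frame(i = integer(0), j = integer(0))
  prev_deg <- rep(0, nrow(pts))
  for (T in thresholds) {
    g <- build_graph(pts, T)
    key_now <- paste(g$edges$i, g$edges$j)
    key_prev <- paste(prev_edges$i, prev_edges$j)
    expect_true(all(key_prev %in% key_now))
    deg <- node_measures(g)$degree
    expect_true(all(deg >= prev_deg))
    prev_edges <- g$edges; prev_deg <- deg
  }
})

test_that("leading-eigenvector partitions match known community structure", {
  # K5: no community structure, one module
  k5 <- graph_from_edges(5, clique_edges(1:5))
  p5 <- newman_partition(k5)
  expect_equal(p5$n_modules, 1)
  # two K4 cliques joined by one edge: exactly the two cliques
  g8 <- graph_from_edges(8, rbind(clique_edges(1:4), clique_edges(5:8),
                                  c(1, 5)))
  p8 <- newman_partition(g8)
  expect_equal(p8$n_modules, 2)
  expect_equal(length(unique(p8$assignment[1:4])), 1)
  expect_equal(length(unique(p8$assignment[5:8])), 1)
  # ring of 3 triangles weakly interconnected: three modules
  ring <- graph_from_edges(9, rbind(clique_edges(1:3), clique_edges(4:6),
                                    clique_edges(7:9),
                                    c(3, 4), c(6, 7), c(9, 1)))
  p9 <- newman_partition(ring)
  expect_equal(p9$n_modules, 3)
  expect_error(newman_partition(graph_from_edges(0, matrix(0, 0, 2))))
})

test_that("returned modularity is near the exhaustive-search maximum", {
  graphs <- list(
    graph_from_edges(8, rbind(clique_edges(1:4), clique_edges(5:8),
                              c(1, 5))),
    graph_from_edges(9, rbind(clique_edges(1:3), clique_edges(4:6),
                              clique_edges(7:9), c(3, 4), c(6, 7), c(9, 1))),
    graph_from_edges(6, rbind(clique_edges(1:3), clique_edges(4:6),
                              c(1, 4))),
    graph_from_edges(7, rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(5, 6),
                              c(6, 7))))
  set.seed(17)   # plus random Erdos-Renyi graphs
  for (r in 1:3) {
    n <- 7
    all_pairs <- t(combn(n, 2))
    sel <- all_pairs[runif(nrow(all_pairs)) < 0.4, , drop = FALSE]
    if (nrow(sel) >= 1)
      graphs[[length(graphs) + 1]] <- graph_from_edges(n, sel)
  }
  for (g in graphs) {
    got <- newman_partition(g)$Q
    qmax <- brute_force_max_modularity(g)
    expect_gte(got, 0)               # at least the trivial partition
    expect_gte(got, 0.9 * qmax)
  }
})

test_that("matched random point sets reproduce the ROI's spatial profile", {
  set.seed(23)
  pts <- cbind(runif(5000, 0, 3000), runif(5000, 0, 3000),
               rnorm(5000, 500, 120))
  roi <- as_roi(pts)
  rnd <- random_points_like(roi, seed = 9)
  expect_equal(nrow(rnd), 5000)
  expect_true(all(rnd[, 1] >= roi$bounds[1, 1] &
                    rnd[, 1] <= roi$bounds[1, 2]))
  expect_true(all(rnd[, 2] >= roi$bounds[2, 1] &
                    rnd[, 2] <= roi$bounds[2, 2]))
  # Z moments within standard error at n = 5000
  expect_equal(mean(rnd[, 3]), mean(pts[, 3]),
               tolerance = 4 * 120 / sqrt(5000) / abs(mean(pts[, 3])))
  expect_equal(sd(rnd[, 3]), sd(pts[, 3]), tolerance = 0.1)
  # reproducibility
  expect_identical(rnd, random_points_like(roi, seed = 9))
  expect_error(random_points_like(as_roi(matrix(0, 1, 3)), 1), ">= 2")
})
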