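# Shared fixtures and independent oracles, all built in code.

# A proximity_graph from an explicit edge list (unit distances by default).
graph_from_edges <- function(n, edges, d = 50, T = 80,
                             mode = "unweighted") {
  edges <- matrix(edges, ncol = 2, byrow = FALSE)
  dd <- rep_len(d, nrow(edges))
  structure(list(n = n,
                 edges = data.frame(i = pmin(edges[, 1], edges[, 2]),
                                    j = pmax(edges[, 1], edges[, 2]),
                                    d = dd, w = 1 / pmax(dd, 1)),
                 threshold_T = T, mode = mode),
            class = "proximity_graph")
}

clique_edges <- function(members) t(utils::combn(members, 2))

# Exhaustive maximum-modularity oracle: enumerate all set partitions
# (restricted growth strings) of <= ~10 nodes.
brute_force_max_modularity <- function(g) {
  n <- g$n
  best <- -Inf
  a <- integer(n)          # restricted growth string
  recurse <- function(pos, maxid) {
    if (pos > n) {
      q <- modularity_score(g, a[1:n] + 1L)
      if (q > best) best <<- q
      return(invisible(NULL))
    }
    for (v in 0:(maxid + 1L)) {
      a[pos] <<- v
      recurse(pos + 1L, max(maxid, v))
    }
  }
  recurse(1L, -1L)
  best
}

# Uniform points on a sphere shell of given radius.
shell_points <- function(n, radius, center = c(0, 0, 0), seed = 1) {
  set.seed(seed)
  u <- matrix(stats::rnorm(n * 3), ncol = 3)
  sweep(radius * u / sqrt(rowSums(u^2)), 2, center, "+")
}

# Uniform points in a solid ball.
ball_points <- function(n, radius, center = c(0, 0, 0), seed = 1) {
  set.seed(seed)
  u <- matrix(stats::rnorm(n * 3), ncol = 3)
  u <- u / sqrt(rowSums(u^2)) * radius * stats::runif(n)^(1 / 3)
  sweep(u, 2, center, "+")
}

# Simulate n isolated single-antibody rods on a sparse grid; returns the
# pooled raw event list.
simulate_rod_field <- function(n_rod, seed = 100, spacing = 1000,
                               p = sim_params(), epitope_count = 1) {
  gx <- ((seq_len(n_rod) - 1) %% 25) * spacing
  gy <- ((seq_len(n_rod) - 1) %/% 25) * spacing
  pts <- vector("list", n_rod)
  for (i in seq_len(n_rod)) {
    ep <- place_epitopes(
      ground_truth("rod", epitope_count = epitope_count,
                   center = c(gx[i], gy[i], 0)), seed = seed + i)
    pts[[i]] <- simulate_blinks(ep, p, seed = seed + 5000L + i)$points
  }
  event_list(do.call(rbind, pts))
}

# Adjusted Rand index between two labelings.
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

# Planted Gaussian descriptor matrices in the 28-feature space.
planted_descriptors <- function(n_per_group, centers_scale = 10, sd = 1,
                                k = 2, seed = 1) {
  set.seed(seed)
  d <- length(blob_descriptor_names())
  centers <- matrix(stats::rnorm(k * d, 0, centers_scale), k)
  X <- do.call(rbind, lapply(seq_len(k), function(g)
    sweep(matrix(stats::rnorm(n_per_group * d, 0, sd), n_per_group), 2,
          centers[g, ], "+")))
  colnames(X) <- blob_descriptor_names()
  list(X = X, labels = rep(seq_len(k), each = n_per_group),
       centers = centers)
}
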