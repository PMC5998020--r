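test_that("mean shift separates well-separated clusters exactly", {
  set.seed(71)
  a <- matrix(rnorm(300, 0, 30), ncol = 3)
  b <- sweep(matrix(rnorm(300, 0, 30), ncol = 3), 2, c(500, 0, 0), "+")
  sb <- segment_blobs(rbind(a, b), bandwidth = 100)
  expect_length(sb$blobs, 2)
  expect_equal(sort(vapply(sb$blobs, function(x) n_points(x$members),
                           integer(1))), c(100, 100))
  # memberships match generation
  expect_length(unique(sb$assignment[1:100]), 1)
  expect_length(unique(sb$assignment[101:200]), 1)
  expect_false(sb$assignment[1] == sb$assignment[101])
})

test_that("single and degenerate clusters form one blob", {
  set.seed(72)
  one <- matrix(rnorm(150, 0, 20), ncol = 3)
  sb <- segment_blobs(one, bandwidth = 100)
  expect_length(sb$blobs, 1)
  expect_equal(n_points(sb$blobs[[1]]$members), 50)
  # all points identical: one blob, mode at that point
  same <- matrix(7, 20, 3)
  sb2 <- segment_blobs(same, bandwidth = 50)
  expect_length(sb2$blobs, 1)
  expect_equal(unname(sb2$blobs[[1]]$mode), c(7, 7, 7))
  # empty input
  expect_length(segment_blobs(matrix(numeric(0), ncol = 3), 50)$blobs, 0)
})

test_that("under-size blobs go to the unassigned pool", {
  set.seed(73)
  big <- matrix(rnorm(240, 0, 25), ncol = 3)
  lone <- matrix(c(4000, 0, 0, 4010, 0, 0), 2, 3, byrow = TRUE)
  sb <- segment_blobs(rbind(big, lone), bandwidth = 100, min_size = 3)
  expect_length(sb$blobs, 1)
  expect_equal(sum(is.na(sb$assignment)), 2)
})

test_that("hull volume agrees with an independent geometry oracle", {
  # frozen oracle values: scipy.spatial.ConvexHull on the same seeded points
  set.seed(11); x <- matrix(round(runif(120, 0, 100), 4), ncol = 3)
  expect_equal(as.numeric(convex_hull_volume(x)), 352933.19457548374,
               tolerance = 1e-10)
  set.seed(99); y <- matrix(round(rnorm(150, 0, 50), 4), ncol = 3)
  expect_equal(as.numeric(convex_hull_volume(y)), 3406633.615823169,
               tolerance = 1e-10)
  # analytic cases
  cube <- as.matrix(expand.grid(0:1, 0:1, 0:1)) * 10
  expect_equal(as.numeric(convex_hull_volume(cube)), 1000)
  flat <- cbind(runif(10), runif(10), 0)
  expect_true(attr(convex_hull_volume(flat), "degenerate"))
  expect_equal(as.numeric(convex_hull_volume(flat)), 0)
  # 2D area: unit square
  sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1), 0) * 10
  expect_equal(xy_hull_area(sq), 100)
})

test_that("descriptors separate hollow shells from filled balls", {
  shell <- shell_points(500, 95, seed = 74)
  ds <- blob_descriptor(shell)
  expect_equal(unname(ds["mean_dist_centroid"]), 95, tolerance = 0.02)
  expect_gt(ds["min_dist_centroid"], 80)      # hollow signature
  ball <- ball_points(500, 80, seed = 75)
  db <- blob_descriptor(ball)
  expect_equal(unname(db["mean_dist_centroid"]), 0.75 * 80,
               tolerance = 0.05)
  expect_lt(db["min_dist_centroid"], 15)      # filled signature
  # the shell/ball margin dwarfs the sampling noise of min distance
  mins <- t(vapply(1:8, function(s) c(
    blob_descriptor(shell_points(500, 95, seed = s))["min_dist_centroid"],
    blob_descriptor(ball_points(500, 95, seed = s))["min_dist_centroid"]),
    numeric(2)))
  margin <- mean(mins[, 1]) - mean(mins[, 2])
  expect_gt(margin, 3 * max(sd(mins[, 1]), sd(mins[, 2])))
})

test_that("shape terms follow the covariance eigenstructure", {
  line <- cbind(seq(0, 200, length.out = 50), 0, 0)
  dl <- blob_descriptor(line)
  expect_equal(unname(dl["linearity"]), 1, tolerance = 1e-9)
  expect_equal(unname(dl["planarity"]), 0, tolerance = 1e-9)
  expect_equal(unname(dl["sphericity"]), 0, tolerance = 1e-9)
  expect_equal(unname(dl["y_range"]), 0)
  expect_equal(unname(dl["z_range"]), 0)
  set.seed(76)
  iso <- matrix(rnorm(3000, 0, 50), ncol = 3)
  di <- blob_descriptor(iso)
  expect_lt(di["fractional_anisotropy"], 0.1)
  expect_gt(di["sphericity"], 0.8)
})

test_that("descriptors are rigid-motion aware exactly as documented", {
  set.seed(77)
  pts <- matrix(rnorm(360, 0, 40), ncol = 3)
  d0 <- blob_descriptor(pts)
  # translation: everything unchanged
  d1 <- blob_descriptor(sweep(pts, 2, c(1000, -500, 200), "+"))
  expect_equal(unclass(d1), unclass(d0), tolerance = 1e-8)
  # rotation: only the axis-aligned ranges may change
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  d2 <- blob_descriptor(pts %*% t(R))
  keep <- setdiff(names(d0), c("x_range", "y_range", "z_range"))
  expect_equal(unclass(d2[keep]), unclass(d0[keep]), tolerance = 1e-6)
})

test_that("descriptor count and degenerate handling match the registry", {
  expect_length(blob_descriptor_names(), 28)
  d <- blob_descriptor(matrix(c(0, 0, 0, 10, 0, 0), 2, 3, byrow = TRUE))
  expect_length(d, 28)
  expect_true(attr(d, "partial"))
  expect_equal(unname(d["volume"]), 0)
  expect_equal(unname(d["n_nodes"]), 2)
})

test_that("multi-threshold modularity tracks component structure", {
  set.seed(78)
  # two sub-clusters whose closest inter-point distance is ~120 nm
  a <- ball_points(40, 40, c(0, 0, 0), seed = 1)
  b <- ball_points(40, 40, c(200, 0, 0), seed = 2)
  pts <- rbind(a, b)
  mt <- multi_threshold_modularity(pts, grid = seq(20, 250, 10))
  expect_true(all(diff(mt$n_components) <= 0))     # non-increasing in T
  expect_equal(mt$n_components[mt$threshold == 250], 1)
  # bridge distance: components drop to 1 exactly past the actual gap
  dmin <- min(sqrt(smlmnet:::cross_dist2(a, b)))
  expect_true(all(mt$n_components[mt$threshold >= dmin] == 1))
  expect_true(all(mt$n_components[mt$threshold < min(dmin, 100)] >= 2))
})
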