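test_that("X-means recovers the planted number of groups", {
  pd2 <- planted_descriptors(40, k = 2, seed = 81)
  fit2 <- xmeans(pd2$X, k_max = 10, seed = 1)
  expect_equal(fit2$K, 2)
  expect_gt(adjusted_rand_index(fit2$assignment, pd2$labels), 0.95)
  pd4 <- planted_descriptors(40, k = 4, seed = 82)
  fit4 <- xmeans(pd4$X, k_max = 10, seed = 1)
  expect_equal(fit4$K, 4)
  expect_gt(adjusted_rand_index(fit4$assignment, pd4$labels), 0.95)
  # identical descriptors: no split improves BIC
  same <- matrix(1, 30, 28)
  expect_equal(xmeans(same, k_max = 10, seed = 1)$K, 1)
})

test_that("group discovery scales features and orders groups by size", {
  pd <- planted_descriptors(30, k = 2, seed = 83)
  X <- rbind(pd$X, pd$X[pd$labels == 1, ][1:10, ])   # make group 1 larger
  model <- discover_groups(X, seed = 2, population_tag = "popA")
  expect_s3_class(model, "group_model")
  expect_equal(model$K, 2)
  expect_true(all(diff(model$sizes) <= 0))
  expect_equal(dim(model$centroids), c(2, 28))
  # stored scaling reproduces the assignment on the training data
  lab <- assign_blobs(model, X)
  expect_equal(lab$group, model$assignment)
})

test_that("group matching applies the beta rule on centroid distances", {
  pd <- planted_descriptors(30, k = 2, seed = 84)
  model <- discover_groups(pd$X, seed = 1)
  # identical models: zero distance, everything matched
  m <- match_groups(model, model, beta = 30)
  expect_true(all(m$pairs$matched))
  expect_lt(max(m$pairs$distance), 1e-5)   # 0 up to float cancellation
  expect_equal(m$pairs$group_b, seq_len(model$K))
  expect_equal(m$pairs$similarity, rep(1, model$K), tolerance = 1e-5)

  # constructed centroid geometry: distances 5, 12, 40 against beta = 30
  base <- matrix(0, 3, 28)
  base[2, 1] <- 12; base[3, 1] <- 40
  ma <- structure(list(centroids = matrix(c(5, rep(0, 27)), 1, 28,
                                          byrow = TRUE),
                       centroids_scaled = matrix(0, 1, 28),
                       scaling = list(center = rep(0, 28),
                                      scale = rep(1, 28),
                                      impute = rep(0, 28)),
                       sizes = 1, K = 1,
                       registry_version = "blob-registry-1",
                       population_tag = "a"), class = "group_model")
  mb <- ma; mb$centroids <- base; mb$K <- 3; mb$sizes <- c(1, 1, 1)
  mb$centroids_scaled <- matrix(0, 3, 28)
  mm <- match_groups(ma, mb, beta = 30)
  expect_equal(as.vector(mm$distance_matrix), c(5, 7, 35))
  expect_true(mm$pairs$matched[1])
  expect_equal(mm$pairs$group_b[1], 1)    # nearest within beta

  # an outlier group beyond beta from everything stays unmatched
  mo <- ma; mo$centroids <- matrix(c(500, rep(0, 27)), 1, 28, byrow = TRUE)
  expect_false(match_groups(mo, mb, beta = 30)$pairs$matched[1])

  # monotone beta: matched set only grows
  n1 <- sum(match_groups(mb, mo, beta = 10)$pairs$matched)
  n2 <- sum(match_groups(mb, mo, beta = 1000)$pairs$matched)
  expect_lte(n1, n2)

  # registry guard
  bad <- ma; bad$registry_version <- "other"
  expect_error(match_groups(ma, bad), "registry")
})

test_that("matching is robust to dropping the molecule-count feature", {
  pd <- planted_descriptors(40, k = 3, seed = 85)
  mA <- discover_groups(pd$X, seed = 1)
  mB <- discover_groups(pd$X + matrix(rnorm(nrow(pd$X) * 28, 0, 0.05),
                                      nrow(pd$X)), seed = 2)
  full <- match_groups(mA, mB, beta = 30)
  no_n <- match_groups(mA, mB, beta = 30, exclude_features = "n_nodes")
  expect_equal(no_n$pairs$group_b, full$pairs$group_b)
})

test_that("test-phase assignment is nearest-centroid with tie flagging", {
  pd <- planted_descriptors(40, k = 2, seed = 86)
  model <- discover_groups(pd$X, seed = 1)
  # a descriptor equal to a centroid lands in that group at distance 0
  lab <- assign_blobs(model, model$centroids)
  expect_equal(lab$group, seq_len(model$K))
  expect_lt(max(lab$distance), 1e-5)       # 0 up to float cancellation
  # held-out blobs from the planted groups are recovered
  held <- planted_descriptors(40, k = 2, seed = 86)  # same plant, same seed
  lab2 <- assign_blobs(model, held$X)
  expect_gt(adjusted_rand_index(lab2$group, held$labels), 0.95)
  # equidistant tie (exact scaled-space midpoint) goes to the lowest group
  # index and is flagged
  msc <- (model$centroids_scaled[1, ] + model$centroids_scaled[2, ]) / 2
  raw_mid <- msc * model$scaling$scale + model$scaling$center
  lab3 <- assign_blobs(model, matrix(raw_mid, 1))
  expect_equal(lab3$group, 1)
  expect_true(lab3$tie)
})

test_that("group models serialize losslessly to JSON", {
  pd <- planted_descriptors(25, k = 2, seed = 87)
  model <- discover_groups(pd$X, seed = 1)
  f <- withr::local_tempfile(fileext = ".json")
  write_group_model(model, f)
  back <- read_group_model(f)
  expect_equal(back$centroids, model$centroids, tolerance = 1e-12)
  expect_equal(back$K, model$K)
  lab_a <- assign_blobs(model, pd$X)
  lab_b <- assign_blobs(back, pd$X)
  expect_equal(lab_a$group, lab_b$group)
})
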