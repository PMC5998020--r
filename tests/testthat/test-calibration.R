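test_that("the gate is the conjunction of the blink and area clauses", {
  mk_blob <- function(pts, id) structure(
    list(members = localization_set(pts), member_idx = seq_len(nrow(pts)),
         mode = colMeans(pts), blob_id = id), class = "blob")
  tight <- cbind(runif(5, 0, 5), runif(5, 0, 5), 0)      # area < 100, 5 blinks
  wide5 <- cbind(c(0, 30, 0, 30, 15), c(0, 0, 30, 30, 15), 0)  # area 900
  tight20 <- cbind(runif(20, 0, 5), runif(20, 0, 5), 0)  # small but many
  bs <- structure(list(blobs = list(mk_blob(tight, 1L), mk_blob(wide5, 2L),
                                    mk_blob(tight20, 3L)),
                       assignment = c(rep(1L, 5), rep(2L, 5), rep(3L, 20)),
                       modes = matrix(0, 3, 3), bandwidth = 100),
                  class = "blob_set")
  out <- gate_blobs(bs, min_blinks = 6, max_area = 100)
  kept <- vapply(out$blobs, function(b) b$blob_id, integer(1))
  expect_equal(kept, c(2L, 3L))       # only the doubly-failing blob goes
  expect_equal(attr(out, "removed"), 1L)
})

test_that("K-means split recovers planted single vs cluster blobs", {
  set.seed(91)
  singles <- lapply(1:30, function(i)
    sweep(cbind(rnorm(12, 0, 20), rnorm(12, 0, 20), rnorm(12, 0, 38)),
          2, c(i * 2000, 0, 0), "+"))
  clusters <- lapply(1:30, function(i) {
    ctr <- c(i * 2000, 8000, 0)
    do.call(rbind, lapply(1:3, function(a)
      sweep(cbind(rnorm(12, 0, 20), rnorm(12, 0, 20), rnorm(12, 0, 38)),
            2, ctr + runif(3, -100, 100), "+")))
  })
  ev <- event_list(do.call(rbind, c(singles, clusters)))
  sb <- segment_blobs(ev, bandwidth = 250, min_size = 3)
  sp <- split_single_vs_cluster(sb, seed = 1)
  truth <- ifelse(vapply(sb$blobs, function(b) b$members$points[1, 2] < 4000,
                         logical(1)), "single", "cluster")
  expect_gt(adjusted_rand_index(sp$class, truth), 0.9)
  # the single class reports the smaller spreads
  expect_lt(sp$class_spread["single", "z"], sp$class_spread["cluster", "z"])
})

test_that("identical blobs make the split degenerate", {
  pts <- cbind(c(0, 10, 0, 10), c(0, 0, 10, 10), c(0, 0, 0, 5))
  mk <- function(off, id) structure(
    list(members = localization_set(sweep(pts, 2, c(off, 0, 0), "+")),
         member_idx = 1:4, mode = c(off, 0, 0), blob_id = id),
    class = "blob")
  bs <- structure(list(blobs = lapply(1:4, function(i) mk(i * 1000, i)),
                       assignment = rep(1:4, each = 4),
                       modes = matrix(0, 4, 3), bandwidth = 100),
                  class = "blob_set")
  sp <- split_single_vs_cluster(bs, seed = 1)
  expect_true(sp$degenerate)
  expect_equal(unique(sp$class), "single")
})

test_that("calibration on simulated rods recovers the set precision", {
  ev <- simulate_rod_field(150, seed = 200)
  rep <- calibrate_antibody(ev, seed = 1)
  expect_s3_class(rep, "calibration_report")
  expect_gt(rep$n_blobs_gated, 50)
  # every blob here is a single antibody: pooled over all gated blobs the
  # bias-corrected spread estimates the simulation input precision
  all_sp <- colMeans(rep$blobs[, c("sd_x", "sd_y", "sd_z")])
  expect_equal(unname(all_sp["sd_x"]), 20, tolerance = 0.08)
  expect_equal(unname(all_sp["sd_y"]), 20, tolerance = 0.08)
  expect_equal(unname(all_sp["sd_z"]), 38, tolerance = 0.08)
})

test_that("the blink/area gate is stable to +/- 20% parameter changes", {
  ev <- simulate_rod_field(150, seed = 300)
  sb <- segment_blobs(ev, bandwidth = 100, min_size = 3)
  base <- sort(vapply(gate_blobs(sb, 6, 100)$blobs,
                      function(b) b$blob_id, integer(1)))
  for (mb in c(5, 6, 7)) for (ar in c(80, 100, 120)) {
    got <- sort(vapply(gate_blobs(sb, mb, ar)$blobs,
                       function(b) b$blob_id, integer(1)))
    change <- (length(setdiff(base, got)) + length(setdiff(got, base))) /
      length(base)
    expect_lt(change, 0.05)
  }
})
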