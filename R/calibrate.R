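#' Gate calibration blobs on blink count and area
#'
#' Single-antibody calibration data contain tiny spurious clusters; blobs
#' with *both* fewer than `min_blinks` blinks *and* XY convex-hull area at or
#' below `max_area` are removed (the gate is the conjunction — a blob
#' failing only one clause is retained).
#'
#' @param blob_set a [segment_blobs()] result (built on raw blinks).
#' @param min_blinks blink-count clause (default 6).
#' @param max_area area clause in nm^2 (default 100).
#' @return a `blob_set` containing only the retained blobs (attribute
#'   `removed`: ids of gated-out blobs).
#' @export
gate_blobs <- function(blob_set, min_blinks = 6, max_area = 100) {
  blobs <- blob_set$blobs
  keep <- vapply(blobs, function(b) {
    nb <- sum(b$members$merged_from)
    area <- xy_hull_area(b$members$points)
    !(nb < min_blinks && area <= max_area)
  }, logical(1))
  out <- blob_set
  out$blobs <- blobs[keep]
  removed <- vapply(blobs[!keep], function(b) b$blob_id, integer(1))
  out$assignment[out$assignment %in% removed] <- NA_integer_
  attr(out, "removed") <- removed
  out
}

# Unbiasing factor for the sample SD of a normal sample: E[S] = c4(n) sigma.
c4_factor <- function(n) {
  ifelse(n > 1, sqrt(2 / (n - 1)) * exp(lgamma(n / 2) - lgamma((n - 1) / 2)),
         NA_real_)
}

#' Per-axis blink spread of a blob
#'
#' Sample SD of the blob's blink coordinates per axis. Calibration blobs can
#' hold only a handful of blinks, where the raw sample SD underestimates the
#' true spread (`E[S] = c4(n) sigma`); by default the classic `c4` correction
#' is applied so the estimate is unbiased for Gaussian spread.
#'
#' @param b a `blob`.
#' @param correct_bias apply the small-sample `c4` correction (default
#'   `TRUE`).
#' @return length-3 numeric (x, y, z SD in nm).
#' @export
blob_spread_sd <- function(b, correct_bias = TRUE) {
  s <- apply(b$members$points, 2, stats::sd)
  if (correct_bias) s <- s / c4_factor(nrow(b$members$points))
  s
}

#' Split calibration blobs into single- vs multi-antibody classes
#'
#' K-means with K = 2 on the blobs' 28-feature descriptors (standardized);
#' the class with the smaller mean spatial size (mean XY hull area) is
#' labeled `"single"`, the other `"cluster"`. Reports the mean per-axis SD
#' of raw blink coordinates per class (small-sample bias corrected, see
#' [blob_spread_sd()]) — for singles this estimates the localization
#' precision of the acquisition.
#'
#' The split is only meaningful on data that actually contain both classes;
#' on a homogeneous population K-means returns an arbitrary bisection (the
#' limitation is discussed in the vignette). Literally indistinguishable
#' descriptors are flagged degenerate and labeled as one class.
#'
#' @param blob_set a (gated) `blob_set` built on raw blinks.
#' @param seed integer seed.
#' @return list of class `calibration_split`: `class` (per blob), `spread`
#'   (per-blob per-axis SDs), `class_spread` (mean per-axis SD per class),
#'   `degenerate` (logical: all blobs indistinguishable).
#' @export
split_single_vs_cluster <- function(blob_set, seed = 1) {
  blobs <- blob_set$blobs
  if (length(blobs) < 2)
    stop("split_single_vs_cluster: need at least 2 blobs")
  desc <- blob_table(blob_set)
  X <- descriptor_matrix(desc)
  scaling <- fit_scaling(X)
  Xs <- apply_scaling(X, scaling)
  degenerate <- nrow(unique(Xs)) < 2
  if (degenerate) {
    cls <- rep("single", length(blobs))
  } else {
    old <- get_rng_state(); on.exit(restore_rng_state(old))
    set.seed(as.integer(seed))
    fit <- suppressWarnings(stats::kmeans(Xs, centers = 2, nstart = 10,
                                          iter.max = 100))
    areas <- vapply(blobs, function(b) xy_hull_area(b$members$points),
                    numeric(1))
    mean_area <- tapply(areas, fit$cluster, mean)
    single_id <- as.integer(names(which.min(mean_area)))
    cls <- ifelse(fit$cluster == single_id, "single", "cluster")
  }
  spread <- t(vapply(blobs, blob_spread_sd, numeric(3)))
  colnames(spread) <- c("x", "y", "z")
  class_spread <- do.call(rbind, lapply(split(seq_along(blobs), cls),
                                        function(idx)
                                          colMeans(spread[idx, , drop = FALSE])))
  structure(list(class = cls, spread = spread, class_spread = class_spread,
                 degenerate = degenerate), class = "calibration_split")
}

#' Single-antibody calibration analysis
#'
#' The full calibration chain on a raw event list: mean-shift segmentation
#' of the raw blinks, blink/area gating, K-means single-vs-cluster split,
#' and per-class spread statistics. SD of the blink spread is deliberately
#' computed on *raw* (pre-merge) blinks — merging at the resolution limit
#' would collapse exactly the spread being measured.
#'
#' @param events an [event_list()] of raw blinks.
#' @param bandwidth mean-shift bandwidth (nm, default 100; comfortably above
#'   the axial precision so one antibody's blinks form one blob).
#' @param min_blinks,max_area gate parameters (see [gate_blobs()]).
#' @param min_size minimum blob size for segmentation (default 3; an SD
#'   needs at least a few blinks).
#' @param seed integer seed.
#' @return list of class `calibration_report`: `blobs` (per-blob `n_blinks`,
#'   `area`, per-axis SDs, class), `class_spread`, `gate`, `n_blobs_total`,
#'   `n_blobs_gated`.
#' @export
calibrate_antibody <- function(events, bandwidth = 100, min_blinks = 6,
                               max_area = 100, min_size = 3, seed = 1) {
  sb <- segment_blobs(events, bandwidth = bandwidth, min_size = min_size)
  n_total <- length(sb$blobs)
  gated <- gate_blobs(sb, min_blinks = min_blinks, max_area = max_area)
  split <- split_single_vs_cluster(gated, seed = seed)
  per_blob <- data.frame(
    blob_id = vapply(gated$blobs, function(b) b$blob_id, integer(1)),
    n_blinks = vapply(gated$blobs, function(b) sum(b$members$merged_from),
                      integer(1)),
    area = vapply(gated$blobs, function(b) xy_hull_area(b$members$points),
                  numeric(1)),
    sd_x = split$spread[, "x"], sd_y = split$spread[, "y"],
    sd_z = split$spread[, "z"],
    class = split$class)
  structure(list(blobs = per_blob, class_spread = split$class_spread,
                 gate = c(min_blinks = min_blinks, max_area = max_area),
                 n_blobs_total = n_total, n_blobs_gated = length(gated$blobs),
                 degenerate = split$degenerate),
            class = "calibration_report")
}

#' @export
print.calibration_report <- function(x, ...) {
  cat(sprintf("<calibration_report> %d blobs (%d after gate)\n",
              x$n_blobs_total, x$n_blobs_gated))
  print(round(x$class_spread, 2))
  invisible(x)
}
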