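# Flat-kernel mean shift in 3D.
#
# Every point is a seed; each seed is iteratively moved to the mean of the
# data points within `bandwidth` of it until it stops moving (a mode of the
# flat-kernel density estimate). Converged modes are de-duplicated in order
# of basin population — a mode within `bandwidth` of an already accepted,
# more populated mode is suppressed — and every point is assigned to the
# accepted mode nearest to its own converged position. The procedure is
# seed-free and deterministic.

mean_shift_modes <- function(pts, bandwidth, tol = 1e-3, max_iter = 300) {
  n <- nrow(pts)
  pos <- pts
  active <- rep(TRUE, n)
  for (it in seq_len(max_iter)) {
    idx <- which(active)
    if (!length(idx)) break
    cr <- radius_cross(pos[idx, , drop = FALSE], pts, bandwidth)
    # every active seed is within bandwidth of at least its origin point,
    # except seeds that started on isolated points and have not moved
    newpos <- pos[idx, , drop = FALSE]
    if (nrow(cr)) {
      sums <- rowsum(pts[cr$j, , drop = FALSE], cr$i)
      cnt <- as.vector(rowsum(rep(1, nrow(cr)), cr$i))
      rows <- as.integer(rownames(sums))
      newpos[rows, ] <- sums / cnt
    }
    shift <- sqrt(rowSums((newpos - pos[idx, , drop = FALSE])^2))
    pos[idx, ] <- newpos
    active[idx] <- shift > tol
  }
  pos
}

#' Segment localizations into blobs by mean shift
#'
#' Mode-seeking segmentation of a 3D localization set with a flat (uniform)
#' kernel of the given bandwidth. Points converging to the same density mode
#' form one blob; blobs smaller than `min_size` are moved to an unassigned
#' pool (`blob_id = NA`).
#'
#' @param points a [localization_set()], [event_list()] or n x 3 matrix (nm).
#' @param bandwidth kernel radius in nm (default 80, the blob-analysis
#'   threshold; not a value stated by the acquisition, see the vignette).
#' @param min_size minimum number of members for a blob (default 3).
#' @param tol,max_iter convergence controls for the mode iteration.
#' @return list of class `blob_set`: `blobs` (list of `blob` objects with
#'   `members` localization set, `member_idx`, `mode`, `blob_id`),
#'   `assignment` (integer blob id per input point, `NA` = unassigned pool),
#'   `modes` (matrix of accepted mode positions), `bandwidth`.
#' @examples
#' pts <- rbind(matrix(rnorm(60, 0, 20), ncol = 3),
#'              matrix(rnorm(60, 1000, 20), ncol = 3))
#' sb <- segment_blobs(pts, bandwidth = 100)
#' length(sb$blobs)  # 2
#' @export
segment_blobs <- function(points, bandwidth = 80, min_size = 3,
                          tol = 1e-3, max_iter = 300) {
  stopifnot(bandwidth > 0)
  pts <- as_points(points)
  mf <- if (inherits(points, "localization_set")) points$merged_from
        else rep(1L, nrow(pts))
  n <- nrow(pts)
  if (n == 0)
    return(structure(list(blobs = list(), assignment = integer(0),
                          modes = matrix(numeric(0), ncol = 3),
                          bandwidth = bandwidth), class = "blob_set"))
  conv <- mean_shift_modes(pts, bandwidth, tol = tol, max_iter = max_iter)
  # group converged positions that are numerically identical
  key <- apply(round(conv / max(tol, 1e-6)), 1, paste, collapse = ",")
  groups <- split(seq_len(n), key)
  cand_modes <- t(vapply(groups, function(idx)
    colMeans(conv[idx, , drop = FALSE]), numeric(3)))
  basin_n <- lengths(groups)
  ord <- order(-basin_n, vapply(groups, min, integer(1)))
  accepted <- integer(0)
  for (gi in ord) {
    m <- cand_modes[gi, ]
    if (length(accepted)) {
      d2 <- colSums((t(cand_modes[accepted, , drop = FALSE]) - m)^2)
      if (any(d2 <= bandwidth^2)) next
    }
    accepted <- c(accepted, gi)
  }
  modes <- cand_modes[accepted, , drop = FALSE]
  # assign each point to the accepted mode nearest its converged position
  d2all <- cross_dist2(conv, modes)
  lab <- max.col(-d2all, ties.method = "first")
  # renumber blobs by decreasing size, then build member lists
  keep_sizes <- tabulate(lab, nrow(modes))
  order_blobs <- order(-keep_sizes)
  rank_of <- integer(nrow(modes)); rank_of[order_blobs] <- seq_len(nrow(modes))
  lab <- rank_of[lab]
  modes <- modes[order_blobs, , drop = FALSE]
  sizes <- tabulate(lab, nrow(modes))
  valid <- which(sizes >= min_size)
  assignment <- rep(NA_integer_, n)
  blobs <- vector("list", length(valid))
  for (bi in seq_along(valid)) {
    members <- which(lab == valid[bi])
    assignment[members] <- bi
    blobs[[bi]] <- structure(list(
      members = localization_set(pts[members, , drop = FALSE], mf[members]),
      member_idx = members,
      mode = modes[valid[bi], ],
      blob_id = bi), class = "blob")
  }
  structure(list(blobs = blobs, assignment = assignment,
                 modes = modes[valid, , drop = FALSE],
                 bandwidth = bandwidth), class = "blob_set")
}

#' @export
print.blob_set <- function(x, ...) {
  cat(sprintf("<blob_set> %d blobs (bandwidth %g nm), %d unassigned points\n",
              length(x$blobs), x$bandwidth, sum(is.na(x$assignment))))
  invisible(x)
}
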