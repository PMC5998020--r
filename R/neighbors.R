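# Fixed-radius neighbor search on a uniform grid (cell lists).
#
# All pipeline stages ask one of two questions about 3D points: "which pairs
# lie within r of each other" and "which points of B lie within r of each
# point of A". A uniform grid with cell edge r answers both in near-linear
# time at SMLM densities, playing the role a k-d tree plays elsewhere.

cross_dist2 <- function(P, Q) {
  # squared Euclidean cross-distances, |P| x |Q|
  d2 <- outer(rowSums(P^2), rowSums(Q^2), "+") - 2 * tcrossprod(P, Q)
  d2[d2 < 0] <- 0
  d2
}

cell_ids <- function(pts, r, origin) {
  cc <- floor(sweep(pts, 2, origin) / r)
  storage.mode(cc) <- "integer"
  cc
}

key_of <- function(cc) paste(cc[, 1], cc[, 2], cc[, 3], sep = ",")

#' All point pairs within a distance
#'
#' Returns every unordered pair `(i, j)`, `i < j`, of rows of `pts` whose
#' Euclidean distance is at most `r`, together with the distance.
#'
#' @param pts n x 3 numeric matrix (nm), or anything [event_list()]-like.
#' @param r radius (nm), > 0.
#' @return data.frame with integer columns `i`, `j` and numeric `d`.
#' @export
radius_pairs <- function(pts, r) {
  pts <- as_points(pts)
  stopifnot(r > 0)
  n <- nrow(pts)
  empty <- data.frame(i = integer(0), j = integer(0), d = numeric(0))
  if (n < 2) return(empty)
  origin <- apply(pts, 2, min)
  cc <- cell_ids(pts, r, origin)
  keys <- key_of(cc)
  groups <- split(seq_len(n), keys)
  first <- vapply(groups, `[`, integer(1), 1L)
  gcell <- cc[first, , drop = FALSE]
  # half-space of the 26 neighbor offsets, so each cell pair is visited once
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[offs[, 3] > 0 | (offs[, 3] == 0 & offs[, 2] > 0) |
                 (offs[, 3] == 0 & offs[, 2] == 0 & offs[, 1] > 0), ,
               drop = FALSE]
  out_i <- vector("list", length(groups) * 2); out_j <- out_i; out_d <- out_i
  slot <- 0L
  r2 <- r * r
  for (g in seq_along(groups)) {
    A <- groups[[g]]
    if (length(A) > 1) {      # within-cell pairs
      d2 <- cross_dist2(pts[A, , drop = FALSE], pts[A, , drop = FALSE])
      sel <- which(upper.tri(d2) & d2 <= r2, arr.ind = TRUE)
      if (nrow(sel)) {
        slot <- slot + 1L
        out_i[[slot]] <- A[sel[, 1]]; out_j[[slot]] <- A[sel[, 2]]
        out_d[[slot]] <- sqrt(d2[sel])
      }
    }
    nb_keys <- paste(gcell[g, 1] + offs[, 1], gcell[g, 2] + offs[, 2],
                     gcell[g, 3] + offs[, 3], sep = ",")
    hit <- nb_keys[nb_keys %in% names(groups)]
    for (k in hit) {
      B <- groups[[k]]
      d2 <- cross_dist2(pts[A, , drop = FALSE], pts[B, , drop = FALSE])
      sel <- which(d2 <= r2, arr.ind = TRUE)
      if (nrow(sel)) {
        slot <- slot + 1L
        ii <- A[sel[, 1]]; jj <- B[sel[, 2]]
        sw <- ii > jj
        out_i[[slot]] <- ifelse(sw, jj, ii); out_j[[slot]] <- ifelse(sw, ii, jj)
        out_d[[slot]] <- sqrt(d2[sel])
      }
    }
  }
  if (slot == 0L) return(empty)
  data.frame(i = unlist(out_i[seq_len(slot)]),
             j = unlist(out_j[seq_len(slot)]),
             d = unlist(out_d[seq_len(slot)]))
}

#' Per-point neighbor counts within a radius
#'
#' `counts[i]` is the number of *other* points at distance `<= r` from point
#' `i` (the point itself is excluded).
#'
#' @inheritParams radius_pairs
#' @return integer vector of length `nrow(pts)`.
#' @export
radius_counts <- function(pts, r) {
  pts <- as_points(pts)
  pr <- radius_pairs(pts, r)
  counts <- integer(nrow(pts))
  if (nrow(pr)) {
    t1 <- tabulate(pr$i, nbins = nrow(pts))
    t2 <- tabulate(pr$j, nbins = nrow(pts))
    counts <- t1 + t2
  }
  counts
}

# For each row of A, the rows of B within r: data.frame(i = A-row, j = B-row, d).
radius_cross <- function(A, B, r) {
  A <- as_points(A); B <- as_points(B)
  empty <- data.frame(i = integer(0), j = integer(0), d = numeric(0))
  if (nrow(A) == 0 || nrow(B) == 0) return(empty)
  origin <- apply(B, 2, min)
  ccB <- cell_ids(B, r, origin)
  groupsB <- split(seq_len(nrow(B)), key_of(ccB))
  ccA <- cell_ids(A, r, origin)
  groupsA <- split(seq_len(nrow(A)), key_of(ccA))
  firstA <- vapply(groupsA, `[`, integer(1), 1L)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  out <- vector("list", length(groupsA)); slot <- 0L
  r2 <- r * r
  for (g in seq_along(groupsA)) {
    Aidx <- groupsA[[g]]
    base <- ccA[firstA[g], ]
    nb_keys <- paste(base[1] + offs[, 1], base[2] + offs[, 2],
                     base[3] + offs[, 3], sep = ",")
    Bidx <- unlist(groupsB[nb_keys[nb_keys %in% names(groupsB)]],
                   use.names = FALSE)
    if (!length(Bidx)) next
    d2 <- cross_dist2(A[Aidx, , drop = FALSE], B[Bidx, , drop = FALSE])
    sel <- which(d2 <= r2, arr.ind = TRUE)
    if (nrow(sel)) {
      slot <- slot + 1L
      out[[slot]] <- data.frame(i = Aidx[sel[, 1]], j = Bidx[sel[, 2]],
                                d = sqrt(d2[sel]))
    }
  }
  if (slot == 0L) return(empty)
  do.call(rbind, out[seq_len(slot)])
}

#' Minimum pairwise distance of a point set
#'
#' @inheritParams radius_pairs
#' @return the smallest Euclidean distance between any two points; `Inf` for
#'   fewer than 2 points.
#' @export
min_pairwise_distance <- function(pts) {
  pts <- as_points(pts)
  n <- nrow(pts)
  if (n < 2) return(Inf)
  if (n <= 1500) return(min(stats::dist(pts)))
  ext <- apply(pts, 2, function(v) diff(range(v)))
  r <- max(1e-9, (prod(pmax(ext, 1)) / n)^(1 / 3))
  repeat {
    pr <- radius_pairs(pts, r)
    if (nrow(pr)) return(min(pr$d))
    r <- r * 2
  }
}

# Mutable grid supporting insert / remove / range query, used by the merge.
point_grid <- function(capacity, cell) {
  pts <- matrix(NA_real_, nrow = capacity, ncol = 3)
  tab <- new.env(hash = TRUE, parent = emptyenv())
  keyfun <- function(p) paste(floor(p / cell), collapse = ",")
  insert <- function(i, p) {
    pts[i, ] <<- p
    k <- keyfun(p)
    tab[[k]] <- c(tab[[k]], i)
    invisible(NULL)
  }
  remove <- function(i) {
    k <- keyfun(pts[i, ])
    v <- tab[[k]]
    tab[[k]] <- v[v != i]
    invisible(NULL)
  }
  query <- function(center, r, exclude = 0L) {
    lo <- floor((center - r) / cell); hi <- floor((center + r) / cell)
    cand <- integer(0)
    for (cx in lo[1]:hi[1]) for (cy in lo[2]:hi[2]) for (cz in lo[3]:hi[3]) {
      v <- tab[[paste(cx, cy, cz, sep = ",")]]
      if (!is.null(v)) cand <- c(cand, v)
    }
    cand <- cand[cand != exclude]
    if (!length(cand)) return(cand)
    d2 <- colSums((t(pts[cand, , drop = FALSE]) - center)^2)
    cand[d2 <= r * r]
  }
  list(insert = insert, remove = remove, query = query,
       coords = function(i) pts[i, , drop = FALSE])
}
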