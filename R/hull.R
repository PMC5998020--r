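# Convex hull geometry.
#
# Blob descriptors need the volume of the 3D convex hull and the area of the
# XY-projected 2D hull. No hull package ships with the target environment,
# so the 3D hull is computed with a straightforward incremental
# (beneath-beyond) algorithm; point counts per blob are small, so the O(n^2)
# worst case is irrelevant.

#' Volume of the 3D convex hull of a point set
#'
#' Degenerate inputs (fewer than 4 points, or coplanar/collinear points) have
#' zero volume; the result then carries attribute `degenerate = TRUE`.
#'
#' @param points n x 3 matrix (nm) or point-like object.
#' @return hull volume in nm^3 (attribute `degenerate` flags rank-deficient
#'   input).
#' @export
convex_hull_volume <- function(points) {
  pts <- as_points(points)
  n <- nrow(pts)
  degenerate <- function() structure(0, degenerate = TRUE)
  if (n < 4) return(degenerate())
  scale <- max(apply(pts, 2, function(v) diff(range(v))), 1e-12)
  eps <- 1e-9 * scale

  # initial simplex: two extreme points, the point farthest from their line,
  # then the point farthest from that plane
  i1 <- which.min(pts[, 1]); i2 <- which.max(pts[, 1])
  if (i1 == i2) {
    i1 <- which.min(pts[, 2]); i2 <- which.max(pts[, 2])
  }
  if (sqrt(sum((pts[i1, ] - pts[i2, ])^2)) < eps) return(degenerate())
  ab <- pts[i2, ] - pts[i1, ]
  rel <- sweep(pts, 2, pts[i1, ])
  crossp <- cbind(rel[, 2] * ab[3] - rel[, 3] * ab[2],
                  rel[, 3] * ab[1] - rel[, 1] * ab[3],
                  rel[, 1] * ab[2] - rel[, 2] * ab[1])
  dline <- sqrt(rowSums(crossp^2))
  i3 <- which.max(dline)
  if (dline[i3] < eps * sqrt(sum(ab^2))) return(degenerate())
  nrm <- crossp[i3, ] / sqrt(sum(crossp[i3, ]^2)) # later recomputed per facet
  dplane <- abs(rel %*% (vcross(ab, pts[i3, ] - pts[i1, ]) /
                           sqrt(sum(vcross(ab, pts[i3, ] - pts[i1, ])^2))))
  i4 <- which.max(dplane)
  if (dplane[i4] < eps) return(degenerate())

  interior <- colMeans(pts[c(i1, i2, i3, i4), ])
  facets <- list(c(i1, i2, i3), c(i1, i2, i4), c(i1, i3, i4), c(i2, i3, i4))
  facets <- lapply(facets, orient_facet, pts = pts, interior = interior)

  rest <- setdiff(seq_len(n), c(i1, i2, i3, i4))
  for (p in rest) {
    vis <- vapply(facets, function(f)
      facet_dist(f, pts, pts[p, ]) > eps, logical(1))
    if (!any(vis)) next
    # horizon: edges of visible facets shared with an invisible facet
    edge_key <- function(a, b) paste(min(a, b), max(a, b))
    counts <- new.env(parent = emptyenv())
    for (f in facets[vis]) {
      for (ei in 1:3) {
        a <- f[ei]; b <- f[ei %% 3 + 1]
        k <- edge_key(a, b)
        counts[[k]] <- if (is.null(counts[[k]])) list(n = 1L, e = c(a, b))
                       else list(n = counts[[k]]$n + 1L, e = c(a, b))
      }
    }
    horizon <- Filter(function(x) x$n == 1L,
                      mget(ls(counts), envir = counts))
    facets <- facets[!vis]
    for (h in horizon)
      facets[[length(facets) + 1]] <-
        orient_facet(c(h$e, p), pts, interior)
  }
  vol <- 0
  for (f in facets) {
    a <- pts[f[1], ] - interior; b <- pts[f[2], ] - interior
    c3 <- pts[f[3], ] - interior
    vol <- vol + abs(sum(a * vcross(b, c3))) / 6
  }
  structure(vol, degenerate = FALSE)
}

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

facet_normal <- function(f, pts) {
  vcross(pts[f[2], ] - pts[f[1], ], pts[f[3], ] - pts[f[1], ])
}

facet_dist <- function(f, pts, p) {
  nrm <- facet_normal(f, pts)
  nn <- sqrt(sum(nrm^2))
  if (nn == 0) return(0)
  sum((p - pts[f[1], ]) * nrm) / nn
}

orient_facet <- function(f, pts, interior) {
  if (facet_dist(f, pts, interior) > 0) f[c(1, 3, 2)] else f
}

#' Area of the 2D convex hull of the XY projection
#'
#' Used for blob area gating in the single-antibody calibration. Degenerate
#' (collinear) projections have zero area.
#'
#' @param points n x 3 matrix (nm) or point-like object (Z ignored), or an
#'   n x 2 matrix.
#' @return hull area in nm^2.
#' @export
xy_hull_area <- function(points) {
  if (is.matrix(points) && ncol(points) == 2) xy <- points
  else xy <- as_points(points)[, 1:2, drop = FALSE]
  if (nrow(xy) < 3) return(0)
  h <- grDevices::chull(xy)
  if (length(h) < 3) return(0)
  x <- xy[h, 1]; y <- xy[h, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}
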