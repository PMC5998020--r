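#' Tile a point cloud into fixed-size ROIs
#'
#' Whole-cell point clouds are too large to analyze as one graph, so the cell
#' extent is divided into equal axis-aligned boxes (regions of interest)
#' analyzed independently — the unit of parallelism. With the nominal
#' 18 x 18 x 1 um^3 image and 3 x 3 x 1 um^3 ROIs this yields 36 tiles.
#'
#' Intervals are half-open, closed at the lower edge, so each point falls in
#' exactly one ROI; the global maximum faces are closed so no point on the
#' outer boundary is lost. Empty ROIs are retained (flagged via their zero
#' point count).
#'
#' @param points a [localization_set()], [event_list()] or n x 3 matrix (nm).
#' @param roi_size numeric length-3 `(dx, dy, dz)` in nm
#'   (default `c(3000, 3000, 1000)`).
#' @param cell_extent 3 x 2 matrix of `(min, max)` per axis in nm, or `NULL`
#'   to use the tight bounding box of the data expanded outward to a multiple
#'   of `roi_size`. Must be an exact multiple of `roi_size` on every axis.
#' @param cell_id identifier copied onto every ROI.
#' @return list of `roi` objects; each has `points` (matrix), `merged_from`,
#'   `bounds` (3 x 2), `cell_id`, `roi_index` and logical `empty`.
#' @export
tile_rois <- function(points, roi_size = c(3000, 3000, 1000),
                      cell_extent = NULL, cell_id = "") {
  pts <- as_points(points)
  mf <- if (inherits(points, "localization_set")) points$merged_from
        else rep(1L, nrow(pts))
  stopifnot(length(roi_size) == 3, all(roi_size > 0))
  if (is.null(cell_extent)) {
    if (nrow(pts) == 0) stop("tile_rois: no points and no cell_extent given")
    lo <- apply(pts, 2, min)
    hi <- apply(pts, 2, max)
    span <- pmax(roi_size, ceiling((hi - lo) / roi_size) * roi_size)
    cell_extent <- cbind(lo, lo + span)
  }
  cell_extent <- matrix(as.numeric(cell_extent), nrow = 3)
  span <- cell_extent[, 2] - cell_extent[, 1]
  ncell <- span / roi_size
  for (ax in 1:3) {
    if (abs(ncell[ax] - round(ncell[ax])) > 1e-9)
      stop(sprintf(
        "tile_rois: extent not divisible by roi_size on the %s axis",
        c("x", "y", "z")[ax]))
  }
  ncell <- as.integer(round(ncell))

  idx3 <- function(p) {
    k <- floor((p - cell_extent[, 1]) / roi_size)
    k <- pmin(pmax(k, 0), ncell - 1)  # closed global max face
    k
  }
  inside <- rep(TRUE, nrow(pts))
  if (nrow(pts)) {
    for (ax in 1:3)
      inside <- inside & pts[, ax] >= cell_extent[ax, 1] &
        pts[, ax] <= cell_extent[ax, 2]
  }
  assign_idx <- rep(NA_integer_, nrow(pts))
  if (any(inside)) {
    sub <- pts[inside, , drop = FALSE]
    kx <- pmin(pmax(floor((sub[, 1] - cell_extent[1, 1]) / roi_size[1]), 0), ncell[1] - 1)
    ky <- pmin(pmax(floor((sub[, 2] - cell_extent[2, 1]) / roi_size[2]), 0), ncell[2] - 1)
    kz <- pmin(pmax(floor((sub[, 3] - cell_extent[3, 1]) / roi_size[3]), 0), ncell[3] - 1)
    assign_idx[inside] <- 1L + kx + ncell[1] * (ky + ncell[2] * kz)
  }
  n_roi <- prod(ncell)
  rois <- vector("list", n_roi)
  for (r in seq_len(n_roi)) {
    k0 <- r - 1L
    kx <- k0 %% ncell[1]
    ky <- (k0 %/% ncell[1]) %% ncell[2]
    kz <- k0 %/% (ncell[1] * ncell[2])
    lo <- cell_extent[, 1] + c(kx, ky, kz) * roi_size
    sel <- which(!is.na(assign_idx) & assign_idx == r)
    rois[[r]] <- structure(list(
      points = pts[sel, , drop = FALSE],
      merged_from = mf[sel],
      bounds = cbind(lo, lo + roi_size),
      cell_id = cell_id,
      roi_index = r,
      empty = length(sel) == 0L), class = "roi")
  }
  rois
}

#' @export
print.roi <- function(x, ...) {
  cat(sprintf("<roi %d%s> %d points, bounds x[%g,%g) y[%g,%g) z[%g,%g) nm\n",
              x$roi_index,
              if (nzchar(x$cell_id)) paste0(" of ", x$cell_id) else "",
              nrow(x$points),
              x$bounds[1, 1], x$bounds[1, 2], x$bounds[2, 1], x$bounds[2, 2],
              x$bounds[3, 1], x$bounds[3, 2]))
  invisible(x)
}

#' Wrap a bare point set as a single ROI
#'
#' Convenience for running per-ROI operations (filtering, features) on an
#' arbitrary point set: bounds default to the tight bounding box.
#'
#' @param points point set ([localization_set()], [event_list()] or matrix).
#' @param cell_id,roi_index identifiers stored on the ROI.
#' @return a `roi` object.
#' @export
as_roi <- function(points, cell_id = "", roi_index = 1L) {
  if (inherits(points, "roi")) return(points)
  pts <- as_points(points)
  mf <- if (inherits(points, "localization_set")) points$merged_from
        else rep(1L, nrow(pts))
  b <- if (nrow(pts)) t(apply(pts, 2, range)) else matrix(0, 3, 2)
  structure(list(points = pts, merged_from = mf, bounds = b,
                 cell_id = cell_id, roi_index = roi_index,
                 empty = nrow(pts) == 0L), class = "roi")
}
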