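#' Matched random point set for an ROI (random-graph null)
#'
#' Generates a random point cloud with the same number of points as the ROI,
#' emulating the spatial statistics of pure background: X and Y uniform over
#' the ROI bounds, Z normal with mean and SD fitted to the ROI's own Z
#' sample (the axial distribution of SMLM acquisitions is bell-shaped because
#' of the limited focal range, while background is laterally homogeneous).
#'
#' @param roi a `roi` (see [tile_rois()] / [as_roi()]).
#' @param seed integer seed; the result is reproducible given `(roi, seed)`.
#' @return n x 3 numeric matrix (nm).
#' @export
random_points_like <- function(roi, seed) {
  roi <- as_roi(roi)
  n <- nrow(roi$points)
  if (n < 2)
    stop("random_points_like: need >= 2 points to fit the Z distribution")
  zs <- roi$points[, 3]
  mu <- mean(zs); sdz <- stats::sd(zs)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  cbind(x = stats::runif(n, roi$bounds[1, 1], roi$bounds[1, 2]),
        y = stats::runif(n, roi$bounds[2, 1], roi$bounds[2, 2]),
        z = stats::rnorm(n, mu, sdz))
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
  invisible(NULL)
}
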