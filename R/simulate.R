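#' Ground-truth structures for the blink simulator
#'
#' Two parametric geometries cover the calibration experiments: a short rod
#' (a single antibody, default length 10 nm) and a sphere surface (a
#' caveola-like vesicle, default diameter 60 nm). Custom point sets are
#' accepted for arbitrary geometries.
#'
#' @param kind `"rod"`, `"sphere"` or `"custom"`.
#' @param length_nm rod length (nm).
#' @param diameter_nm sphere diameter (nm).
#' @param epitope_density surface density of antibody binding sites, nm^-2
#'   (spheres; default 0.012821, which puts 145 epitopes on a 60 nm sphere).
#' @param epitope_count explicit epitope count; for rods the default is 1
#'   (see the vignette), for spheres `NULL` means derive from density.
#' @param points custom epitope coordinates (kind `"custom"`).
#' @param center 3-vector, structure center (nm).
#' @return list of class `ground_truth`.
#' @export
ground_truth <- function(kind = c("sphere", "rod", "custom"),
                         length_nm = 10, diameter_nm = 60,
                         epitope_density = 0.012821, epitope_count = NULL,
                         points = NULL, center = c(0, 0, 0)) {
  kind <- match.arg(kind)
  if (kind == "rod" && is.null(epitope_count)) epitope_count <- 1L
  if (kind == "custom" && is.null(points))
    stop("ground_truth: custom structure needs 'points'")
  stopifnot(length_nm > 0, diameter_nm > 0, epitope_density >= 0)
  structure(list(kind = kind, length_nm = length_nm,
                 diameter_nm = diameter_nm,
                 epitope_density = epitope_density,
                 epitope_count = epitope_count,
                 points = if (!is.null(points)) as_points(points),
                 center = as.numeric(center)), class = "ground_truth")
}

#' Simulation parameters
#'
#' Defaults are the acquisition-matched settings: lateral (XY) localization
#' precision 20 nm, axial (Z) precision 38 nm, label-epitope linker distance
#' 20 nm, labeling efficiency 100%, 40,000 frames. The number of blinks each
#' label emits is drawn from a geometric distribution (shifted to be >= 1)
#' with configurable mean (default 5) — the simplest memoryless multiplicity
#' model; only multiplicity, not dwell-time structure, matters to the merge.
#'
#' @param lateral_sigma,axial_sigma localization precision SDs (nm).
#' @param labeling_efficiency probability an epitope carries a label.
#' @param label_epitope_distance maximum label displacement from its epitope
#'   (nm); actual displacement is uniform in magnitude and direction.
#' @param n_frames number of acquisition frames.
#' @param mean_blinks_per_label mean of the (>= 1) blink-count distribution.
#' @return list of class `sim_params`.
#' @export
sim_params <- function(lateral_sigma = 20, axial_sigma = 38,
                       labeling_efficiency = 1.0,
                       label_epitope_distance = 20,
                       n_frames = 40000, mean_blinks_per_label = 5) {
  stopifnot(lateral_sigma >= 0, axial_sigma >= 0,
            labeling_efficiency >= 0, labeling_efficiency <= 1,
            label_epitope_distance >= 0, n_frames >= 1,
            mean_blinks_per_label >= 1)
  structure(list(lateral_sigma = lateral_sigma, axial_sigma = axial_sigma,
                 labeling_efficiency = labeling_efficiency,
                 label_epitope_distance = label_epitope_distance,
                 n_frames = n_frames,
                 mean_blinks_per_label = mean_blinks_per_label),
            class = "sim_params")
}

unit_sphere_points <- function(n) {
  z <- stats::runif(n, -1, 1)
  phi <- stats::runif(n, 0, 2 * pi)
  r <- sqrt(pmax(1 - z^2, 0))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Place epitopes on a ground-truth structure
#'
#' Spheres: uniform on the surface; count either fixed at
#' `round(density * 4 pi r^2)` (deterministic, the test default) or Poisson
#' with that mean. Rods: uniform along the segment (axis = z) at the
#' configured count. Custom: the supplied points.
#'
#' @param s a [ground_truth()].
#' @param seed integer seed.
#' @param count_mode `"fixed"` or `"poisson"` (spheres with density-derived
#'   counts only).
#' @return n x 3 matrix of epitope positions (nm).
#' @export
place_epitopes <- function(s, seed = 1, count_mode = c("fixed", "poisson")) {
  count_mode <- match.arg(count_mode)
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  if (s$kind == "custom")
    return(sweep(s$points, 2, s$center, "+"))
  if (s$kind == "sphere") {
    r <- s$diameter_nm / 2
    area <- 4 * pi * r^2
    n <- if (!is.null(s$epitope_count)) s$epitope_count
         else if (count_mode == "fixed") round(s$epitope_density * area)
         else stats::rpois(1, s$epitope_density * area)
    if (n == 0) return(matrix(numeric(0), ncol = 3,
                              dimnames = list(NULL, c("x", "y", "z"))))
    pts <- unit_sphere_points(n) * r
  } else {                                       # rod along z
    n <- s$epitope_count
    if (is.null(n)) stop("place_epitopes: rod needs an epitope_count")
    if (n == 0) return(matrix(numeric(0), ncol = 3,
                              dimnames = list(NULL, c("x", "y", "z"))))
    pts <- cbind(0, 0, stats::runif(n, -s$length_nm / 2, s$length_nm / 2))
  }
  pts <- sweep(pts, 2, s$center, "+")
  colnames(pts) <- c("x", "y", "z")
  pts
}

#' Simulate blinking of labeled epitopes
#'
#' Each epitope is labeled with probability `labeling_efficiency`; the label
#' is displaced from its epitope by a random offset (direction uniform on
#' the sphere, magnitude uniform in `[0, label_epitope_distance]`). Each
#' label emits `k >= 1` blinks (shifted-geometric count); each blink is the
#' label position plus anisotropic Gaussian localization noise
#' (`lateral_sigma` per lateral axis, `axial_sigma` axially) and gets a
#' uniform random frame index.
#'
#' @param epitopes n x 3 matrix from [place_epitopes()].
#' @param p a [sim_params()].
#' @param seed integer seed.
#' @return an [event_list()] with attribute `label_of_blink` (index of the
#'   emitting label/epitope per blink).
#' @export
simulate_blinks <- function(epitopes, p = sim_params(), seed = 1) {
  epitopes <- as_points(epitopes)
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  n_ep <- nrow(epitopes)
  labeled <- which(stats::runif(n_ep) <= p$labeling_efficiency)
  if (!length(labeled)) {
    ev <- event_list(matrix(numeric(0), ncol = 3))
    attr(ev, "label_of_blink") <- integer(0)
    return(ev)
  }
  nl <- length(labeled)
  offs <- unit_sphere_points(nl) *
    stats::runif(nl, 0, p$label_epitope_distance)
  labels <- epitopes[labeled, , drop = FALSE] + offs
  k <- stats::rgeom(nl, prob = 1 / p$mean_blinks_per_label) + 1L
  lab_idx <- rep(seq_len(nl), k)
  ntot <- sum(k)
  blinks <- labels[lab_idx, , drop = FALSE] +
    cbind(stats::rnorm(ntot, 0, p$lateral_sigma),
          stats::rnorm(ntot, 0, p$lateral_sigma),
          stats::rnorm(ntot, 0, p$axial_sigma))
  frame <- sample.int(p$n_frames, ntot, replace = TRUE)
  ev <- event_list(blinks, frame = frame)
  attr(ev, "label_of_blink") <- labeled[lab_idx]
  ev
}

#' Compose a synthetic test cell
#'
#' Scatters ground-truth structures over a cell-scale frame (default
#' 18 x 18 x 1 um^3, the nominal image size), simulates blinks for each, and
#' adds uniform background noise blinks. Per-blink ground-truth structure
#' ids make pipeline recall/precision measurable.
#'
#' @param structures list of [ground_truth()] objects *without* centers; they
#'   are placed at random positions inside the frame (with `margin` from the
#'   faces).
#' @param p a [sim_params()].
#' @param n_noise number of uniform background blinks.
#' @param extent 3 x 2 matrix of the frame bounds (nm); default
#'   18 x 18 x 1 um^3 at the origin.
#' @param margin placement margin from the frame faces (nm).
#' @param seed integer seed.
#' @return list: `events` (an [event_list()]), `truth` (integer per blink:
#'   structure index, 0 = noise), `centers` (structure centers).
#' @export
make_test_cell <- function(structures, p = sim_params(), n_noise = 0,
                           extent = cbind(c(0, 0, 0), c(18000, 18000, 1000)),
                           margin = 300, seed = 1) {
  extent <- matrix(as.numeric(extent), nrow = 3)
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  ns <- length(structures)
  centers <- cbind(
    stats::runif(ns, extent[1, 1] + margin, extent[1, 2] - margin),
    stats::runif(ns, extent[2, 1] + margin, extent[2, 2] - margin),
    stats::runif(ns, extent[3, 1] + margin, extent[3, 2] - margin))
  pts <- list(); truth <- list(); frames <- list()
  for (si in seq_len(ns)) {
    s <- structures[[si]]
    s$center <- centers[si, ]
    ep <- place_epitopes(s, seed = seed + si)
    ev <- simulate_blinks(ep, p, seed = seed + 10000L + si)
    if (n_points(ev)) {
      pts[[length(pts) + 1]] <- ev$points
      frames[[length(frames) + 1]] <- ev$frame
      truth[[length(truth) + 1]] <- rep(si, n_points(ev))
    }
  }
  if (n_noise > 0) {
    noise <- cbind(stats::runif(n_noise, extent[1, 1], extent[1, 2]),
                   stats::runif(n_noise, extent[2, 1], extent[2, 2]),
                   stats::runif(n_noise, extent[3, 1], extent[3, 2]))
    pts[[length(pts) + 1]] <- noise
    frames[[length(frames) + 1]] <- sample.int(p$n_frames, n_noise,
                                               replace = TRUE)
    truth[[length(truth) + 1]] <- rep(0L, n_noise)
  }
  if (!length(pts)) {
    return(list(events = event_list(matrix(numeric(0), ncol = 3)),
                truth = integer(0), centers = centers))
  }
  ev <- event_list(do.call(rbind, pts), frame = unlist(frames))
  list(events = ev, truth = unlist(truth), centers = centers)
}
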