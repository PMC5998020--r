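#' Neighbor counts within the merge radius
#'
#' For every blink, counts the neighboring blinks within a sphere of radius
#' `T` centered on it (the blink itself excluded). This is the ranking
#' statistic driving the iterative merge.
#'
#' @param points an [event_list()], [localization_set()] or n x 3 matrix (nm).
#' @param T radius in nm, > 0.
#' @return integer vector of counts.
#' @export
neighbor_counts <- function(points, T = 20) {
  stopifnot(is.numeric(T), length(T) == 1, T > 0)
  radius_counts(as_points(points), T)
}

#' Merge parameters
#'
#' @param threshold_T merge radius in nm (default 20, the lateral resolution
#'   limit of the GSD system the pipeline targets).
#' @param max_iterations safeguard on the number of merge events; the
#'   algorithm strictly reduces the point count at every step, so the default
#'   (input size + 1, set at run time when `NULL`) is unreachable.
#' @return list of class `merge_params`.
#' @export
merge_params <- function(threshold_T = 20, max_iterations = NULL) {
  stopifnot(threshold_T > 0)
  structure(list(threshold_T = threshold_T, max_iterations = max_iterations),
            class = "merge_params")
}

#' Iterative blink merging (multi-blinking correction)
#'
#' A single fluorophore (or several fluorophores on one antibody) can blink
#' many times, producing several localizations of the same molecule scattered
#' within the resolution limit. The correction merges blinks iteratively:
#' find, for every blink, the neighbors within `T`; take the blink with the
#' most neighbors and replace it and all its neighbors by one blink at their
#' average position (average over all *original* blinks absorbed, tracked via
#' `merged_from` weights); re-rank and repeat until no two blinks are within
#' `T` of each other.
#'
#' Neighbor counts are refreshed locally (within `2T` of each new centroid)
#' after every merge, so the ranking always reflects the current point set;
#' ties are broken by lowest point index (original blinks first, in input
#' order), making the result deterministic.
#'
#' @param ev an [event_list()] (a [localization_set()] is accepted and its
#'   `merged_from` weights are carried through).
#' @param params a [merge_params()].
#' @return a [localization_set()] whose minimum pairwise distance exceeds
#'   `threshold_T` and whose `merged_from` sums to the input blink count.
#' @examples
#' ev <- event_list(cbind(c(0, 15, 30), 0, 0))
#' merge_blinks(ev, merge_params(20))  # one localization at x = 15
#' @export
merge_blinks <- function(ev, params = merge_params()) {
  pts <- as_points(ev)
  w0 <- if (inherits(ev, "localization_set")) ev$merged_from
        else rep(1L, nrow(pts))
  Tm <- params$threshold_T
  n <- nrow(pts)
  src <- if (inherits(ev, "event_list")) ev$source_label else ""
  if (n < 2)
    return(localization_set(pts, w0, source_label = src))

  cap <- 2L * n                     # originals + at most n - 1 centroids
  P <- matrix(NA_real_, cap, 3)
  w <- integer(cap)
  alive <- logical(cap)
  counts <- integer(cap)
  P[1:n, ] <- pts; w[1:n] <- w0; alive[1:n] <- TRUE

  grid <- point_grid(cap, Tm)
  for (i in 1:n) grid$insert(i, P[i, ])
  counts[1:n] <- radius_counts(pts, Tm)

  nxt <- n
  max_iter <- if (is.null(params$max_iterations)) n + 1L
              else params$max_iterations
  iter <- 0L
  while (TRUE) {
    live <- which(alive)
    cmax <- max(counts[live])
    if (cmax == 0L) break
    iter <- iter + 1L
    if (iter > max_iter)
      stop("merge_blinks: failed to converge within max_iterations")
    pick <- live[counts[live] == cmax][1]   # ties: lowest index
    nb <- grid$query(P[pick, ], Tm, exclude = pick)
    grp <- c(pick, nb)
    centroid <- colSums(P[grp, , drop = FALSE] * w[grp]) / sum(w[grp])
    for (i in grp) { grid$remove(i); alive[i] <- FALSE }
    nxt <- nxt + 1L
    P[nxt, ] <- centroid; w[nxt] <- sum(w[grp]); alive[nxt] <- TRUE
    grid$insert(nxt, centroid)
    # local refresh: any point within 2T of the centroid may have changed
    affected <- grid$query(centroid, 2 * Tm)
    for (i in affected)
      counts[i] <- length(grid$query(P[i, ], Tm, exclude = i))
  }
  keep <- which(alive)
  keep <- keep[order(keep)]
  localization_set(P[keep, , drop = FALSE], w[keep], source_label = src)
}

#' Merge report
#'
#' Input/output counts and the percent reduction of total blinks achieved by
#' the merge, the summary used to compare acquisitions.
#'
#' @param ev input [event_list()].
#' @param locs output of [merge_blinks()].
#' @return list with `n_in`, `n_out`, `percent_reduction`.
#' @export
merge_report <- function(ev, locs) {
  n_in <- n_points(ev); n_out <- n_points(locs)
  list(n_in = n_in, n_out = n_out,
       percent_reduction = if (n_in > 0) 100 * (n_in - n_out) / n_in else 0)
}
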