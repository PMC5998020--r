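#' The 28-feature blob descriptor registry
#'
#' Four groups, fixed and versioned:
#' \itemize{
#' \item size (4): `volume` (3D convex hull, nm^3), `x_range`, `y_range`,
#'   `z_range` (nm);
#' \item hollowness (4): `min_dist_centroid`, `mean_dist_centroid`,
#'   `max_dist_centroid`, `sd_dist_centroid` — statistics of member-centroid
#'   distances (nm); a hollow shell has a large *minimum*, a filled body a
#'   minimum near 0;
#' \item shape (13): from the covariance eigenvalues `l1 >= l2 >= l3`:
#'   `sphericity` (`l3/l1`), `fractional_anisotropy` (normalized eigenvalue
#'   dispersion), `linearity` (`(l1-l2)/l1`), `planarity` (`(l2-l3)/l1`),
#'   the principal-axis SDs `pc1_sd`, `pc2_sd`, `pc3_sd` (nm), eigenvalue
#'   ratios `ev_ratio21`, `ev_ratio32`, `omnivariance`, `eigenentropy`,
#'   `surface_variation` and `radius_gyration` (nm);
#' \item network (7) at the 80 nm analysis threshold: `n_nodes` (= predicted
#'   molecule count), `avg_degree`, `avg_cc`, `char_path`, `modularity_Q`,
#'   `n_modules`, `n_components`. When the blob is disconnected at 80 nm,
#'   modularity and module count are computed on the largest component (the
#'   descriptor flags this via `n_components > 1`).
#' }
#'
#' @return character vector of 28 names, attribute `version`.
#' @export
blob_descriptor_names <- function() {
  structure(c(
    "volume", "x_range", "y_range", "z_range",
    "min_dist_centroid", "mean_dist_centroid", "max_dist_centroid",
    "sd_dist_centroid",
    "sphericity", "fractional_anisotropy", "linearity", "planarity",
    "pc1_sd", "pc2_sd", "pc3_sd", "ev_ratio21", "ev_ratio32",
    "omnivariance", "eigenentropy", "surface_variation", "radius_gyration",
    "n_nodes", "avg_degree", "avg_cc", "char_path", "modularity_Q",
    "n_modules", "n_components"),
    version = "blob-registry-1")
}

#' Compute the 28-feature descriptor of a blob
#'
#' See [blob_descriptor_names()] for the registry. Blobs with fewer than 3
#' members (or rank-deficient geometry) get a partial descriptor: volume 0
#' and shape terms `NA`, flagged via the `partial` attribute.
#'
#' @param b a `blob` (from [segment_blobs()]), [localization_set()] or point
#'   matrix.
#' @param network_T threshold (nm) for the network features (default 80).
#' @return named numeric vector of length 28; attributes `partial`,
#'   `registry_version`.
#' @export
blob_descriptor <- function(b, network_T = 80) {
  pts <- if (inherits(b, "blob")) as_points(b$members) else as_points(b)
  nms <- blob_descriptor_names()
  v <- stats::setNames(rep(NA_real_, length(nms)), nms)
  n <- nrow(pts)
  partial <- n < 3
  if (n == 0) {
    attr(v, "partial") <- TRUE
    attr(v, "registry_version") <- attr(nms, "version")
    return(v)
  }
  v["x_range"] <- diff(range(pts[, 1]))
  v["y_range"] <- diff(range(pts[, 2]))
  v["z_range"] <- diff(range(pts[, 3]))
  centroid <- colMeans(pts)
  dc <- sqrt(colSums((t(pts) - centroid)^2))
  v["min_dist_centroid"] <- min(dc)
  v["mean_dist_centroid"] <- mean(dc)
  v["max_dist_centroid"] <- max(dc)
  v["sd_dist_centroid"] <- if (n > 1) stats::sd(dc) else 0

  if (n >= 3) {
    vol <- convex_hull_volume(pts)
    v["volume"] <- as.numeric(vol)
    if (isTRUE(attr(vol, "degenerate"))) partial <- TRUE
    ev <- eigen(stats::cov(pts), symmetric = TRUE, only.values = TRUE)$values
    ev <- pmax(ev, 0)
    l1 <- ev[1]; l2 <- ev[2]; l3 <- ev[3]
    if (l1 > 0) {
      v["sphericity"] <- l3 / l1
      v["linearity"] <- (l1 - l2) / l1
      v["planarity"] <- (l2 - l3) / l1
      v["ev_ratio21"] <- l2 / l1
      lbar <- mean(ev)
      v["fractional_anisotropy"] <-
        sqrt(3 / 2) * sqrt(sum((ev - lbar)^2)) / sqrt(sum(ev^2))
      v["ev_ratio32"] <- if (l2 > 0) l3 / l2 else 0
      v["pc1_sd"] <- sqrt(l1); v["pc2_sd"] <- sqrt(l2); v["pc3_sd"] <- sqrt(l3)
      v["omnivariance"] <- (l1 * l2 * l3)^(1 / 3)
      tot <- sum(ev)
      v["surface_variation"] <- l3 / tot
      v["radius_gyration"] <- sqrt(tot)
      p <- ev[ev > 0] / tot
      v["eigenentropy"] <- -sum(p * log(p))
    } else partial <- TRUE
  } else {
    v["volume"] <- 0
  }

  g <- build_graph(pts, network_T, mode = "unweighted")
  nm_node <- node_measures(g)
  gm <- graph_measures(g, modularity = FALSE)
  v["n_nodes"] <- n
  v["avg_degree"] <- mean(nm_node$degree)
  v["avg_cc"] <- mean(nm_node$cc)
  v["char_path"] <- gm$char_path
  v["n_components"] <- gm$n_components
  mp <- largest_component_partition(g)
  v["modularity_Q"] <- mp$Q
  v["n_modules"] <- mp$n_modules

  attr(v, "partial") <- partial
  attr(v, "registry_version") <- attr(nms, "version")
  v
}

# Newman partition restricted to the largest connected component.
largest_component_partition <- function(g) {
  comp <- igraph::components(as_igraph(g))
  big <- which.max(comp$csize)
  keep <- which(comp$membership == big)
  if (length(keep) == g$n) return(newman_partition(g))
  pos <- integer(g$n); pos[keep] <- seq_along(keep)
  e <- g$edges
  sel <- e$i %in% keep & e$j %in% keep
  sub <- structure(list(
    n = length(keep),
    edges = data.frame(i = pos[e$i[sel]], j = pos[e$j[sel]],
                       d = e$d[sel], w = e$w[sel]),
    threshold_T = g$threshold_T, mode = g$mode), class = "proximity_graph")
  newman_partition(sub)
}

#' Multi-threshold modularity profile of a blob
#'
#' For each threshold of the grid: the number of connected components of the
#' blob's proximity graph, the Newman module count within the largest
#' component, and the mean module size. Blobs typically become one connected
#' component above ~50-60 nm and show a stable modular structure over a broad
#' band of thresholds.
#'
#' @param b a `blob`, [localization_set()] or point matrix.
#' @param grid thresholds (nm), default [threshold_grid()].
#' @return data.frame with columns `threshold`, `n_components`, `n_modules`,
#'   `mean_module_size`.
#' @export
multi_threshold_modularity <- function(b, grid = threshold_grid()) {
  stopifnot(length(grid) > 0)
  pts <- if (inherits(b, "blob")) as_points(b$members) else as_points(b)
  out <- data.frame(threshold = grid, n_components = NA_integer_,
                    n_modules = NA_integer_, mean_module_size = NA_real_)
  pr_max <- radius_pairs(pts, max(grid))
  n <- nrow(pts)
  for (k in seq_along(grid)) {
    Tt <- grid[k]
    sel <- pr_max$d <= Tt
    ed <- data.frame(i = pr_max$i[sel], j = pr_max$j[sel], d = pr_max$d[sel])
    ed$w <- 1 / pmax(ed$d, 1)
    g <- structure(list(n = n, edges = ed, threshold_T = Tt,
                        mode = "unweighted"), class = "proximity_graph")
    comp <- igraph::components(as_igraph(g))
    mp <- largest_component_partition(g)
    out$n_components[k] <- comp$no
    out$n_modules[k] <- mp$n_modules
    out$mean_module_size[k] <- max(comp$csize) / mp$n_modules
  }
  out
}

#' Blob descriptor table
#'
#' @param blob_set a [segment_blobs()] result (or list of blobs).
#' @param network_T threshold (nm) for network features (default 80).
#' @return data.frame: one row per blob, columns `blob_id`, the 28
#'   descriptor features and `partial`.
#' @export
blob_table <- function(blob_set, network_T = 80) {
  blobs <- if (inherits(blob_set, "blob_set")) blob_set$blobs else blob_set
  if (!length(blobs)) {
    nms <- blob_descriptor_names()
    df <- as.data.frame(matrix(numeric(0), 0, length(nms) + 2,
                               dimnames = list(NULL, c("blob_id", nms,
                                                       "partial"))))
    return(df)
  }
  rows <- lapply(blobs, function(b) {
    d <- blob_descriptor(b, network_T = network_T)
    c(blob_id = b$blob_id, d, partial = as.numeric(attr(d, "partial")))
  })
  as.data.frame(do.call(rbind, rows))
}
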