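#' Build a proximity graph from a 3D point set
#'
#' Nodes are points; an undirected edge joins nodes `i` and `j` iff their
#' Euclidean distance `d_ij <= T`. In weighted mode the edge weight is
#' `w_ij = 1/d_ij`, so stronger edges connect more proximate nodes. Weights
#' are capped at `1/eps` with `eps = 1` nm as a defensive guard against
#' coincident points (post-merge data cannot contain pairs closer than the
#' merge threshold, so the cap is normally inert).
#'
#' @param points point set (matrix, [event_list()], [localization_set()] or
#'   `roi`).
#' @param T proximity threshold in nm, > 0.
#' @param mode `"unweighted"` or `"weighted"`.
#' @return object of class `proximity_graph`: list with `n`, `edges`
#'   (data.frame `i`, `j`, `d`, `w`), `threshold_T`, `mode`.
#' @examples
#' g <- build_graph(cbind(c(0, 50, 100), 0, 0), T = 60)
#' node_measures(g)$degree
#' @export
build_graph <- function(points, T, mode = c("unweighted", "weighted")) {
  mode <- match.arg(mode)
  stopifnot(T > 0)
  pts <- as_points(points)
  pr <- radius_pairs(pts, T)
  w <- 1 / pmax(pr$d, 1)            # cap at 1/eps, eps = 1 nm
  structure(list(n = nrow(pts),
                 edges = data.frame(i = pr$i, j = pr$j, d = pr$d, w = w),
                 threshold_T = T, mode = mode),
            class = "proximity_graph")
}

#' @export
print.proximity_graph <- function(x, ...) {
  cat(sprintf("<proximity_graph> %d nodes, %d edges, T = %g nm, %s\n",
              x$n, nrow(x$edges), x$threshold_T, x$mode))
  invisible(x)
}

# igraph view of a proximity graph; edge attributes d and w are carried over.
as_igraph <- function(g) {
  ig <- igraph::make_empty_graph(g$n, directed = FALSE)
  if (nrow(g$edges)) {
    ig <- igraph::add_edges(ig, rbind(g$edges$i, g$edges$j))
    igraph::E(ig)$d <- g$edges$d
    igraph::E(ig)$w <- g$edges$w
  }
  ig
}

#' Node-level network measures
#'
#' Computes, for every node: unweighted degree (incident edge count), weighted
#' degree (sum of incident `1/d` weights), unweighted and weighted neighbor
#' degree (mean unweighted degree / mean weighted degree over the node's
#' neighbors, 0 for isolated nodes), and unweighted / weighted clustering
#' coefficients. The unweighted clustering coefficient is closed triangles
#' over possible triangles at the node; the weighted variant is the
#' Barrat weight-averaged form. Both are 0 by convention for nodes with
#' fewer than two neighbors.
#'
#' @param g a [build_graph()] result.
#' @return data.frame with columns `degree`, `wdegree`, `ndeg`, `wndeg`,
#'   `cc`, `wcc`.
#' @export
node_measures <- function(g) {
  n <- g$n
  out <- data.frame(degree = numeric(n), wdegree = numeric(n),
                    ndeg = numeric(n), wndeg = numeric(n),
                    cc = numeric(n), wcc = numeric(n))
  if (n == 0) return(out)
  e <- g$edges
  if (nrow(e)) {
    out$degree <- tabulate(e$i, n) + tabulate(e$j, n)
    wsum <- numeric(n)
    acc <- rowsum(c(e$w, e$w), c(e$i, e$j))
    wsum[as.integer(rownames(acc))] <- acc[, 1]
    out$wdegree <- wsum
    # neighbor degree: aggregate neighbor values over the edge list
    nd <- rowsum(c(out$degree[e$j], out$degree[e$i]), c(e$i, e$j))
    wd <- rowsum(c(out$wdegree[e$j], out$wdegree[e$i]), c(e$i, e$j))
    idx <- as.integer(rownames(nd))
    out$ndeg[idx] <- nd[, 1] / out$degree[idx]
    out$wndeg[idx] <- wd[, 1] / out$degree[idx]
    ig <- as_igraph(g)
    cc <- igraph::transitivity(ig, type = "local", isolates = "zero")
    wcc <- igraph::transitivity(ig, type = "barrat",
                                weights = igraph::E(ig)$w, isolates = "zero")
    out$cc <- ifelse(is.nan(cc), 0, cc)
    out$wcc <- ifelse(is.nan(wcc), 0, wcc)
  }
  out
}

#' Graph-level network measures
#'
#' Summarizes a proximity graph: characteristic path length (mean
#' shortest-path length over *connected* node pairs; unweighted paths count
#' hops, weighted paths use the inter-node distance `d` as edge length),
#' connected components (count and sizes), edge density, global efficiency,
#' degree assortativity and Newman modularity (see [newman_partition()]).
#'
#' A single-node graph is degenerate: path length is defined as 0 and the
#' result carries `degenerate = TRUE`.
#'
#' @param g a [build_graph()] result.
#' @param modularity compute the (comparatively expensive) Newman partition
#'   (default `TRUE`).
#' @return named list of measures.
#' @export
graph_measures <- function(g, modularity = TRUE) {
  ig <- as_igraph(g)
  comp <- igraph::components(ig)
  res <- list(
    n_nodes = g$n,
    n_edges = nrow(g$edges),
    n_components = comp$no,
    component_sizes = as.integer(comp$csize),
    mean_component_size = if (comp$no > 0) mean(comp$csize) else 0,
    largest_component_fraction = if (g$n > 0) max(comp$csize) / g$n else NA_real_,
    density = if (g$n > 1) nrow(g$edges) / (g$n * (g$n - 1) / 2) else NA_real_,
    degenerate = g$n <= 1)
  if (g$n <= 1) {
    res$char_path <- 0; res$w_char_path <- 0
    res$global_efficiency <- NA_real_; res$w_global_efficiency <- NA_real_
    res$assortativity <- NA_real_; res$w_assortativity <- NA_real_
    if (modularity) { res$Q <- NA_real_; res$n_modules <- NA_integer_ }
    return(res)
  }
  res$char_path <- igraph::mean_distance(ig, weights = NA)
  res$w_char_path <- if (nrow(g$edges))
    igraph::mean_distance(ig, weights = igraph::E(ig)$d) else NaN
  res$char_path[!is.finite(res$char_path)] <- NA_real_
  res$w_char_path[!is.finite(res$w_char_path)] <- NA_real_
  res$global_efficiency <- igraph::global_efficiency(ig, weights = NA)
  res$w_global_efficiency <- if (nrow(g$edges))
    igraph::global_efficiency(ig, weights = igraph::E(ig)$d) else NaN
  res$assortativity <- suppressWarnings(igraph::assortativity_degree(ig))
  nm <- node_measures(g)
  res$w_assortativity <- suppressWarnings(
    igraph::assortativity(ig, values = nm$wdegree))
  if (modularity) {
    mp <- newman_partition(g)
    res$Q <- mp$Q
    res$n_modules <- mp$n_modules
  }
  res
}
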