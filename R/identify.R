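#' X-means clustering (BIC-driven K selection)
#'
#' K-means extended with automatic selection of the number of clusters:
#' starting from one cluster, each cluster is tentatively split in two
#' (2-means on its members) and the split is kept when it improves the BIC
#' under a spherical-Gaussian model of the cluster; splitting continues until
#' no split improves BIC or `k_max` is reached, followed by a global K-means
#' refinement at the selected K.
#'
#' @param X numeric matrix (rows = samples).
#' @param k_max maximum number of clusters (default 10).
#' @param seed integer seed.
#' @param nstart K-means restarts (default 10).
#' @return list with `assignment`, `centers`, `K`.
#' @export
xmeans <- function(X, k_max = 10, seed = 1, nstart = 10) {
  X <- as.matrix(X)
  n <- nrow(X); d <- ncol(X)
  stopifnot(n >= 2)
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))

  bic <- function(Xs, assign, centers) {
    # diagonal-Gaussian BIC: per-dimension variances pooled over clusters.
    # A single shared spherical variance over-splits anisotropic data (any
    # standardized feature set is anisotropic within clusters), so the
    # axis-aligned model is used instead.
    ns <- nrow(Xs); K <- nrow(centers)
    if (ns <= K) return(-Inf)
    resid <- Xs - centers[assign, , drop = FALSE]
    sig2 <- pmax(colMeans(resid^2), 1e-12)
    sizes <- tabulate(assign, K)
    ll <- sum(ifelse(sizes > 0, sizes * log(sizes / ns), 0)) -
      ns / 2 * sum(log(2 * pi * sig2)) - ns * d / 2
    p <- K * d + K + d        # centroids + mixing weights + variances
    ll - p / 2 * log(ns)
  }

  km <- function(Xs, K) {
    if (K == 1 || nrow(unique(Xs)) < K)
      return(list(cluster = rep(1L, nrow(Xs)),
                  centers = matrix(colMeans(Xs), 1)))
    fit <- suppressWarnings(stats::kmeans(Xs, centers = K, nstart = nstart,
                                          iter.max = 100))
    list(cluster = fit$cluster, centers = fit$centers)
  }

  clusters <- list(seq_len(n))
  changed <- TRUE
  while (changed && length(clusters) < k_max) {
    changed <- FALSE
    nxt <- list()
    for (idx in clusters) {
      if (length(clusters) + length(nxt) - 1 >= k_max ||
          length(idx) < 4) { nxt <- c(nxt, list(idx)); next }
      Xs <- X[idx, , drop = FALSE]
      parent <- km(Xs, 1)
      child <- km(Xs, 2)
      if (length(unique(child$cluster)) == 2 &&
          bic(Xs, child$cluster, child$centers) >
            bic(Xs, parent$cluster, parent$centers)) {
        nxt <- c(nxt, list(idx[child$cluster == 1]),
                 list(idx[child$cluster == 2]))
        changed <- TRUE
      } else nxt <- c(nxt, list(idx))
    }
    clusters <- nxt
  }
  K <- length(clusters)
  assignment <- integer(n)
  for (k in seq_len(K)) assignment[clusters[[k]]] <- k
  if (K > 1) {                      # global refinement at the chosen K
    centers0 <- t(vapply(clusters, function(idx)
      colMeans(X[idx, , drop = FALSE]), numeric(d)))
    fit <- suppressWarnings(stats::kmeans(X, centers = centers0,
                                          iter.max = 100))
    assignment <- fit$cluster
    centers <- fit$centers
  } else centers <- matrix(colMeans(X), 1)
  list(assignment = assignment, centers = centers, K = K)
}

# Standardization helpers shared by clustering, matching and assignment.
fit_scaling <- function(X) {
  ctr <- apply(X, 2, function(v) stats::median(v, na.rm = TRUE))
  ctr[!is.finite(ctr)] <- 0
  Ximp <- X
  for (k in seq_len(ncol(X))) Ximp[!is.finite(Ximp[, k]), k] <- ctr[k]
  mu <- colMeans(Ximp)
  sg <- apply(Ximp, 2, stats::sd)
  sg[!is.finite(sg) | sg < 1e-12] <- 1
  list(center = mu, scale = sg, impute = ctr)
}

apply_scaling <- function(X, scaling) {
  X <- as.matrix(X)
  for (k in seq_len(ncol(X)))
    X[!is.finite(X[, k]), k] <- scaling$impute[k]
  sweep(sweep(X, 2, scaling$center), 2, scaling$scale, "/")
}

descriptor_matrix <- function(descriptors) {
  nms <- blob_descriptor_names()
  if (is.data.frame(descriptors)) {
    stopifnot(all(nms %in% names(descriptors)))
    X <- as.matrix(descriptors[, nms])
  } else {
    X <- as.matrix(descriptors)
    stopifnot(ncol(X) == length(nms))
    colnames(X) <- nms
  }
  X
}

#' Discover blob groups by X-means
#'
#' Clusters a population's 28-feature blob descriptors after per-feature
#' standardization (the features mix nm, nm^3 and dimensionless ratios;
#' unscaled Euclidean distance would be volume-dominated). Groups are
#' labeled in decreasing size order. The fitted scaling is stored in the
#' model so test-phase blobs are transformed identically.
#'
#' @param descriptors data.frame from [blob_table()] (or 28-column matrix).
#' @param k_max maximum number of groups (default 10).
#' @param seed integer seed.
#' @param population_tag free-text tag (e.g. the cell line).
#' @return object of class `group_model`: `centroids` (raw feature space),
#'   `centroids_scaled`, `sizes`, `assignment`, `scaling`, `K`,
#'   `registry_version`, `population_tag`.
#' @export
discover_groups <- function(descriptors, k_max = 10, seed = 1,
                            population_tag = "") {
  X <- descriptor_matrix(descriptors)
  if (nrow(X) < 2 * 2)
    stop("discover_groups: too few blobs to cluster")
  scaling <- fit_scaling(X)
  Xs <- apply_scaling(X, scaling)
  fit <- xmeans(Xs, k_max = k_max, seed = seed)
  sizes <- tabulate(fit$assignment, fit$K)
  ord <- order(-sizes)
  relabel <- integer(fit$K); relabel[ord] <- seq_len(fit$K)
  assignment <- relabel[fit$assignment]
  centroids_scaled <- fit$centers[ord, , drop = FALSE]
  Ximp <- apply_scaling(X, scaling)   # imputed+scaled; invert scaling for raw
  centroids <- t(vapply(seq_len(fit$K), function(k)
    colMeans(X[assignment == k, , drop = FALSE], na.rm = TRUE),
    numeric(ncol(X))))
  colnames(centroids) <- colnames(X)
  structure(list(centroids = centroids,
                 centroids_scaled = centroids_scaled,
                 sizes = sizes[ord], assignment = assignment,
                 scaling = scaling, K = fit$K,
                 registry_version = attr(blob_descriptor_names(), "version"),
                 population_tag = population_tag),
            class = "group_model")
}

#' @export
print.group_model <- function(x, ...) {
  cat(sprintf("<group_model%s> K = %d groups, sizes: %s\n",
              if (nzchar(x$population_tag)) paste0(" ", x$population_tag)
              else "", x$K, paste(x$sizes, collapse = ", ")))
  invisible(x)
}

#' Match blob groups across two populations
#'
#' Computes the Euclidean distance matrix `D` between the group centroids of
#' two populations and matches each group of `model_a` to the closest group
#' of `model_b` when that distance is below the matching threshold `beta`
#' (default 30); groups whose closest counterpart is at distance `>= beta`
#' are reported unmatched. More than one group of `model_a` may match the
#' same group of `model_b`. The exponential similarity `exp(-D)` is reported
#' alongside for audit; matching itself operates on the distance.
#'
#' By default distances are taken in the raw (unscaled) feature space, the
#' space in which the default `beta = 30` is calibrated; `space = "scaled"`
#' uses the standardized space of `model_a`.
#'
#' @param model_a,model_b [discover_groups()] models built on the same
#'   descriptor registry.
#' @param beta matching threshold on the centroid distance (default 30).
#' @param space `"raw"` (default) or `"scaled"`.
#' @param exclude_features optional feature names dropped before matching
#'   (e.g. `"n_nodes"` for the molecule-count sensitivity check).
#' @return list of class `group_matching`: `pairs` (data.frame `group_a`,
#'   `group_b`, `distance`, `similarity`, `matched`), `distance_matrix`,
#'   `beta`, `space`.
#' @export
match_groups <- function(model_a, model_b, beta = 30,
                         space = c("raw", "scaled"),
                         exclude_features = NULL) {
  space <- match.arg(space)
  if (!identical(model_a$registry_version, model_b$registry_version))
    stop("match_groups: descriptor registry mismatch")
  A <- if (space == "raw") model_a$centroids else model_a$centroids_scaled
  B <- if (space == "raw") model_b$centroids else {
    # express model_b centroids in model_a's scaled space
    apply_scaling(model_b$centroids, model_a$scaling)
  }
  if (!is.null(exclude_features)) {
    keep <- !(blob_descriptor_names() %in% exclude_features)
    A <- A[, keep, drop = FALSE]; B <- B[, keep, drop = FALSE]
  }
  D <- sqrt(cross_dist2(A, B))
  dimnames(D) <- list(paste0("A", seq_len(nrow(A))),
                      paste0("B", seq_len(nrow(B))))
  jstar <- max.col(-D, ties.method = "first")
  dmin <- D[cbind(seq_len(nrow(D)), jstar)]
  pairs <- data.frame(group_a = seq_len(nrow(D)),
                      group_b = ifelse(dmin < beta, jstar, NA_integer_),
                      distance = dmin,
                      similarity = exp(-dmin),
                      matched = dmin < beta)
  structure(list(pairs = pairs, distance_matrix = D, beta = beta,
                 space = space), class = "group_matching")
}

#' Assign blobs to learned groups (test phase)
#'
#' Each blob's descriptor is standardized with the model's stored scaling and
#' labeled with the nearest group centroid; the distance is reported for
#' audit. Exact ties go to the lowest group index and are flagged.
#'
#' @param model a [discover_groups()] model.
#' @param descriptors data.frame from [blob_table()] (or 28-column matrix).
#' @return data.frame with `group`, `distance`, `tie`.
#' @export
assign_blobs <- function(model, descriptors) {
  X <- descriptor_matrix(descriptors)
  Xs <- apply_scaling(X, model$scaling)
  D <- sqrt(cross_dist2(Xs, model$centroids_scaled))
  grp <- max.col(-D, ties.method = "first")
  dmin <- D[cbind(seq_len(nrow(D)), grp)]
  tie <- vapply(seq_len(nrow(D)), function(r)
    sum(abs(D[r, ] - dmin[r]) < 1e-12) > 1, logical(1))
  data.frame(group = grp, distance = dmin, tie = tie)
}

#' Serialize / restore a group model as JSON
#'
#' @param model a [discover_groups()] model.
#' @param path destination file.
#' @return `path` (write) or a `group_model` (read).
#' @export
write_group_model <- function(model, path) {
  jsonlite::write_json(list(
    centroids = model$centroids, centroids_scaled = model$centroids_scaled,
    sizes = model$sizes, K = model$K,
    scaling = model$scaling, registry_version = model$registry_version,
    population_tag = model$population_tag), path, digits = NA)
  invisible(path)
}

#' @rdname write_group_model
#' @export
read_group_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  nms <- blob_descriptor_names()
  for (f in c("centroids", "centroids_scaled"))
    j[[f]] <- matrix(as.numeric(j[[f]]), ncol = length(nms),
                     dimnames = list(NULL, nms))
  j$scaling <- lapply(j$scaling, as.numeric)
  structure(j[c("centroids", "centroids_scaled", "sizes", "assignment",
                "scaling", "K", "registry_version", "population_tag")],
            class = "group_model")
}
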