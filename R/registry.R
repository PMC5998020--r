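#' Proximity-threshold grid
#'
#' The arithmetic grid of distance thresholds at which ROI networks are
#' built: 20 nm (the resolution limit, also the merge radius) to 250 nm in
#' steps of 10 nm — 24 thresholds.
#'
#' @return numeric vector of 24 threshold values (nm).
#' @export
threshold_grid <- function() seq(20, 250, by = 10)

#' The ROI measure registry (32 named network measures)
#'
#' Names follow the `w`/`uw` (weighted/unweighted) and `Avg`/`Med` scheme of
#' the printed measures (`wAvgDeg`, `uwAvgDeg`, `wAvgNDeg`, `uwAvgNDeg`,
#' `wAvgCC`, `wMedCC`, ...). Node-level statistics (degree, neighbor degree,
#' clustering coefficient; mean/median/SD/max) are complemented by
#' graph-level measures (characteristic path length, global efficiency,
#' assortativity, Newman modularity and module count in both modes, plus
#' component structure, density, node count and isolated-node fraction).
#' The registry is versioned so downstream tables can state which definition
#' produced them.
#'
#' @return character vector of 32 measure names, with attribute `version`.
#' @export
measure_registry <- function() {
  structure(c(
    "uwAvgDeg", "uwMedDeg", "wAvgDeg", "wMedDeg",
    "uwAvgNDeg", "uwMedNDeg", "wAvgNDeg", "wMedNDeg",
    "uwAvgCC", "uwMedCC", "wAvgCC", "wMedCC",
    "uwSdDeg", "wSdDeg", "uwMaxDeg", "wMaxDeg",
    "uwCharPath", "wCharPath", "uwGlobalEff", "wGlobalEff",
    "uwAssort", "wAssort",
    "uwModularity", "wModularity", "uwNModules", "wNModules",
    "nComponents", "meanCompSize", "largestCompFrac", "density",
    "nNodes", "isolatedFrac"),
    version = "roi-registry-1")
}

#' Multi-threshold ROI feature vector
#'
#' Evaluates the full measure registry (see [measure_registry()]) on the
#' ROI's proximity graphs at every threshold of the grid: 32 measures x 24
#' thresholds = 768 features per ROI. Degenerate ROIs (fewer than 2 points)
#' yield an all-missing vector flagged via the `missing` attribute; measures
#' undefined on a particular graph (e.g. assortativity of a regular graph)
#' are `NA` and are treated as missing downstream, never NaN-propagated.
#'
#' @param roi a `roi` (or any point set, wrapped via [as_roi()]).
#' @param thresholds numeric vector of thresholds in nm
#'   (default [threshold_grid()]).
#' @param modularity include the Newman modularity measures (default `TRUE`;
#'   they dominate runtime on dense graphs).
#' @return object of class `roi_features`: list with `values` (32 x 24 named
#'   matrix), `measure_names`, `thresholds`, `missing` (logical),
#'   `cell_id`, `roi_index`.
#' @export
roi_features <- function(roi, thresholds = threshold_grid(),
                         modularity = TRUE) {
  roi <- as_roi(roi)
  measures <- measure_registry()
  vals <- matrix(NA_real_, length(measures), length(thresholds),
                 dimnames = list(measures, paste0("T", thresholds)))
  out <- structure(list(values = vals, measure_names = measures,
                        thresholds = thresholds,
                        missing = FALSE,
                        cell_id = roi$cell_id, roi_index = roi$roi_index),
                   class = "roi_features")
  pts <- roi$points
  if (nrow(pts) < 2) { out$missing <- TRUE; return(out) }
  pr_max <- radius_pairs(pts, max(thresholds))
  n <- nrow(pts)
  for (t_idx in seq_along(thresholds)) {
    Tt <- thresholds[t_idx]
    sel <- pr_max$d <= Tt
    ed <- data.frame(i = pr_max$i[sel], j = pr_max$j[sel], d = pr_max$d[sel])
    ed$w <- 1 / pmax(ed$d, 1)
    g_uw <- structure(list(n = n, edges = ed, threshold_T = Tt,
                           mode = "unweighted"), class = "proximity_graph")
    nm <- node_measures(g_uw)
    gm <- graph_measures(g_uw, modularity = FALSE)
    v <- c(
      uwAvgDeg = mean(nm$degree), uwMedDeg = stats::median(nm$degree),
      wAvgDeg = mean(nm$wdegree), wMedDeg = stats::median(nm$wdegree),
      uwAvgNDeg = mean(nm$ndeg), uwMedNDeg = stats::median(nm$ndeg),
      wAvgNDeg = mean(nm$wndeg), wMedNDeg = stats::median(nm$wndeg),
      uwAvgCC = mean(nm$cc), uwMedCC = stats::median(nm$cc),
      wAvgCC = mean(nm$wcc), wMedCC = stats::median(nm$wcc),
      uwSdDeg = stats::sd(nm$degree), wSdDeg = stats::sd(nm$wdegree),
      uwMaxDeg = max(nm$degree), wMaxDeg = max(nm$wdegree),
      uwCharPath = gm$char_path, wCharPath = gm$w_char_path,
      uwGlobalEff = gm$global_efficiency,
      wGlobalEff = gm$w_global_efficiency,
      uwAssort = gm$assortativity, wAssort = gm$w_assortativity,
      uwModularity = NA_real_, wModularity = NA_real_,
      uwNModules = NA_real_, wNModules = NA_real_,
      nComponents = gm$n_components, meanCompSize = gm$mean_component_size,
      largestCompFrac = gm$largest_component_fraction,
      density = gm$density, nNodes = n,
      isolatedFrac = mean(nm$degree == 0))
    if (modularity) {
      g_w <- g_uw; g_w$mode <- "weighted"
      mp_uw <- newman_partition(g_uw)
      mp_w <- newman_partition(g_w)
      v["uwModularity"] <- mp_uw$Q
      v["wModularity"] <- mp_w$Q
      v["uwNModules"] <- mp_uw$n_modules
      v["wNModules"] <- mp_w$n_modules
    }
    v[is.nan(v)] <- NA_real_
    out$values[, t_idx] <- v[measures]
  }
  out
}

#' Flatten ROI feature vectors into a features-by-ROI table
#'
#' @param fv_list list of [roi_features()] results.
#' @return data.frame: one row per ROI, columns `<measure>@T<threshold>`,
#'   plus `cell_id` and `roi_index`.
#' @export
features_table <- function(fv_list) {
  stopifnot(length(fv_list) > 0)
  rows <- lapply(fv_list, function(fv) {
    v <- as.vector(fv$values)
    names(v) <- as.vector(outer(fv$measure_names,
                                paste0("@T", fv$thresholds), paste0))
    v
  })
  df <- as.data.frame(do.call(rbind, rows), check.names = FALSE)
  df$cell_id <- vapply(fv_list, function(f) f$cell_id, character(1))
  df$roi_index <- vapply(fv_list, function(f) f$roi_index, integer(1))
  df
}
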