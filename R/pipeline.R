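#' Pipeline configuration
#'
#' Gathers every tunable of the end-to-end pipeline, with the analysis
#' defaults: merge at 20 nm, 3 x 3 x 1 um^3 ROIs, the 20-250 nm threshold
#' grid, degree filtering at 80 nm with alpha = 4, mean-shift bandwidth
#' 80 nm, group matching at beta = 30. All randomized stages draw their
#' seeds deterministically from `seed`.
#'
#' @param merge_T merge radius (nm).
#' @param roi_size ROI edge lengths (nm).
#' @param thresholds proximity-threshold grid (nm).
#' @param filter a [filter_params()].
#' @param bandwidth mean-shift bandwidth (nm).
#' @param min_blob_size minimum blob size.
#' @param k_max X-means cap.
#' @param beta group-matching threshold.
#' @param modularity_features include modularity in ROI features.
#' @param n_trees random-forest size for validation.
#' @param seed master seed.
#' @param workers parallel workers for per-ROI stages (default 1).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(merge_T = 20, roi_size = c(3000, 3000, 1000),
                            thresholds = threshold_grid(),
                            filter = filter_params(),
                            bandwidth = 80, min_blob_size = 3,
                            k_max = 10, beta = 30,
                            modularity_features = TRUE,
                            n_trees = 500, seed = 1, workers = 1) {
  structure(list(merge_T = merge_T, roi_size = roi_size,
                 thresholds = thresholds, filter = filter,
                 bandwidth = bandwidth, min_blob_size = min_blob_size,
                 k_max = k_max, beta = beta,
                 modularity_features = modularity_features,
                 n_trees = n_trees, seed = seed, workers = workers,
                 registry_versions = c(
                   roi = attr(measure_registry(), "version"),
                   blob = attr(blob_descriptor_names(), "version"))),
            class = "pipeline_config")
}

roi_apply <- function(rois, fn, workers) {
  if (workers > 1 && .Platform$OS.type == "unix")
    parallel::mclapply(rois, fn, mc.cores = workers)
  else lapply(rois, fn)
}

# Process one cell: merge, tile, per-ROI features / filter / blobs.
process_cell <- function(ev, cfg, cell_id) {
  locs <- merge_blinks(ev, merge_params(cfg$merge_T))
  rois <- tile_rois(locs, roi_size = cfg$roi_size, cell_id = cell_id)
  occupied <- Filter(function(r) nrow(r$points) >= 2, rois)
  fv <- roi_apply(occupied, function(r)
    roi_features(r, thresholds = cfg$thresholds,
                 modularity = cfg$modularity_features), cfg$workers)
  filtered <- roi_apply(occupied, function(r)
    degree_filter(r, cfg$filter,
                  seed = cfg$seed + 7919L * r$roi_index), cfg$workers)
  kept <- do.call(rbind, lapply(filtered, as_points))
  kept_mf <- unlist(lapply(filtered, function(f) f$merged_from))
  retained <- localization_set(
    if (is.null(kept)) matrix(numeric(0), ncol = 3) else kept,
    if (is.null(kept_mf)) integer(0) else kept_mf,
    source_label = cell_id)
  blobs <- segment_blobs(retained, bandwidth = cfg$bandwidth,
                         min_size = cfg$min_blob_size)
  bt <- blob_table(blobs, network_T = cfg$filter$T_filter)
  if (nrow(bt)) bt$cell_id <- cell_id
  list(cell_id = cell_id,
       merge = merge_report(ev, locs),
       localizations = locs, rois = rois, features = fv,
       retained = retained, blob_set = blobs, blob_table = bt)
}

#' Run the full analysis pipeline
#'
#' Executes the whole chain on one or more cells (event lists): blink
#' merging, ROI tiling, multi-threshold ROI features, random-graph degree
#' filtering, mean-shift blob segmentation and 28-feature descriptors;
#' with two or more populations it additionally produces the Mann-Whitney /
#' L2 / Bonferroni significance map and per-population group models with
#' cross-population matching. Per-ROI stages share no state and honor
#' `cfg$workers`.
#'
#' @param events named list of [event_list()] objects (names = cell ids).
#' @param labels character vector, population label per cell (same length as
#'   `events`); a single population is allowed (no comparison stages then).
#' @param cfg a [pipeline_config()].
#' @return list of class `pipeline_result`: per-cell results, `blob_table`
#'   (all cells), optional `significance`, `models`, `matching`,
#'   `labeled_blobs`, and `provenance` (config, seeds, registry versions).
#' @export
run_pipeline <- function(events, labels = NULL, cfg = pipeline_config()) {
  stopifnot(length(events) >= 1)
  if (is.null(names(events)))
    names(events) <- paste0("cell", seq_along(events))
  if (is.null(labels)) labels <- rep("pop1", length(events))
  stopifnot(length(labels) == length(events))
  cells <- lapply(seq_along(events), function(i)
    process_cell(events[[i]], cfg, names(events)[i]))
  names(cells) <- names(events)
  bt <- do.call(rbind, Filter(nrow, lapply(cells, `[[`, "blob_table")))
  res <- list(cells = cells, blob_table = bt, labels = labels,
              provenance = list(config = cfg, registry = cfg$registry_versions,
                                timestamp = format(Sys.time())))
  pops <- unique(labels)
  if (length(pops) >= 2 && !is.null(bt) && nrow(bt)) {
    fv_by_pop <- lapply(pops, function(p)
      unlist(lapply(cells[labels == p], `[[`, "features"),
             recursive = FALSE))
    names(fv_by_pop) <- pops
    if (all(lengths(fv_by_pop) > 0)) {
      pmat <- population_pvalues(fv_by_pop[[1]], fv_by_pop[[2]])
      res$significance <- aggregate_pvalues(list(pmat))
    }
    models <- lapply(pops, function(p) {
      rows <- bt[bt$cell_id %in% names(events)[labels == p], , drop = FALSE]
      if (nrow(rows) >= 4)
        discover_groups(rows, k_max = cfg$k_max, seed = cfg$seed,
                        population_tag = p)
      else NULL
    })
    names(models) <- pops
    res$models <- models
    if (!is.null(models[[1]]) && !is.null(models[[2]]))
      res$matching <- match_groups(models[[1]], models[[2]], beta = cfg$beta)
    ref <- models[[which(!vapply(models, is.null, logical(1)))[1]]]
    if (!is.null(ref))
      res$labeled_blobs <- cbind(bt, assign_blobs(ref, bt))
  }
  class(res) <- "pipeline_result"
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d cell(s), %d blobs\n",
              length(x$cells),
              if (is.null(x$blob_table)) 0L else nrow(x$blob_table)))
  invisible(x)
}
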