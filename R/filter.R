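#' Filter parameters for random-graph-null noise removal
#'
#' @param T_filter proximity threshold (nm) at which the node measure is
#'   evaluated; default 80 nm, the mean of the thresholds at which degree
#'   measures discriminate the populations.
#' @param alpha non-negative multiplier on the null mean; default 4, the
#'   value at which retained degrees clear the tail of the random-graph
#'   degree histogram.
#' @param measure node measure used: `"uwDeg"` (unweighted degree, primary),
#'   `"wNDeg"` (weighted average neighbor degree; stricter, removes tiny
#'   clusters) or `"wCC"` (weighted clustering coefficient).
#' @param null_replicates number of random point sets pooled into the null
#'   mean (default 10).
#' @return list of class `filter_params`.
#' @export
filter_params <- function(T_filter = 80, alpha = 4,
                          measure = c("uwDeg", "wNDeg", "wCC"),
                          null_replicates = 10) {
  measure <- match.arg(measure)
  stopifnot(alpha >= 0, T_filter > 0, null_replicates >= 1)
  structure(list(T_filter = T_filter, alpha = alpha, measure = measure,
                 null_replicates = null_replicates), class = "filter_params")
}

node_measure_values <- function(points, T, measure) {
  g <- build_graph(points, T, mode = "weighted")
  nm <- node_measures(g)
  switch(measure,
         uwDeg = nm$degree,
         wNDeg = nm$wndeg,
         wCC = nm$wcc)
}

#' Remove noise-like localizations against a random-graph null
#'
#' Background labeling produces spatially random localizations whose network
#' properties match those of a random point cloud. For each ROI, a matched
#' random point set (same count; X/Y uniform over the ROI bounds, Z normal
#' fitted to the data; see [random_points_like()]) is generated
#' `null_replicates` times, the chosen node measure is evaluated on each
#' replicate's graph at `T_filter`, and its pooled mean defines the null
#' level. A node `i` is retained iff
#' `measure_i > alpha * mean(measure_null)`. Monomer-like isolated nodes are
#' removed by construction — the filter deliberately keeps only clustered
#' signal.
#'
#' @param roi a `roi` (or point set, wrapped via [as_roi()]).
#' @param params a [filter_params()].
#' @param seed integer seed for the null replicates.
#' @return a [localization_set()] of retained points, with attributes
#'   `retained_idx` (indices into the ROI's points), `null_mean` and
#'   `threshold_value` (`alpha * null_mean`).
#' @export
degree_filter <- function(roi, params = filter_params(), seed = 1) {
  roi <- as_roi(roi)
  n <- nrow(roi$points)
  if (n < 2) {
    warning("degree_filter: ROI too small for a null fit; passing through")
    out <- localization_set(roi$points, roi$merged_from)
    attr(out, "retained_idx") <- seq_len(n)
    attr(out, "null_mean") <- NA_real_
    attr(out, "threshold_value") <- NA_real_
    return(out)
  }
  obs <- node_measure_values(roi$points, params$T_filter, params$measure)
  null_vals <- unlist(lapply(seq_len(params$null_replicates), function(r) {
    rnd <- random_points_like(roi, seed = seed + r - 1L)
    node_measure_values(rnd, params$T_filter, params$measure)
  }))
  null_mean <- mean(null_vals)
  cutoff <- params$alpha * null_mean
  keep <- which(obs > cutoff)
  out <- localization_set(roi$points[keep, , drop = FALSE],
                          roi$merged_from[keep])
  attr(out, "retained_idx") <- keep
  attr(out, "null_mean") <- null_mean
  attr(out, "threshold_value") <- cutoff
  out
}
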