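#' Two-sided Mann-Whitney test between two feature samples
#'
#' Thin, contract-stable wrapper used for every (measure, threshold) cell of
#' the ROI feature comparison: exact U distribution for small samples without
#' ties, normal approximation with tie correction otherwise (the convention
#' of `stats::wilcox.test`). Missing values are dropped. If the pooled sample
#' is constant there is no evidence against the null and `p = 1` is returned.
#'
#' @param a,b numeric samples (non-empty after NA removal).
#' @return two-sided p-value.
#' @export
mw_test <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) == 0 || length(b) == 0)
    stop("mw_test: empty sample")
  if (length(unique(c(a, b))) == 1) return(1)
  suppressWarnings(stats::wilcox.test(a, b, alternative = "two.sided",
                                      exact = NULL, correct = TRUE)$p.value)
}

#' Combine per-experiment p-value matrices (L2-norm) and apply Bonferroni
#'
#' Replicate experiments each yield a 32 x 24 matrix of Mann-Whitney
#' p-values. The matrices are combined entrywise by the L2-norm
#' `sqrt(p1^2 + p2^2 + ...)`; any non-significant (large) p-value dominates
#' the norm, so a feature-threshold pair is only retained when it is
#' significant in *every* experiment — a deliberately conservative rule.
#' Significance is then declared where the combined value falls below the
#' Bonferroni-corrected level `alpha_sig / n_comparisons` with
#' `n_comparisons = 32 x 24 = 768` by default.
#'
#' @param p_per_experiment list of equal-shaped numeric matrices of p-values.
#' @param alpha_sig familywise significance level (default 0.05).
#' @param n_comparisons Bonferroni divisor (default: number of entries per
#'   matrix).
#' @return object of class `significance_map`: list with `p_combined`,
#'   `significant_mask`, `alpha_sig`, `n_comparisons`.
#' @export
aggregate_pvalues <- function(p_per_experiment, alpha_sig = 0.05,
                              n_comparisons = NULL) {
  stopifnot(length(p_per_experiment) >= 1)
  dims <- lapply(p_per_experiment, dim)
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1)
    stop("aggregate_pvalues: p-value matrices differ in shape")
  sq <- Reduce(`+`, lapply(p_per_experiment, function(p) p^2))
  combined <- sqrt(sq)
  if (is.null(n_comparisons)) n_comparisons <- length(combined)
  mask <- !is.na(combined) & combined < alpha_sig / n_comparisons
  structure(list(p_combined = combined, significant_mask = mask,
                 alpha_sig = alpha_sig, n_comparisons = n_comparisons),
            class = "significance_map")
}

#' Compare two populations of ROI feature vectors
#'
#' Convenience wrapper producing the per-experiment Mann-Whitney p-value
#' matrix for two populations of [roi_features()] results.
#'
#' @param fv_a,fv_b lists of [roi_features()] (one population each).
#' @return 32 x 24 matrix of two-sided p-values (`NA` where a cell has no
#'   usable data).
#' @export
population_pvalues <- function(fv_a, fv_b) {
  stopifnot(length(fv_a) > 0, length(fv_b) > 0)
  tmpl <- fv_a[[1]]
  p <- matrix(NA_real_, nrow(tmpl$values), ncol(tmpl$values),
              dimnames = dimnames(tmpl$values))
  arr_a <- simplify2array(lapply(fv_a, function(f) f$values))
  arr_b <- simplify2array(lapply(fv_b, function(f) f$values))
  for (i in seq_len(nrow(p))) for (j in seq_len(ncol(p))) {
    a <- arr_a[i, j, ]; b <- arr_b[i, j, ]
    a <- a[is.finite(a)]; b <- b[is.finite(b)]
    if (length(a) && length(b)) p[i, j] <- mw_test(a, b)
  }
  p
}

#' Random-forest leave-one-cell-out validation of ROI features
#'
#' For each proximity threshold, trains a random forest on the 32 registry
#' measures at that threshold and evaluates it with leave-one-cell-out
#' cross-validation: all ROIs of one cell are held out, the forest is trained
#' on the remaining cells' ROIs, and the held-out ROIs are predicted. ROI
#' accuracy is the fraction of correctly classified ROIs; cell accuracy
#' labels each cell with the majority vote of its ROI predictions.
#'
#' @param features data.frame from [features_table()] with added columns
#'   `label` (population, factor/character) and `cell_id`.
#' @param feature_subset optional character vector of registry measure names
#'   to restrict to (e.g. degree measures only).
#' @param thresholds thresholds (nm) to evaluate (default [threshold_grid()]).
#' @param n_trees trees per forest (default 500; lower for quick runs).
#' @param seed integer seed.
#' @return data.frame with columns `threshold`, `roi_accuracy`,
#'   `cell_accuracy`.
#' @export
rf_validate <- function(features, feature_subset = NULL,
                        thresholds = threshold_grid(), n_trees = 500,
                        seed = 1) {
  stopifnot(all(c("label", "cell_id") %in% names(features)))
  cells <- unique(features$cell_id)
  lab_of_cell <- vapply(cells, function(cl)
    as.character(features$label[features$cell_id == cl][1]), character(1))
  if (any(table(lab_of_cell) < 2))
    warning("rf_validate: fewer than 2 cells in a class; ",
            "leave-one-cell-out folds will lack that class")
  out <- data.frame(threshold = thresholds, roi_accuracy = NA_real_,
                    cell_accuracy = NA_real_)
  for (ti in seq_along(thresholds)) {
    Tt <- thresholds[ti]
    suffix <- paste0("@T", Tt)
    cols <- grep(suffix, names(features), fixed = TRUE, value = TRUE)
    if (!is.null(feature_subset))
      cols <- cols[sub("@.*$", "", cols) %in% feature_subset]
    X <- as.matrix(features[, cols, drop = FALSE])
    y <- as.character(features$label)
    roi_ok <- c(); cell_ok <- c()
    for (ci in seq_along(cells)) {
      test <- features$cell_id == cells[ci]
      Xtr <- X[!test, , drop = FALSE]; ytr <- y[!test]
      Xte <- X[test, , drop = FALSE]
      # impute per-column training medians into missing entries
      med <- apply(Xtr, 2, function(v) stats::median(v, na.rm = TRUE))
      med[!is.finite(med)] <- 0
      for (cidx in seq_len(ncol(Xtr))) {
        Xtr[!is.finite(Xtr[, cidx]), cidx] <- med[cidx]
        Xte[!is.finite(Xte[, cidx]), cidx] <- med[cidx]
      }
      fit <- rf_fit(Xtr, ytr, n_trees = n_trees,
                    seed = seed + 1000L * ti + ci)
      pred <- rf_predict(fit, Xte)
      roi_ok <- c(roi_ok, pred == y[test])
      vote <- names(sort(table(pred), decreasing = TRUE))[1]
      cell_ok <- c(cell_ok, vote == lab_of_cell[ci])
    }
    out$roi_accuracy[ti] <- mean(roi_ok)
    out$cell_accuracy[ti] <- mean(cell_ok)
  }
  out
}
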