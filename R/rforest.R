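# Compact random forest (bagged CART with random feature subsets).
#
# No random-forest package ships with the target environment, and the
# classification problems here are small (tens to hundreds of rows, <= 32
# features per threshold), so a plain R implementation is adequate: Gini
# impurity, midpoint split candidates, bootstrap resampling, majority vote.

grow_tree <- function(X, y, classes, mtry, min_node, max_depth) {
  nodes <- list()
  build <- function(idx, depth) {
    id <- length(nodes) + 1L
    ytab <- tabulate(match(y[idx], classes), length(classes))
    pred <- classes[which.max(ytab)]
    leaf <- list(leaf = TRUE, pred = pred)
    if (depth >= max_depth || length(idx) < 2 * min_node ||
        sum(ytab > 0) == 1) {
      nodes[[id]] <<- leaf
      return(id)
    }
    feats <- sample.int(ncol(X), min(mtry, ncol(X)))
    best <- list(gain = 0)
    n <- length(idx)
    gini <- function(tab) 1 - sum((tab / max(sum(tab), 1))^2)
    g0 <- gini(ytab)
    for (f in feats) {
      v <- X[idx, f]
      uq <- sort(unique(v))
      if (length(uq) < 2) next
      cuts <- (uq[-1] + uq[-length(uq)]) / 2
      if (length(cuts) > 16)           # cap candidate splits for speed
        cuts <- stats::quantile(v, probs = seq(0.05, 0.95, length.out = 16),
                                names = FALSE, type = 1)
      for (cut in unique(cuts)) {
        left <- v <= cut
        nl <- sum(left)
        if (nl < min_node || n - nl < min_node) next
        tl <- tabulate(match(y[idx[left]], classes), length(classes))
        tr <- ytab - tl
        gain <- g0 - (nl / n) * gini(tl) - ((n - nl) / n) * gini(tr)
        if (gain > best$gain + 1e-12)
          best <- list(gain = gain, f = f, cut = cut, left = left)
      }
    }
    if (best$gain <= 0) {
      nodes[[id]] <<- leaf
      return(id)
    }
    nodes[[id]] <<- list(leaf = FALSE, f = best$f, cut = best$cut,
                         left = NA_integer_, right = NA_integer_,
                         pred = pred)
    lid <- build(idx[best$left], depth + 1L)
    rid <- build(idx[!best$left], depth + 1L)
    nodes[[id]]$left <<- lid
    nodes[[id]]$right <<- rid
    id
  }
  root <- build(seq_len(nrow(X)), 0L)
  list(nodes = nodes, root = root)
}

predict_tree <- function(tree, X) {
  vapply(seq_len(nrow(X)), function(r) {
    id <- tree$root
    repeat {
      nd <- tree$nodes[[id]]
      if (nd$leaf) return(nd$pred)
      id <- if (X[r, nd$f] <= nd$cut) nd$left else nd$right
    }
  }, character(1))
}

#' Fit a random forest classifier
#'
#' @param X numeric matrix (rows = samples).
#' @param y class labels (character/factor).
#' @param n_trees number of trees (default 500).
#' @param mtry features sampled per split (default `floor(sqrt(ncol(X)))`).
#' @param min_node minimum samples per leaf (default 1).
#' @param max_depth maximum tree depth (default 12).
#' @param seed integer seed.
#' @return object of class `rf_model`.
#' @export
rf_fit <- function(X, y, n_trees = 500, mtry = NULL, min_node = 1,
                   max_depth = 12, seed = 1) {
  X <- as.matrix(X); y <- as.character(y)
  stopifnot(nrow(X) == length(y), nrow(X) >= 2)
  classes <- sort(unique(y))
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(X))))
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  trees <- vector("list", n_trees)
  for (t in seq_len(n_trees)) {
    boot <- sample.int(nrow(X), nrow(X), replace = TRUE)
    trees[[t]] <- grow_tree(X[boot, , drop = FALSE], y[boot], classes,
                            mtry, min_node, max_depth)
  }
  structure(list(trees = trees, classes = classes), class = "rf_model")
}

#' Predict with a random forest
#'
#' @param model an [rf_fit()] result.
#' @param X numeric matrix of samples to classify.
#' @return character vector of majority-vote class labels.
#' @export
rf_predict <- function(model, X) {
  X <- as.matrix(X)
  votes <- matrix(0L, nrow(X), length(model$classes),
                  dimnames = list(NULL, model$classes))
  for (tree in model$trees) {
    p <- predict_tree(tree, X)
    for (k in seq_along(model$classes))
      votes[, k] <- votes[, k] + (p == model$classes[k])
  }
  model$classes[max.col(votes, ties.method = "first")]
}
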