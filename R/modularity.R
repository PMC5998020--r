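#' Newman leading-eigenvector module detection
#'
#' Finds a high-modularity partition of a graph into modules (communities) by
#' recursive spectral bisection of the modularity matrix
#' `B = A - k k' / 2m` (weighted graphs use edge weights and strengths).
#' Connected components are the initial communities; each is repeatedly split
#' along the sign pattern of the leading eigenvector of its generalized
#' modularity matrix, with a Kernighan-Lin-style vertex-flipping refinement
#' after every split, and a split is accepted only while it increases the
#' modularity contribution. Modularity of the returned assignment is
#'
#' `Q = sum_c [ W_c / m - (K_c / 2m)^2 ]`
#'
#' with `W_c` the total within-module edge weight and `K_c` the total degree
#' (strength) of module `c`.
#'
#' A graph with nodes but no edges has undefined modularity; it is returned
#' as one module per node with `Q = 0` and `degenerate = TRUE`.
#'
#' @param g a [build_graph()] result; its `mode` selects weighted vs
#'   unweighted modularity.
#' @param tol positive-split tolerance on the eigenvector contribution.
#' @return list of class `module_partition`: `assignment` (integer module id
#'   per node), `Q`, `n_modules`, `degenerate`.
#' @export
newman_partition <- function(g, tol = 1e-9) {
  n <- g$n
  if (n == 0) stop("newman_partition: empty graph")
  e <- g$edges
  wt <- if (g$mode == "weighted") e$w else rep(1, nrow(e))
  if (nrow(e) == 0) {
    return(structure(list(assignment = seq_len(n), Q = 0,
                          n_modules = n, degenerate = TRUE),
                     class = "module_partition"))
  }
  k <- numeric(n)
  acc <- rowsum(c(wt, wt), c(e$i, e$j))
  k[as.integer(rownames(acc))] <- acc[, 1]
  m2 <- sum(k)                       # 2m

  # adjacency rows as index/weight lists for subgraph extraction
  adj_i <- split(c(e$j, e$i), c(e$i, e$j))
  adj_w <- split(c(wt, wt), c(e$i, e$j))

  Bsub <- function(S) {
    # generalized modularity matrix of community S (dense)
    ns <- length(S)
    pos <- integer(n); pos[S] <- seq_len(ns)
    A <- matrix(0, ns, ns)
    for (a in seq_len(ns)) {
      v <- S[a]
      key <- as.character(v)
      nb <- adj_i[[key]]
      if (!is.null(nb)) {
        inS <- pos[nb] > 0L
        if (any(inS)) A[a, pos[nb[inS]]] <- adj_w[[key]][inS]
      }
    }
    B <- A - tcrossprod(k[S]) / m2
    diag(B) <- diag(B) - rowSums(B)
    B
  }

  leading_eig <- function(B) {
    ns <- nrow(B)
    if (ns <= 400) {
      es <- eigen(B, symmetric = TRUE)
      return(list(value = es$values[1], vector = es$vectors[, 1]))
    }
    shift <- max(rowSums(abs(B)))    # Gershgorin bound: B + shift*I is PSD
    v <- sin(seq_len(ns))            # deterministic, generic start
    v <- v / sqrt(sum(v^2))
    for (it in 1:1000) {
      u <- B %*% v + shift * v
      nu <- sqrt(sum(u^2))
      if (nu == 0) break
      u <- as.numeric(u / nu)
      if (sum((u - v)^2) < 1e-16) { v <- u; break }
      v <- u
    }
    list(value = sum(v * (B %*% v)), vector = v)
  }

  assignment <- integer(n)
  next_id <- 0L

  subdivide <- function(S) {
    if (length(S) == 1) {
      next_id <<- next_id + 1L
      assignment[S] <<- next_id
      return(invisible(NULL))
    }
    B <- Bsub(S)
    le <- leading_eig(B)
    s <- ifelse(le$vector >= 0, 1, -1)
    if (le$value > tol && length(unique(s)) == 2) {
      # refinement: greedily flip vertices while s' B s improves
      Bs <- as.numeric(B %*% s)
      repeat {
        gains <- -4 * s * Bs + 4 * diag(B)
        # a flip emptying one side is not a split; forbid it
        for (side in c(-1, 1))
          if (sum(s == side) == 1) gains[s == side] <- -Inf
        best <- which.max(gains)
        if (gains[best] <= tol) break
        Bs <- Bs - 2 * s[best] * B[, best]
        s[best] <- -s[best]
      }
      dq <- sum(s * (B %*% s))
      if (dq > tol && length(unique(s)) == 2) {
        subdivide(S[s > 0])
        subdivide(S[s < 0])
        return(invisible(NULL))
      }
    }
    next_id <<- next_id + 1L
    assignment[S] <<- next_id
    invisible(NULL)
  }

  comp <- igraph::components(as_igraph(g))
  for (cid in seq_len(comp$no)) subdivide(which(comp$membership == cid))

  structure(list(assignment = assignment,
                 Q = modularity_score(g, assignment),
                 n_modules = length(unique(assignment)),
                 degenerate = FALSE),
            class = "module_partition")
}

#' Modularity of a given node-to-module assignment
#'
#' @param g a [build_graph()] result.
#' @param assignment integer module id per node.
#' @return modularity `Q` (0 for an edgeless graph).
#' @export
modularity_score <- function(g, assignment) {
  e <- g$edges
  if (nrow(e) == 0) return(0)
  wt <- if (g$mode == "weighted") e$w else rep(1, nrow(e))
  n <- g$n
  k <- numeric(n)
  acc <- rowsum(c(wt, wt), c(e$i, e$j))
  k[as.integer(rownames(acc))] <- acc[, 1]
  m2 <- sum(k)
  within <- assignment[e$i] == assignment[e$j]
  W_in <- tapply(wt[within], assignment[e$i][within], sum)
  K_c <- tapply(k, assignment, sum)
  Q <- sum(2 * W_in / m2) + sum(-(K_c / m2)^2)
  if (length(W_in) == 0) Q <- sum(-(K_c / m2)^2)
  Q
}
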