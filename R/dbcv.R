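# Kruskal's algorithm with lexicographic tie-breaking on (weight, i, j).
# Mutual-reachability graphs are full of exact ties (many pairs share a
# dominating core distance), so the MST topology -- and with it the internal
# node set -- is only well defined once a tie rule is fixed.
kruskal_mst_lex <- function(M) {
  n <- nrow(M)
  ut <- which(upper.tri(M), arr.ind = TRUE)
  w <- M[ut]
  ord <- order(w, ut[, 1], ut[, 2])
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  edges <- matrix(0, n - 1L, 3L)
  e <- 0L
  for (r in ord) {
    a <- find(ut[r, 1]); b <- find(ut[r, 2])
    if (a != b) {
      e <- e + 1L
      edges[e, ] <- c(ut[r, 1], ut[r, 2], w[r])
      parent[a] <- b
      if (e == n - 1L) break
    }
  }
  edges
}

#' Density-based clustering validation (DBCV) index
#'
#' Scores a flat clustering by the density structure it induces: for every
#' cluster, the all-points core distance defines a mutual-reachability
#' distance; the maximum internal edge of its mutual-reachability minimum
#' spanning tree measures density sparseness within the cluster (DSC), and
#' the minimum mutual-reachability distance between internal nodes of two
#' clusters measures their density separation (DSPC). Each cluster's
#' validity is `(min DSPC - DSC) / max(min DSPC, DSC)` and the index is the
#' size-weighted sum over clusters, weighted by the total sample count, so
#' noise points lower the score through the weighting only. Range [-1, 1];
#' higher is denser and better separated.
#'
#' Mutual-reachability distances tie frequently (many pairs share a
#' dominating core distance), which would leave the spanning tree -- and the
#' internal-edge maximum -- ambiguous; the tree is therefore built with a
#' fixed lexicographic tie rule on (weight, i, j), making the score fully
#' deterministic.
#'
#' @param points Numeric n x d matrix (the space the labels were produced in).
#' @param labels Integer labels, `-1` = noise.
#' @return The DBCV score, or `NA` (an undefined score, e.g. fewer than two
#'   clusters of size >= 2; ranked below every defined score in grid search).
#' @export
dbcv <- function(points, labels) {
  points <- as.matrix(points)
  n_total <- length(labels)
  stopifnot(nrow(points) == n_total, n_total >= 1)
  ids <- sort(unique(labels[labels >= 0L]))
  ids <- ids[vapply(ids, function(k) sum(labels == k) >= 2L, logical(1))]
  if (length(ids) < 2L) return(NA_real_)
  d_dim <- ncol(points)

  members <- lapply(ids, function(k) which(labels == k))
  acore <- vector("list", length(ids))
  internal <- vector("list", length(ids))
  dsc <- numeric(length(ids))

  for (ci in seq_along(ids)) {
    idx <- members[[ci]]
    P <- points[idx, , drop = FALSE]
    Dm <- as.matrix(stats::dist(P))
    ni <- length(idx)
    inv_pow <- (1 / Dm)^d_dim
    diag(inv_pow) <- 0
    acore[[ci]] <- (rowSums(inv_pow) / (ni - 1))^(-1 / d_dim)
    mr <- pmax(Dm, outer(acore[[ci]], acore[[ci]], pmax))
    diag(mr) <- 0
    edges <- kruskal_mst_lex(mr)
    deg <- tabulate(c(edges[, 1], edges[, 2]), nbins = ni)
    int_nodes <- which(deg >= 2L)
    if (length(int_nodes) == 0L) int_nodes <- seq_len(ni)  # size-2 cluster
    internal[[ci]] <- idx[int_nodes]
    int_edge <- edges[, 1] %in% int_nodes & edges[, 2] %in% int_nodes
    dsc[ci] <- if (any(int_edge)) max(edges[int_edge, 3]) else max(edges[, 3])
  }

  acore_flat <- numeric(n_total)
  for (ci in seq_along(ids)) acore_flat[members[[ci]]] <- acore[[ci]]

  validity <- numeric(length(ids))
  for (ci in seq_along(ids)) {
    sep <- Inf
    for (cj in seq_along(ids)) {
      if (cj == ci) next
      u <- internal[[ci]]; v <- internal[[cj]]
      Dcross <- cross_dist(points[u, , drop = FALSE], points[v, , drop = FALSE])
      mr <- pmax(Dcross, outer(acore_flat[u], acore_flat[v], pmax))
      sep <- min(sep, min(mr))
    }
    denom <- max(sep, dsc[ci])
    validity[ci] <- if (denom > 0) (sep - dsc[ci]) / denom else 0
  }
  sum(lengths(members) / n_total * validity)
}

# Euclidean cross-distance matrix between two point sets.
cross_dist <- function(A, B) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d2 <- outer(an, bn, `+`) - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  sqrt(d2)
}
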