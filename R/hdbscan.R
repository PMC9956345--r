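#' HDBSCAN hyper-parameters
#'
#' @param min_cluster_size Minimum members for a group to count as a cluster
#'   (>= 2); smaller density peaks are dissolved into their parents or noise.
#' @param min_samples Neighborhood size k for the core distance (distance to
#'   the k-th nearest neighbour, the point itself included); controls how
#'   conservative the density estimate is (>= 1).
#' @param metric Distance in the clustered space: `"euclidean"` or
#'   `"manhattan"`.
#' @param cluster_selection_method How flat clusters are cut from the cluster
#'   hierarchy: `"eom"` (excess of mass, default) or `"leaf"`.
#' @return A `cluster_params` list.
#' @export
cluster_params <- function(min_cluster_size, min_samples = 5,
                           metric = c("euclidean", "manhattan"),
                           cluster_selection_method = c("eom", "leaf")) {
  metric <- match.arg(metric)
  cluster_selection_method <- match.arg(cluster_selection_method)
  if (min_cluster_size < 2) stop("min_cluster_size must be >= 2")
  if (min_samples < 1) stop("min_samples must be >= 1")
  structure(list(min_cluster_size = as.integer(min_cluster_size),
                 min_samples = as.integer(min_samples),
                 metric = metric,
                 cluster_selection_method = cluster_selection_method),
            class = "cluster_params")
}

# Prim's algorithm on a full symmetric weight matrix; returns a (n-1) x 3
# matrix of edges (from, to, weight).
prim_mst <- function(M) {
  n <- nrow(M)
  in_tree <- logical(n)
  best_w <- rep(Inf, n)
  best_from <- integer(n)
  in_tree[1] <- TRUE
  best_w_upd <- M[1, ]
  upd <- best_w_upd < best_w
  best_w[upd] <- best_w_upd[upd]; best_from[upd] <- 1L
  best_w[1] <- Inf
  edges <- matrix(0, n - 1L, 3L)
  for (e in seq_len(n - 1L)) {
    v <- which.min(best_w)
    edges[e, ] <- c(best_from[v], v, best_w[v])
    in_tree[v] <- TRUE
    best_w[v] <- Inf
    w_v <- M[v, ]
    upd <- !in_tree & w_v < best_w
    best_w[upd] <- w_v[upd]; best_from[upd] <- v
  }
  edges
}

# Single-linkage merge tree from MST edges. Leaves are 1..n; internal nodes
# n+1 .. 2n-1 in order of increasing merge distance. Returns per internal
# node: children ids and merge height.
single_linkage_tree <- function(edges, n) {
  ord <- order(edges[, 3])
  parent <- seq_len(2L * n - 1L)          # union-find with current root node
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  child1 <- integer(n - 1L); child2 <- integer(n - 1L); height <- numeric(n - 1L)
  nxt <- n
  for (k in ord) {
    a <- find(edges[k, 1]); b <- find(edges[k, 2])
    nxt <- nxt + 1L
    child1[nxt - n] <- a; child2[nxt - n] <- b; height[nxt - n] <- edges[k, 3]
    parent[a] <- nxt; parent[b] <- nxt
  }
  list(child1 = child1, child2 = child2, height = height, n = n)
}

# Condense the single-linkage tree: clusters smaller than min_cluster_size
# fall out of their parent as points. Returns the condensed tree as parallel
# vectors (rows are either point rows, child <= n, or cluster rows) plus the
# number of condensed clusters. Cluster ids: 1 = root.
condense_tree <- function(sl, min_cluster_size) {
  n <- sl$n
  node_size <- c(rep(1L, n), integer(n - 1L))
  for (m in seq_len(n - 1L))
    node_size[n + m] <- node_size[sl$child1[m]] + node_size[sl$child2[m]]

  # iterative collection of all leaf points under a node
  points_under <- function(node) {
    out <- integer(0); stack <- node
    while (length(stack)) {
      v <- stack[[length(stack)]]; stack <- stack[-length(stack)]
      if (v <= n) out <- c(out, v)
      else stack <- c(stack, sl$child1[v - n], sl$child2[v - n])
    }
    out
  }

  par_v <- integer(0); child_v <- integer(0); lam_v <- numeric(0); size_v <- integer(0)
  add_row <- function(p, c, l, s) {
    par_v[length(par_v) + 1L] <<- p
    child_v[length(child_v) + 1L] <<- c
    lam_v[length(lam_v) + 1L] <<- l
    size_v[length(size_v) + 1L] <<- s
  }

  n_clusters <- 1L
  # stack of (tree node, condensed cluster id it belongs to)
  stack <- list(c(2L * n - 1L, 1L))
  while (length(stack)) {
    top <- stack[[length(stack)]]; stack <- stack[-length(stack)]
    node <- top[1]; clus <- top[2]
    if (node <= n) next
    m <- node - n
    lam <- if (sl$height[m] > 0) 1 / sl$height[m] else Inf
    kids <- c(sl$child1[m], sl$child2[m])
    sizes <- node_size[kids]
    big <- sizes >= min_cluster_size
    if (all(big)) {
      for (kid in kids) {
        n_clusters <- n_clusters + 1L
        add_row(clus, n + n_clusters, lam, node_size[kid])  # cluster row (child > n marks cluster id child-n)
        stack[[length(stack) + 1L]] <- c(kid, n_clusters)
      }
    } else {
      for (kk in seq_along(kids)) {
        kid <- kids[kk]
        if (big[kk]) {
          stack[[length(stack) + 1L]] <- c(kid, clus)
        } else {
          for (p in points_under(kid)) add_row(clus, p, lam, 1L)
        }
      }
    }
  }
  list(parent = par_v, child = child_v, lambda = lam_v, size = size_v,
       n_points = n, n_clusters = n_clusters)
}

# Stability of each condensed cluster: sum over rows with that parent of
# (lambda - lambda_birth(parent)) * size, finite-capped.
condensed_stability <- function(ct) {
  births <- rep(0, ct$n_clusters)
  cl_rows <- ct$child > ct$n_points
  births[ct$child[cl_rows] - ct$n_points] <- ct$lambda[cl_rows]
  lam <- ct$lambda
  lam[!is.finite(lam)] <- max(c(1, lam[is.finite(lam)])) * 2  # cap Inf (duplicate points)
  stab <- numeric(ct$n_clusters)
  for (r in seq_along(ct$parent)) {
    p <- ct$parent[r]
    stab[p] <- stab[p] + (lam[r] - births[p]) * ct$size[r]
  }
  stab
}

select_clusters <- function(ct, method) {
  nc <- ct$n_clusters
  cl_rows <- which(ct$child > ct$n_points)
  kids_of <- split(ct$child[cl_rows] - ct$n_points, ct$parent[cl_rows])
  children <- vector("list", nc)
  children[as.integer(names(kids_of))] <- kids_of
  is_leaf <- vapply(children, function(k) length(k) == 0L, logical(1))
  if (nc == 1L) return(integer(0))           # no split survived: everything noise
  if (method == "leaf") return(which(is_leaf & seq_len(nc) != 1L))
  stab <- condensed_stability(ct)
  subtree <- numeric(nc); selected <- logical(nc)
  for (cl in rev(seq_len(nc))) {             # children have larger ids: bottom-up
    if (is_leaf[cl]) { subtree[cl] <- stab[cl]; selected[cl] <- TRUE; next }
    kid_sum <- sum(subtree[children[[cl]]])
    if (cl == 1L) { subtree[cl] <- kid_sum; next }   # root never eligible
    if (stab[cl] >= kid_sum) { subtree[cl] <- stab[cl]; selected[cl] <- TRUE }
    else subtree[cl] <- kid_sum
  }
  # highest selected nodes win; prune selected descendants
  final <- integer(0)
  stack <- children[[1]]
  while (length(stack)) {
    cl <- stack[[1]]; stack <- stack[-1]
    if (selected[cl]) final <- c(final, cl)
    else stack <- c(stack, children[[cl]])
  }
  sort(final)
}

#' Cluster points with HDBSCAN
#'
#' Hierarchical density-based clustering: core distances at `min_samples`
#' neighbours define a mutual-reachability distance, whose minimum spanning
#' tree yields a single-linkage hierarchy; the hierarchy is condensed at
#' `min_cluster_size` and flat clusters are selected by excess of mass or at
#' the leaves. Points in no selected cluster are labelled `-1` (noise). The
#' implementation is deterministic for fixed input.
#'
#' @param points Numeric n x d matrix.
#' @param params A [cluster_params()].
#' @return Integer vector of length n: cluster labels `0 .. k-1`, `-1` for
#'   noise; attribute `n_clusters` = k.
#' @export
hdbscan_cluster <- function(points, params) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < params$min_cluster_size) {
    warning("n (", n, ") < min_cluster_size (", params$min_cluster_size,
            "): all points labelled noise")
    return(structure(rep(-1L, n), n_clusters = 0L))
  }
  if (params$min_samples > n) stop("min_samples exceeds number of points")
  D <- as.matrix(stats::dist(points, method = params$metric))
  core <- apply(D, 1, function(r) sort(r)[params$min_samples])
  M <- pmax(D, outer(core, core, pmax))
  diag(M) <- 0
  edges <- prim_mst(M)
  sl <- single_linkage_tree(edges, n)
  ct <- condense_tree(sl, params$min_cluster_size)
  chosen <- select_clusters(ct, params$cluster_selection_method)

  labels <- rep(-1L, n)
  if (length(chosen)) {
    # map each condensed cluster to its selected ancestor-or-self (if any)
    parent_of <- rep(NA_integer_, ct$n_clusters)
    cl_rows <- which(ct$child > ct$n_points)
    parent_of[ct$child[cl_rows] - ct$n_points] <- ct$parent[cl_rows]
    sel_anc <- rep(NA_integer_, ct$n_clusters)
    for (cl in seq_len(ct$n_clusters)) {
      v <- cl
      while (!is.na(v)) {
        if (v %in% chosen) { sel_anc[cl] <- v; break }
        v <- parent_of[v]
      }
    }
    lab_of <- stats::setNames(seq_along(chosen) - 1L, chosen)
    pt_rows <- which(ct$child <= ct$n_points)
    for (r in pt_rows) {
      anc <- sel_anc[ct$parent[r]]
      if (!is.na(anc)) labels[ct$child[r]] <- lab_of[[as.character(anc)]]
    }
  }
  structure(labels, n_clusters = length(unique(labels[labels >= 0L])))
}

#' Number of non-noise clusters in a label vector
#'
#' @param labels Integer labels with `-1` as noise.
#' @return Integer count of distinct non-negative labels.
#' @export
n_clusters <- function(labels) length(unique(labels[labels >= 0L]))
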