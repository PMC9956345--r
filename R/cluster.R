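#' UMAP reduction parameters
#'
#' Defaults follow the reference analysis: 15 neighbours, 5 output
#' components, cosine distance.
#'
#' @param n_neighbors Local neighbourhood size (>= 2).
#' @param n_components Output dimensionality.
#' @param metric Input-space metric (default `"cosine"`).
#' @param seed Integer seed; with single-threaded execution this makes the
#'   projection deterministic.
#' @return A `reduction_params` list.
#' @export
reduction_params <- function(n_neighbors = 15, n_components = 5,
                             metric = "cosine", seed = 1L) {
  if (n_neighbors < 2) stop("n_neighbors must be >= 2")
  structure(list(n_neighbors = as.integer(n_neighbors),
                 n_components = as.integer(n_components),
                 metric = metric, seed = as.integer(seed)),
            class = "reduction_params")
}

#' Project a latent matrix with UMAP
#'
#' Reduces the n x 64 latent matrix to `n_components` dimensions (5 before
#' clustering; 2 for display coordinates) with uniform manifold approximation
#' and projection. Runs single-threaded under the configured seed, so
#' repeated calls are identical.
#'
#' @param latent Numeric matrix, individuals in rows.
#' @param p A [reduction_params()].
#' @return n x `n_components` matrix with the input rownames.
#' @export
umap_project <- function(latent, p = reduction_params()) {
  latent <- as.matrix(latent)
  if (nrow(latent) <= p$n_neighbors)
    stop("n (", nrow(latent), ") must exceed n_neighbors (", p$n_neighbors,
         "); use a smaller n_neighbors")
  if (p$n_components >= ncol(latent))
    stop("n_components must be below the latent dimensionality")
  out <- uwot::umap(latent, n_neighbors = p$n_neighbors,
                    n_components = p$n_components, metric = p$metric,
                    seed = p$seed, n_threads = 1, n_sgd_threads = 0,
                    batch = TRUE)
  rownames(out) <- rownames(latent)
  out
}

#' Clustering coverage
#'
#' Fraction of samples assigned to any cluster: 1 means no sample was marked
#' as noise; low values signal poorly clusterable data.
#'
#' @param labels Integer labels with `-1` = noise.
#' @return Numeric in [0, 1].
#' @export
coverage <- function(labels) {
  if (length(labels) == 0) stop("coverage needs at least one sample")
  sum(labels != -1L) / length(labels)
}

#' Grid of HDBSCAN hyper-parameters
#'
#' @param min_cluster_size,min_samples Integer vectors of candidate values.
#' @param metric Character vector from \{"euclidean", "manhattan"\}.
#' @param cluster_selection_method Character vector from \{"eom", "leaf"\}.
#' @return A `cluster_grid` data.frame, one row per combination (full
#'   Cartesian product, in grid order).
#' @export
cluster_grid <- function(min_cluster_size, min_samples = c(5L, 10L),
                         metric = c("euclidean", "manhattan"),
                         cluster_selection_method = c("eom", "leaf")) {
  g <- expand.grid(min_cluster_size = as.integer(min_cluster_size),
                   min_samples = as.integer(min_samples),
                   metric = metric,
                   cluster_selection_method = cluster_selection_method,
                   stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  class(g) <- c("cluster_grid", "data.frame")
  g
}

#' Exhaustive HDBSCAN grid search scored by DBCV
#'
#' Evaluates every parameter combination on the full data and scores each
#' flat clustering with [dbcv()] (DBCV is the sole selection metric;
#' coverage is recorded alongside). By default DBCV is computed with
#' Euclidean distance in the projected space for every cell, so scores are
#' comparable across metrics under evaluation; set
#' `dbcv_metric = "cluster"` to score each cell in its own HDBSCAN metric.
#' The winner is the maximum DBCV; ties break by higher coverage, then
#' larger `min_cluster_size`, then grid order. Undefined DBCV (degenerate
#' clusterings) ranks below every defined score.
#'
#' @param points Numeric n x d matrix (the reduced space).
#' @param grid A [cluster_grid()] (non-empty).
#' @param dbcv_metric `"euclidean"` (fixed yardstick, default) or
#'   `"cluster"`.
#' @return List with `best_labels` (labels of the winning cell, attribute
#'   `params`), `best_params` and `results` (data.frame: one row per
#'   combination with `dbcv`, `coverage`, `n_clusters`).
#' @export
grid_search <- function(points, grid, dbcv_metric = c("euclidean", "cluster")) {
  dbcv_metric <- match.arg(dbcv_metric)
  if (!nrow(grid)) stop("empty parameter grid")
  points <- as.matrix(points)
  res <- grid
  res$dbcv <- NA_real_
  res$coverage <- NA_real_
  res$n_clusters <- NA_integer_
  labels_list <- vector("list", nrow(grid))
  for (r in seq_len(nrow(grid))) {
    p <- cluster_params(grid$min_cluster_size[r], grid$min_samples[r],
                        grid$metric[r], grid$cluster_selection_method[r])
    lab <- suppressWarnings(hdbscan_cluster(points, p))
    labels_list[[r]] <- lab
    score_pts <- points
    if (dbcv_metric == "cluster" && p$metric == "manhattan") {
      res$dbcv[r] <- dbcv_with_metric(points, lab, "manhattan")
    } else {
      res$dbcv[r] <- dbcv(score_pts, lab)
    }
    res$coverage[r] <- coverage(lab)
    res$n_clusters[r] <- n_clusters(lab)
  }
  if (all(is.na(res$dbcv)))
    stop(paste0("every grid combination produced an undefined DBCV; ",
                "grid table:\n",
                paste(utils::capture.output(print(res)), collapse = "\n")))
  key <- order(ifelse(is.na(res$dbcv), -Inf, res$dbcv),
               res$coverage, res$min_cluster_size,
               -seq_len(nrow(res)), decreasing = TRUE)
  best <- key[1]
  best_params <- cluster_params(grid$min_cluster_size[best],
                                grid$min_samples[best],
                                grid$metric[best],
                                grid$cluster_selection_method[best])
  best_labels <- labels_list[[best]]
  attr(best_labels, "params") <- best_params
  list(best_labels = best_labels, best_params = best_params,
       best_index = best, results = res)
}

# DBCV under a non-Euclidean point-space metric (used when the grid is scored
# in each cell's own HDBSCAN metric rather than the fixed yardstick).
dbcv_with_metric <- function(points, labels, metric) {
  if (metric == "euclidean") return(dbcv(points, labels))
  # Manhattan scoring via the same formulas with L1 distances: embed by
  # overriding the distance computations through a local copy.
  dbcv_l1(points, labels)
}

dbcv_l1 <- function(points, labels) {
  points <- as.matrix(points)
  n_total <- length(labels)
  ids <- sort(unique(labels[labels >= 0L]))
  ids <- ids[vapply(ids, function(k) sum(labels == k) >= 2L, logical(1))]
  if (length(ids) < 2L) return(NA_real_)
  d_dim <- ncol(points)
  members <- lapply(ids, function(k) which(labels == k))
  acore <- vector("list", length(ids))
  internal <- vector("list", length(ids))
  dsc <- numeric(length(ids))
  l1_cross <- function(A, B)
    apply(B, 1, function(b) colSums(abs(t(A) - b)))
  for (ci in seq_along(ids)) {
    idx <- members[[ci]]
    P <- points[idx, , drop = FALSE]
    Dm <- as.matrix(stats::dist(P, method = "manhattan"))
    ni <- length(idx)
    inv_pow <- (1 / Dm)^d_dim
    diag(inv_pow) <- 0
    acore[[ci]] <- (rowSums(inv_pow) / (ni - 1))^(-1 / d_dim)
    mr <- pmax(Dm, outer(acore[[ci]], acore[[ci]], pmax))
    diag(mr) <- 0
    edges <- kruskal_mst_lex(mr)
    deg <- tabulate(c(edges[, 1], edges[, 2]), nbins = ni)
    int_nodes <- which(deg >= 2L)
    if (length(int_nodes) == 0L) int_nodes <- seq_len(ni)
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
      Dcross <- matrix(l1_cross(points[u, , drop = FALSE],
                                points[v, , drop = FALSE]),
                       nrow = length(u))
      mr <- pmax(Dcross, outer(acore_flat[u], acore_flat[v], pmax))
      sep <- min(sep, min(mr))
    }
    denom <- max(sep, dsc[ci])
    validity[ci] <- if (denom > 0) (sep - dsc[ci]) / denom else 0
  }
  sum(lengths(members) / n_total * validity)
}

#' Per-cluster gene sets and census
#'
#' For each non-noise cluster: member count, the union of member gene sets,
#' the distinct-gene count, and (if an ASD-linked list is supplied) the size
#' of the intersection with it. Noise individuals contribute to no cluster.
#'
#' @param labels Integer labels aligned with `sets`.
#' @param sets An `individual_gene_sets` object (same order as `labels`).
#' @param events Optional `variant_events` table restricted to the same
#'   individuals; adds a per-cluster variant-event count to the census.
#' @param asd_list Optional character vector of ASD-linked gene symbols.
#' @return List with `gene_sets` (list of character vectors, one per
#'   cluster, named by label) and `census` (data.frame: cluster, individuals,
#'   genes, and optionally variants, asd_linked_genes).
#' @export
cluster_gene_sets <- function(labels, sets, events = NULL, asd_list = NULL) {
  if (length(labels) != length(sets))
    stop("labels (", length(labels), ") and gene sets (", length(sets),
         ") are not aligned")
  ids <- sort(unique(labels[labels >= 0L]))
  gene_sets <- lapply(ids, function(k)
    sort(unique(unlist(sets[labels == k], use.names = FALSE))))
  names(gene_sets) <- ids
  census <- data.frame(cluster = ids,
                       individuals = vapply(ids, function(k) sum(labels == k), integer(1)),
                       genes = lengths(gene_sets))
  if (!is.null(events)) {
    ev_by_ind <- table(factor(events$individual_id, levels = names(sets)))
    census$variants <- vapply(ids, function(k)
      sum(ev_by_ind[labels == k]), numeric(1))
  }
  if (!is.null(asd_list)) {
    asd_list <- norm_symbol(asd_list)
    census$asd_linked_genes <- vapply(gene_sets, function(g)
      length(intersect(g, asd_list)), integer(1))
  }
  list(gene_sets = gene_sets, census = census)
}
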