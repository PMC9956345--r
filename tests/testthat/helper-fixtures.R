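# Shared fixture builders and independent oracles for the test suite.

# Tiny embedding with hand-set vectors.
toy_embedding <- function() {
  v <- rbind(A = c(0.1, -0.5, 0.3),
             B = c(-0.2, -0.1, -0.4),
             C = c(0.0, 0.0, 0.0))
  gene_embedding(v)
}

# Write a small VariCarta-dialect CSV and return its path.
write_toy_varicarta <- function(rows, path = tempfile(fileext = ".csv")) {
  header <- paste("individual_id,gene_symbol,sequencing_type,variant_category",
                  "chromosome,position,ref,alt,source_paper", sep = ",")
  writeLines(c(header, rows), path)
  path
}

# Gaussian blobs with known assignment.
make_blobs <- function(n_per = 60, centers = rbind(c(0, 0), c(10, 0), c(0, 10)),
                       sd = 0.3, seed = 42) {
  set.seed(seed)
  X <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i)
    sweep(matrix(rnorm(n_per * ncol(centers), 0, sd), ncol = ncol(centers)),
          2, centers[i, ], `+`)))
  list(points = X, truth = rep(seq_len(nrow(centers)) - 1L, each = n_per))
}

# Naive MST: repeatedly scan the full edge list (ordered by weight, then by
# endpoint indices -- the same tie rule the package documents) and take the
# cheapest edge joining two components, tracked by a plain label vector.
naive_mst <- function(M) {
  n <- nrow(M)
  eis <- which(upper.tri(M), arr.ind = TRUE)
  ew <- M[eis]
  o <- order(ew, eis[, 1], eis[, 2])
  eis <- eis[o, , drop = FALSE]; ew <- ew[o]
  comp <- seq_len(n)
  out <- NULL
  for (r in seq_along(ew)) {
    a <- comp[eis[r, 1]]; b <- comp[eis[r, 2]]
    if (a != b) {
      out <- rbind(out, c(eis[r, 1], eis[r, 2], ew[r]))
      comp[comp == b] <- a
    }
  }
  out
}

# Independent DBCV implementation: plain loops for every quantity and the
# naive MST routine above instead of the package's Kruskal/union-find.
dbcv_oracle <- function(points, labels) {
  pts <- as.matrix(points)
  n_tot <- length(labels)
  ids <- sort(unique(labels[labels >= 0]))
  ids <- ids[vapply(ids, function(k) sum(labels == k) >= 2, logical(1))]
  if (length(ids) < 2) return(NA_real_)
  d <- ncol(pts)
  euc <- function(a, b) sqrt(sum((a - b)^2))
  acore <- rep(NA_real_, n_tot)
  internal <- vector("list", length(ids))
  dsc <- numeric(length(ids))
  for (ci in seq_along(ids)) {
    idx <- which(labels == ids[ci]); ni <- length(idx)
    for (i in idx) {
      s <- 0
      for (j in idx) if (j != i) s <- s + (1 / euc(pts[i, ], pts[j, ]))^d
      acore[i] <- (s / (ni - 1))^(-1 / d)
    }
    mr <- matrix(0, ni, ni)
    for (a in seq_len(ni)) for (b in seq_len(ni)) if (a != b)
      mr[a, b] <- max(acore[idx[a]], acore[idx[b]], euc(pts[idx[a], ], pts[idx[b], ]))
    el <- naive_mst(mr)
    deg <- integer(ni)
    for (r in seq_len(nrow(el))) {
      deg[el[r, 1]] <- deg[el[r, 1]] + 1L
      deg[el[r, 2]] <- deg[el[r, 2]] + 1L
    }
    int <- which(deg >= 2)
    if (!length(int)) int <- seq_len(ni)
    is_int <- el[, 1] %in% int & el[, 2] %in% int
    dsc[ci] <- if (any(is_int)) max(el[is_int, 3]) else max(el[, 3])
    internal[[ci]] <- idx[int]
  }
  v <- numeric(length(ids))
  for (ci in seq_along(ids)) {
    sep <- Inf
    for (cj in seq_along(ids)) if (cj != ci)
      for (u in internal[[ci]]) for (vv in internal[[cj]])
        sep <- min(sep, max(acore[u], acore[vv], euc(pts[u, ], pts[vv, ])))
    den <- max(sep, dsc[ci])
    v[ci] <- if (den > 0) (sep - dsc[ci]) / den else 0
  }
  sum(vapply(ids, function(k) sum(labels == k), numeric(1)) / n_tot * v)
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# Reduced-scale synthetic config for fast pipeline-level tests.
small_synth_config <- function(seed, ...) {
  synthetic_config(n_genes = 200, embed_dim = 40, n_modules = 4,
                   n_phenotypes = 80, individuals_per_subtype = 30,
                   n_terms = 24, seed = seed, ...)
}

small_ae_cfg <- function(G, seed) {
  autoencoder_config(input_dim = G, epochs = 80, seed = seed)
}

run_small_pipeline <- function(cfg, seed, dir = tempfile(), ...) {
  paths <- write_synthetic_inputs(cfg, dir)
  truth <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  fit <- subtype_pipeline(paths[["cohort"]], paths[["embedding"]],
                          paths[["phenotypes"]], terms = paths[["terms"]],
                          asd_list = paths[["asd_list"]],
                          ae_cfg = small_ae_cfg(cfg$n_genes,
                                                derive_stage_seed(seed, 1L)),
                          compute_2d = FALSE, seed = seed, ...)
  list(fit = fit, truth = unlist(truth$subtypes), paths = paths)
}

default_grid_for_test <- function(n) asdclust:::default_grid(n)

# Full study-condition run (generator defaults): used where recovery quality
# itself is asserted; reduced-scale runs cannot support those claims.
run_default_pipeline <- function(cfg, seed, ...) {
  paths <- write_synthetic_inputs(cfg, tempfile())
  truth <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  fit <- subtype_pipeline(paths[["cohort"]], paths[["embedding"]],
                          paths[["phenotypes"]], terms = paths[["terms"]],
                          asd_list = paths[["asd_list"]],
                          compute_2d = FALSE, seed = seed, ...)
  list(fit = fit, truth = unlist(truth$subtypes), paths = paths)
}
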