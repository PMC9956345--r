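#' Derive a deterministic per-stage seed from the global seed
#'
#' Each pipeline stage draws its own seed from the global one through a
#' fixed affine-modular map, so stages can be rerun in isolation and still
#' reproduce the full run: `stage_seed = (seed * 7919 + 104729 * stage) mod
#' (2^31 - 1)`.
#'
#' @param seed Global integer seed.
#' @param stage Integer stage index (1 = autoencoder, 2 = projection,
#'   3 = display coordinates).
#' @return Integer seed below 2^31.
#' @export
derive_stage_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 7919 + 104729 * as.numeric(stage)) %% 2147483647)
}

default_grid <- function(n) {
  mcs <- sort(unique(pmax(5L, round(n * c(0.05, 0.15, 0.30)))))
  cluster_grid(min_cluster_size = mcs,
               min_samples = c(5L, 10L),
               metric = c("euclidean", "manhattan"),
               cluster_selection_method = c("eom", "leaf"))
}

#' Fit the full genetic-subtyping pipeline
#'
#' Runs the stages in order: ingest and deduplicate the variant-event table,
#' restrict to the configured sequencing types, group events into
#' per-individual gene sets; build the phenotype matrix over the embedding
#' vocabulary and train the autoencoder on it; encode the individuals into
#' the latent space; project with UMAP and run the exhaustive HDBSCAN grid
#' search scored by DBCV; extract per-cluster gene sets and profile them by
#' term over-representation, phenotype fold enrichment and ASD-list
#' intersection.
#'
#' @param cohort Path to a VariCarta-dialect CSV, or a `variant_events`
#'   data.frame.
#' @param embedding Path to a Gene2Vec-format file, or a `gene_embedding`.
#' @param phenotypes Path to a genes_to_phenotype TSV, or a list of
#'   `phenotype_annotation` records.
#' @param terms Path to a term-annotation TSV, a `term_db`, or `NULL` to
#'   skip term enrichment.
#' @param asd_list Path to a gene list, a character vector, or `NULL`.
#' @param sequencing_keep Sequencing types retained (default whole-genome
#'   only).
#' @param ae_cfg An [autoencoder_config()]; derived from the data (64 latent
#'   components, 6 + 6 layers) when `NULL`.
#' @param reduction A [reduction_params()] for the 64 -> 5 projection (its
#'   `seed` is overridden by the derived stage seed).
#' @param grid A [cluster_grid()]; when `NULL`, `min_cluster_size` candidates
#'   are 5%, 15% and 30% of the cohort and both metrics and both selection
#'   methods are crossed with `min_samples` in \{5, 10\}.
#' @param background `"intersection"` (embedding vocabulary intersected with
#'   annotated genes; default) or `"annotated"` (all annotated genes) as the
#'   enrichment universe.
#' @param fdr_max,fe_min,fallback_top,fe_display Enrichment reporting
#'   thresholds (defaults 0.005, 1.5, 20, 1.0).
#' @param compute_2d Also compute 2-D display coordinates with a second UMAP.
#' @param out_dir If non-`NULL`, write the report bundle (census, labels,
#'   grid table, coordinates, enrichment and phenotype-FE tables, run-report
#'   JSON with checksums) there.
#' @param seed Global integer seed (required).
#' @return A `subtype_fit` object; see [print.subtype_fit()].
#' @export
subtype_pipeline <- function(cohort, embedding, phenotypes, terms = NULL,
                             asd_list = NULL, sequencing_keep = "whole_genome",
                             ae_cfg = NULL, reduction = reduction_params(),
                             grid = NULL,
                             background = c("intersection", "annotated"),
                             fdr_max = 0.005, fe_min = 1.5, fallback_top = 20L,
                             fe_display = 1.0, compute_2d = TRUE,
                             out_dir = NULL, seed) {
  if (missing(seed)) stop("'seed' is required")
  background <- match.arg(background)
  t0 <- Sys.time()
  warnings_log <- character(0)

  ## stage 1: variant ingestion
  raw <- if (is.character(cohort)) read_varicarta(cohort) else as_variant_events(cohort)
  dedup <- deduplicate_events(raw)
  filtered <- filter_by_sequencing(dedup, keep = sequencing_keep)
  if (!nrow(filtered)) stop("stage variant_io: no events left after sequencing filter")
  sets <- group_individuals(filtered)

  ## stage 2: embedding space
  emb <- if (is.character(embedding)) load_gene_embedding(embedding) else embedding
  ann <- if (is.character(phenotypes)) read_phenotype_annotations(phenotypes) else phenotypes
  pm <- build_phenotype_matrix(ann, emb)
  if (sum(!pm$flagged) < 2)
    stop("stage embedding_space: fewer than 2 phenotype rows with in-vocabulary genes")

  ## stage 3: latent encoder
  ae_seed <- derive_stage_seed(seed, 1L)
  if (is.null(ae_cfg))
    ae_cfg <- autoencoder_config(input_dim = length(emb$vocabulary), seed = ae_seed)
  model <- train_autoencoder(pm, ae_cfg)
  latent <- encode_individuals(sets, emb, model)
  if (any(attr(latent, "flagged")))
    warnings_log <- c(warnings_log,
      sprintf("%d individual(s) had no in-vocabulary genes (retained, flagged)",
              sum(attr(latent, "flagged"))))

  ## stage 4: reduction + clustering
  reduction$seed <- derive_stage_seed(seed, 2L)
  projected <- umap_project(latent, reduction)
  if (is.null(grid)) grid <- default_grid(nrow(projected))
  gs <- grid_search(projected, grid)
  labels <- gs$best_labels
  cov <- coverage(labels)
  coords2d <- NULL
  if (compute_2d) {
    p2 <- reduction
    p2$n_components <- 2L
    p2$seed <- derive_stage_seed(seed, 3L)
    coords2d <- umap_project(latent, p2)
  }

  ## stage 5: cluster profiling
  asd <- if (is.character(asd_list) && length(asd_list) == 1 && file.exists(asd_list))
    read_gene_list(asd_list) else asd_list
  cgs <- cluster_gene_sets(labels, sets, events = filtered, asd_list = asd)

  db <- NULL; enr <- NULL; pfe <- NULL
  if (!is.null(terms)) {
    db <- if (is.character(terms)) read_term_annotations(terms) else terms
    if (background == "intersection") {
      db <- term_db(db$terms, intersect(db$background, emb$vocabulary))
    }
    enr <- lapply(cgs$gene_sets, enrich_cluster, db = db, fdr_max = fdr_max,
                  fe_min = fe_min, fallback_top = fallback_top)
    pfe <- lapply(cgs$gene_sets, phenotype_fe, phenotypes = ann,
                  background = db$background, fe_display = fe_display)
  }

  report <- list(
    seed = seed,
    stage_seeds = list(autoencoder = derive_stage_seed(seed, 1L),
                       projection = derive_stage_seed(seed, 2L),
                       coordinates = if (compute_2d) derive_stage_seed(seed, 3L) else NULL),
    ingestion = ingestion_report(raw, dedup),
    retained_fraction = attr(filtered, "retained_fraction"),
    n_individuals = length(sets),
    phenotype_matrix = list(rows = nrow(pm$values), cols = ncol(pm$values),
                            stored = length(pm$values@x),
                            flagged_rows = sum(pm$flagged),
                            flagged_excluded_from_training = TRUE),
    autoencoder = c(unclass(ae_cfg),
                    list(final_loss = model$history[length(model$history)])),
    reduction = unclass(reduction),
    clustering = list(best = unclass(gs$best_params),
                      dbcv = gs$results$dbcv[gs$best_index],
                      coverage = cov, n_clusters = n_clusters(labels)),
    enrichment = list(background = background,
                      background_size = if (!is.null(db)) length(db$background) else NA,
                      fdr_max = fdr_max, fe_min = fe_min,
                      fallback_top = fallback_top, fe_display = fe_display),
    warnings = warnings_log,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))

  fit <- structure(list(labels = labels, coverage = cov,
                        dbcv = gs$results$dbcv[gs$best_index],
                        best_params = gs$best_params,
                        grid_results = gs$results,
                        census = cgs$census, gene_sets = cgs$gene_sets,
                        enrichment = enr, phenotype_fe = pfe,
                        latent = latent, projected = projected,
                        coords2d = coords2d, encoder = model,
                        individual_ids = names(sets),
                        report = report),
                   class = "subtype_fit")
  if (!is.null(out_dir)) write_fit_bundle(fit, out_dir)
  fit
}

#' @export
print.subtype_fit <- function(x, ...) {
  cat("Genetic subtyping fit\n")
  cat("  individuals:", length(x$labels), " clusters:", n_clusters(x$labels),
      " coverage:", sprintf("%.1f%%", 100 * x$coverage),
      " DBCV:", sprintf("%.3f", x$dbcv), "\n")
  cat("  winning params: min_cluster_size =", x$best_params$min_cluster_size,
      ", min_samples =", x$best_params$min_samples,
      ",", x$best_params$metric, ",", x$best_params$cluster_selection_method, "\n")
  invisible(x)
}

#' @export
summary.subtype_fit <- function(object, ...) {
  print(object)
  cat("\nCluster census:\n")
  print(object$census, row.names = FALSE)
  if (!is.null(object$enrichment)) {
    reported <- vapply(object$enrichment, function(e) sum(e$report_tier != "none"),
                       integer(1))
    cat("\nReported enriched terms per cluster:\n")
    print(reported)
  }
  invisible(object)
}

#' Plot the 2-D display coordinates of a subtyping fit
#'
#' @param x A `subtype_fit` with `compute_2d = TRUE`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.subtype_fit <- function(x, ...) {
  if (is.null(x$coords2d)) stop("fit has no 2-D coordinates (compute_2d = FALSE)")
  cols <- ifelse(x$labels < 0, "grey60", x$labels + 2)
  graphics::plot(x$coords2d, col = cols, pch = 19, cex = 0.6,
                 xlab = "UMAP 1", ylab = "UMAP 2", ...)
  invisible(x)
}

#' Write the report bundle of a fit
#'
#' Emits labels, census, grid-search table, 2-D coordinates, enrichment and
#' phenotype-FE tables as TSV plus a run-report JSON listing every file with
#' its MD5 checksum.
#'
#' @param fit A `subtype_fit`.
#' @param dir Output directory (created if missing).
#' @return Named character vector of written paths, invisibly.
#' @export
write_fit_bundle <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(labels = file.path(dir, "labels.tsv"),
             census = file.path(dir, "census.tsv"),
             grid = file.path(dir, "grid_search.tsv"))
  utils::write.table(data.frame(individual_id = fit$individual_ids,
                                cluster = as.integer(fit$labels)),
                     paths[["labels"]], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(fit$census, paths[["census"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(fit$grid_results, paths[["grid"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(fit$coords2d)) {
    paths["coords2d"] <- file.path(dir, "coords_2d.tsv")
    utils::write.table(data.frame(individual_id = fit$individual_ids,
                                  round(fit$coords2d, 6)),
                       paths[["coords2d"]], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(fit$enrichment)) {
    paths["enrichment"] <- file.path(dir, "enrichment.tsv")
    enr <- do.call(rbind, lapply(names(fit$enrichment), function(cl) {
      e <- fit$enrichment[[cl]]
      if (nrow(e)) cbind(cluster = cl, e) else NULL
    }))
    if (is.null(enr)) enr <- cbind(cluster = character(0), empty_enrichment())
    utils::write.table(enr, paths[["enrichment"]], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths["phenotype_fe"] <- file.path(dir, "phenotype_fe.tsv")
    pfe <- do.call(rbind, lapply(names(fit$phenotype_fe), function(cl) {
      e <- fit$phenotype_fe[[cl]]
      if (nrow(e)) cbind(cluster = cl, e) else NULL
    }))
    if (is.null(pfe))
      pfe <- data.frame(cluster = character(0), phenotype_id = character(0),
                        name = character(0), FE = numeric(0))
    utils::write.table(pfe, paths[["phenotype_fe"]], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  report <- fit$report
  report$files <- lapply(stats::setNames(as.list(paths), names(paths)), function(p)
    list(path = basename(p), md5 = unname(tools::md5sum(p))))
  path_report <- file.path(dir, "report.json")
  jsonlite::write_json(report, path_report, auto_unbox = TRUE, digits = NA,
                       null = "null")
  paths["report"] <- path_report
  invisible(paths)
}
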