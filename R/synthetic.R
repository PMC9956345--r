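#' Configuration for the synthetic-data generator
#'
#' Generates every input the pipeline consumes, with planted structure at
#' each level: gene modules in the embedding space, module-linked phenotype
#' and term annotations, and a cohort whose individuals draw their variated
#' genes from latent subtypes (one module per subtype) plus background
#' noise. All generators are pure functions of this config (seed included).
#'
#' @param n_genes Vocabulary size G.
#' @param embed_dim Embedding dimensionality D.
#' @param n_modules Number of planted gene modules M (`M <= G`).
#' @param module_spread Within-module Gaussian component noise sigma.
#' @param n_phenotypes Number of phenotype annotations P.
#' @param genes_per_phenotype Genes annotated to each phenotype.
#' @param phenotype_module_purity rho in [0, 1]: fraction of each
#'   phenotype's genes drawn from its own module.
#' @param n_subtypes Latent subtypes S (`S <= M`; subtype s is tied to
#'   module s).
#' @param individuals_per_subtype Cohort individuals per subtype.
#' @param genes_per_individual Variated genes drawn per individual.
#' @param subtype_module_fraction f in [0, 1]: fraction of an individual's
#'   genes drawn from the subtype's module.
#' @param n_terms Ontology-style terms T in the annotation db.
#' @param genes_per_term Genes annotated to each term.
#' @param n_asd_genes Size of the synthetic ASD-linked list.
#' @param duplicate_rate Fraction of cohort events re-emitted as duplicated
#'   rows (same individual and coordinates, different source paper), to
#'   exercise deduplication.
#' @param oov_rate Fraction of extra events carrying out-of-vocabulary gene
#'   symbols, to exercise vocabulary intersection.
#' @param seed Integer seed (required).
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_genes = 300, embed_dim = 50, n_modules = 6,
                             module_spread = 0.05, n_phenotypes = 120,
                             genes_per_phenotype = 20,
                             phenotype_module_purity = 0.9,
                             n_subtypes = 3, individuals_per_subtype = 60,
                             genes_per_individual = 15,
                             subtype_module_fraction = 0.9,
                             n_terms = 40, genes_per_term = 25,
                             n_asd_genes = 60,
                             duplicate_rate = 0.05, oov_rate = 0.02, seed) {
  if (missing(seed)) stop("'seed' is required")
  stopifnot(n_modules <= n_genes, n_subtypes <= n_modules,
            phenotype_module_purity >= 0, phenotype_module_purity <= 1,
            subtype_module_fraction >= 0, subtype_module_fraction <= 1,
            duplicate_rate >= 0, duplicate_rate <= 1,
            oov_rate >= 0, oov_rate <= 1,
            embed_dim >= n_modules)
  structure(as.list(environment()), class = "synthetic_config")
}

#' Generate a gene embedding with planted modules
#'
#' Module centroids are made exactly orthogonal unit vectors (QR of a random
#' Gaussian matrix), so their pairwise cosine similarity is 0; gene g of
#' module m is `centroid_m + N(0, sigma^2)` per component. Genes are split
#' evenly over modules.
#'
#' @param cfg A [synthetic_config()].
#' @return List with `embedding` (a `gene_embedding`), `modules` (named
#'   integer vector: gene -> module) and `centroid_max_cosine` (reported
#'   bound on pairwise centroid similarity).
#' @export
make_gene_embedding <- function(cfg) {
  set.seed(cfg$seed)
  Q <- qr.Q(qr(matrix(stats::rnorm(cfg$embed_dim * cfg$n_modules),
                      cfg$embed_dim, cfg$n_modules)))
  centroids <- t(Q)                                   # M x D, orthonormal rows
  modules <- sample(rep_len(seq_len(cfg$n_modules), cfg$n_genes))
  vectors <- centroids[modules, , drop = FALSE] +
    matrix(stats::rnorm(cfg$n_genes * cfg$embed_dim, sd = cfg$module_spread),
           cfg$n_genes, cfg$embed_dim)
  rownames(vectors) <- sprintf("GENE%04d", seq_len(cfg$n_genes))
  cs <- centroids %*% t(centroids)
  diag(cs) <- 0
  list(embedding = gene_embedding(vectors),
       modules = stats::setNames(modules, rownames(vectors)),
       centroid_max_cosine = max(abs(cs)))
}

draw_module_set <- function(n_draw, own_fraction, own_genes, other_genes) {
  n_own <- min(round(own_fraction * n_draw), length(own_genes))
  n_oth <- min(n_draw - n_own, length(other_genes))
  c(sample(own_genes, n_own), sample(other_genes, n_oth))
}

#' Generate phenotype annotations linked to gene modules
#'
#' Phenotype p is assigned module `1 + (p-1) mod M`; a fraction rho of its
#' genes come from that module, the rest uniformly from the other modules.
#'
#' @param cfg A [synthetic_config()].
#' @param modules Gene -> module assignment from [make_gene_embedding()].
#' @return List of `phenotype_annotation` records with attribute
#'   `truth_module` (integer per phenotype).
#' @export
make_phenotype_annotations <- function(cfg, modules) {
  set.seed(cfg$seed + 1L)
  genes <- names(modules)
  truth <- rep_len(seq_len(cfg$n_modules), cfg$n_phenotypes)
  ann <- lapply(seq_len(cfg$n_phenotypes), function(p) {
    own <- genes[modules == truth[p]]
    oth <- genes[modules != truth[p]]
    phenotype_annotation(sprintf("HP:%07d", p),
                         sprintf("synthetic phenotype %d (module %d)", p, truth[p]),
                         draw_module_set(cfg$genes_per_phenotype,
                                         cfg$phenotype_module_purity, own, oth))
  })
  attr(ann, "truth_module") <- truth
  ann
}

#' Generate a module-linked ontology-style term database
#'
#' Terms cycle through the three namespaces and through the modules; each
#' term draws its genes like a phenotype (purity rho from its module).
#'
#' @param cfg A [synthetic_config()].
#' @param modules Gene -> module assignment.
#' @return A `term_db` whose background is the full synthetic vocabulary;
#'   attribute `truth_module` on the term list.
#' @export
make_term_annotations <- function(cfg, modules) {
  set.seed(cfg$seed + 2L)
  genes <- names(modules)
  ns <- c("biological_process", "cellular_component", "molecular_function")
  truth <- rep_len(seq_len(cfg$n_modules), cfg$n_terms)
  terms <- lapply(seq_len(cfg$n_terms), function(t) {
    own <- genes[modules == truth[t]]
    oth <- genes[modules != truth[t]]
    list(name = sprintf("synthetic term %d (module %d)", t, truth[t]),
         namespace = ns[1 + (t - 1) %% 3],
         genes = draw_module_set(cfg$genes_per_term,
                                 cfg$phenotype_module_purity, own, oth))
  })
  names(terms) <- sprintf("GO:%07d", seq_len(cfg$n_terms))
  db <- term_db(terms, genes)
  attr(db, "truth_module") <- truth
  db
}

#' Generate a synthetic ASD-linked gene list
#'
#' A uniform sample of the vocabulary, standing in for a curated
#' disease-gene list (synthetic; carries no biological meaning).
#'
#' @param cfg A [synthetic_config()].
#' @param modules Gene -> module assignment.
#' @return Character vector of gene symbols.
#' @export
make_asd_list <- function(cfg, modules) {
  set.seed(cfg$seed + 3L)
  sort(sample(names(modules), min(cfg$n_asd_genes, length(modules))))
}

#' Generate a synthetic variant cohort in the VariCarta dialect
#'
#' Individual i of subtype s draws `genes_per_individual` genes, a fraction
#' f from module s and the rest uniformly elsewhere; each gene becomes one
#' whole-genome variant event with synthetic coordinates. Duplicated rows
#' (same individual and coordinates, different source paper) are injected at
#' `duplicate_rate`, and out-of-vocabulary events at `oov_rate`, so the
#' ingestion edge paths are exercised. Ground-truth subtype labels are
#' returned separately.
#'
#' @param cfg A [synthetic_config()].
#' @param modules Gene -> module assignment.
#' @return List with `events` (data.frame in the VariCarta CSV dialect),
#'   `truth` (named integer vector: individual id -> subtype) and
#'   `n_base_events` (event count before duplicate/OOV injection).
#' @export
make_variant_cohort <- function(cfg, modules) {
  set.seed(cfg$seed + 4L)
  genes <- names(modules)
  n_ind <- cfg$n_subtypes * cfg$individuals_per_subtype
  ind_ids <- sprintf("IND%04d", seq_len(n_ind))
  truth <- stats::setNames(rep(seq_len(cfg$n_subtypes),
                               each = cfg$individuals_per_subtype), ind_ids)
  cats <- c("nonsynonymous SNV", "synonymous SNV", "frameshift insertion",
            "frameshift deletion", "stopgain")
  rows <- lapply(seq_len(n_ind), function(i) {
    s <- truth[[i]]
    gs <- draw_module_set(cfg$genes_per_individual, cfg$subtype_module_fraction,
                          genes[modules == s], genes[modules != s])
    data.frame(individual_id = ind_ids[i],
               gene_symbol = gs,
               sequencing_type = "whole genome sequencing",
               variant_category = sample(cats, length(gs), replace = TRUE),
               chromosome = as.character(sample.int(22, length(gs), replace = TRUE)),
               position = as.character(sample.int(2e8, length(gs))),
               ref = sample(c("A", "C", "G", "T"), length(gs), replace = TRUE),
               alt = sample(c("A", "C", "G", "T"), length(gs), replace = TRUE),
               source_paper = "synth-paper-1",
               stringsAsFactors = FALSE)
  })
  ev <- do.call(rbind, rows)
  n_base <- nrow(ev)
  n_dup <- floor(cfg$duplicate_rate * n_base)
  if (n_dup > 0) {
    dup <- ev[sample.int(n_base, n_dup), , drop = FALSE]
    dup$source_paper <- "synth-paper-2"
    ev <- rbind(ev, dup)
  }
  n_oov <- floor(cfg$oov_rate * n_base)
  if (n_oov > 0) {
    who <- sample(ind_ids, n_oov, replace = TRUE)
    oov <- data.frame(individual_id = who,
                      gene_symbol = sprintf("NOVELGENE%03d", seq_len(n_oov)),
                      sequencing_type = "whole genome sequencing",
                      variant_category = sample(cats, n_oov, replace = TRUE),
                      chromosome = as.character(sample.int(22, n_oov, replace = TRUE)),
                      position = as.character(sample.int(2e8, n_oov)),
                      ref = sample(c("A", "C", "G", "T"), n_oov, replace = TRUE),
                      alt = sample(c("A", "C", "G", "T"), n_oov, replace = TRUE),
                      source_paper = "synth-paper-1",
                      stringsAsFactors = FALSE)
    ev <- rbind(ev, oov)
  }
  ev <- ev[sample.int(nrow(ev)), , drop = FALSE]   # shuffle row order
  rownames(ev) <- NULL
  list(events = ev, truth = truth, n_base_events = n_base)
}

#' Write the full set of synthetic pipeline inputs to disk
#'
#' Emits every dialect the real pipeline reads: the embedding in Gene2Vec
#' text format, phenotype annotations as a genes_to_phenotype-style TSV,
#' term annotations as a long TSV, the cohort as a VariCarta-dialect CSV,
#' the ASD-linked list as a flat file, and a ground-truth JSON (module
#' assignment, subtype labels, bookkeeping counts). Regeneration from the
#' same config is byte-identical.
#'
#' @param cfg A [synthetic_config()].
#' @param dir Output directory (created if missing).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_synthetic_inputs <- function(cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ge <- make_gene_embedding(cfg)
  ann <- make_phenotype_annotations(cfg, ge$modules)
  db <- make_term_annotations(cfg, ge$modules)
  asd <- make_asd_list(cfg, ge$modules)
  coh <- make_variant_cohort(cfg, ge$modules)

  paths <- c(embedding = file.path(dir, "embedding.txt"),
             phenotypes = file.path(dir, "genes_to_phenotype.tsv"),
             terms = file.path(dir, "term_annotations.tsv"),
             cohort = file.path(dir, "cohort.csv"),
             asd_list = file.path(dir, "asd_genes.txt"),
             truth = file.path(dir, "truth.json"))

  vec <- ge$embedding$vectors
  writeLines(paste(rownames(vec),
                   apply(vec, 1, function(r) paste(sprintf("%.6f", r), collapse = " "))),
             paths[["embedding"]])

  ph_rows <- do.call(rbind, lapply(ann, function(a)
    data.frame(gene_symbol = a$genes, hpo_id = a$phenotype_id,
               hpo_name = a$name, stringsAsFactors = FALSE)))
  utils::write.table(ph_rows, paths[["phenotypes"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)

  tm_rows <- do.call(rbind, lapply(names(db$terms), function(id)
    data.frame(term_id = id, namespace = db$terms[[id]]$namespace,
               term_name = db$terms[[id]]$name,
               gene_symbol = db$terms[[id]]$genes, stringsAsFactors = FALSE)))
  utils::write.table(tm_rows, paths[["terms"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)

  utils::write.table(coh$events, paths[["cohort"]], sep = ",", quote = FALSE,
                     row.names = FALSE)
  writeLines(asd, paths[["asd_list"]])
  jsonlite::write_json(list(config = unclass(cfg),
                            modules = as.list(ge$modules),
                            subtypes = as.list(coh$truth),
                            n_base_events = coh$n_base_events,
                            centroid_max_cosine = ge$centroid_max_cosine),
                       paths[["truth"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
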