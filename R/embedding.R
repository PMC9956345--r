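#' Load a gene embedding in Gene2Vec text format
#'
#' One line per gene: the gene symbol followed by D whitespace-separated
#' floats. The pretrained co-expression space distributed with Gene2Vec has
#' 24,447 genes in 200 dimensions; any (G, D) with a consistent D is
#' accepted. Symbols are upper-cased and trimmed; duplicates are fatal.
#'
#' @param path Path to the embedding text file.
#' @return A `gene_embedding` object: list with `vocabulary` (character, G),
#'   `vectors` (G x D numeric matrix, rows named by symbol) and `dim` (D).
#' @export
load_gene_embedding <- function(path) {
  if (!file.exists(path)) stop("embedding file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("embedding file is empty: ", path)
  toks <- strsplit(trimws(lines), "[[:space:]]+")
  d <- length(toks[[1]]) - 1L
  if (d < 1) stop("line 1 has no vector components")
  lens <- lengths(toks)
  if (any(lens != d + 1L))
    stop("ragged embedding file: line ", which(lens != d + 1L)[1],
         " has ", lens[lens != d + 1L][1] - 1L, " components, expected ", d)
  syms <- norm_symbol(vapply(toks, `[[`, "", 1L))
  if (anyDuplicated(syms))
    stop("duplicate gene symbol in embedding: ", syms[duplicated(syms)][1])
  vals <- suppressWarnings(
    vapply(toks, function(t) as.numeric(t[-1]), numeric(d)))
  if (anyNA(vals)) {
    bad <- which(apply(if (d > 1) is.na(vals) else matrix(is.na(vals), nrow = 1), 2, any))[1]
    stop("non-numeric embedding component at line ", bad)
  }
  vectors <- if (d > 1) t(vals) else matrix(vals, ncol = 1)
  rownames(vectors) <- syms
  structure(list(vocabulary = syms, vectors = vectors, dim = d),
            class = "gene_embedding")
}

#' Construct a gene embedding from a matrix
#'
#' @param vectors G x D numeric matrix with unique rownames (gene symbols).
#' @return A `gene_embedding` object.
#' @export
gene_embedding <- function(vectors) {
  stopifnot(is.matrix(vectors), !is.null(rownames(vectors)))
  syms <- norm_symbol(rownames(vectors))
  if (anyDuplicated(syms)) stop("duplicate gene symbol: ", syms[duplicated(syms)][1])
  if (any(!is.finite(vectors))) stop("non-finite embedding components")
  rownames(vectors) <- syms
  structure(list(vocabulary = syms, vectors = vectors, dim = ncol(vectors)),
            class = "gene_embedding")
}

#' @export
print.gene_embedding <- function(x, ...) {
  cat("Gene embedding:", length(x$vocabulary), "genes x", x$dim, "dimensions\n")
  invisible(x)
}

#' Scalar summary of a gene: maximum embedding component
#'
#' Every constructed vector (phenotype rows, individual vectors) stores, at
#' the position of an annotated/variated gene, the maximum of that gene's D
#' embedding components. The true maximum is used, so the scalar can be
#' negative or exactly zero.
#'
#' @param gene Gene symbol(s), normalised internally.
#' @param emb A `gene_embedding`.
#' @return Numeric vector of per-gene maxima.
#' @export
gene_scalar <- function(gene, emb) {
  gene <- norm_symbol(gene)
  miss <- setdiff(gene, emb$vocabulary)
  if (length(miss))
    stop("gene(s) not in embedding vocabulary: ", paste(utils::head(miss, 5), collapse = ", "))
  apply(emb$vectors[gene, , drop = FALSE], 1, max)
}

#' Read phenotype-to-gene annotations (genes_to_phenotype TSV dialect)
#'
#' Expects a header row; the default column map matches the HPO
#' `genes_to_phenotype.txt` export (gene symbol, HPO term id, HPO term name).
#' Rows sharing a phenotype id are aggregated into one annotation record.
#'
#' @param path Path to the TSV file.
#' @param columns Named character vector with entries `gene_symbol`,
#'   `phenotype_id`, `phenotype_name`.
#' @return List of `phenotype_annotation` records, each a list with
#'   `phenotype_id`, `name` and `genes` (character set).
#' @export
read_phenotype_annotations <- function(path,
    columns = c(gene_symbol = "gene_symbol", phenotype_id = "hpo_id",
                phenotype_name = "hpo_name")) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                           colClasses = "character", comment.char = "",
                           stringsAsFactors = FALSE, check.names = FALSE)
  for (f in c("gene_symbol", "phenotype_id")) {
    if (!columns[[f]] %in% names(tab))
      stop("required column missing from ", path, ": '", columns[[f]], "'")
  }
  ids <- tab[[columns[["phenotype_id"]]]]
  genes <- norm_symbol(tab[[columns[["gene_symbol"]]]])
  names_col <- if (columns[["phenotype_name"]] %in% names(tab))
    tab[[columns[["phenotype_name"]]]] else ids
  uid <- unique(ids)
  ann <- lapply(uid, function(p) {
    sel <- ids == p
    phenotype_annotation(p, names_col[sel][1], genes[sel])
  })
  ann
}

#' Construct a phenotype annotation record
#'
#' @param phenotype_id Term id (e.g. `HP:0001250`).
#' @param name Human-readable label.
#' @param genes Character vector of gene symbols (deduplicated, normalised).
#' @return A `phenotype_annotation` list.
#' @export
phenotype_annotation <- function(phenotype_id, name, genes) {
  structure(list(phenotype_id = phenotype_id, name = name,
                 genes = sort(unique(norm_symbol(genes)))),
            class = "phenotype_annotation")
}

#' Build the phenotype x gene matrix (max-of-components rule)
#'
#' Row p has one stored entry per gene annotated to phenotype p that is in
#' the embedding vocabulary; the entry value is [gene_scalar()] of that gene.
#' Column order is exactly the embedding vocabulary order, shared with every
#' individual vector. Entries are "stored" by annotation membership, so a
#' coincidental 0.0 maximum remains an explicit entry. Rows with no
#' in-vocabulary gene are flagged (and by default excluded from autoencoder
#' training downstream, but retained in the matrix).
#'
#' @param annotations List of `phenotype_annotation` records.
#' @param emb A `gene_embedding`.
#' @return A `phenotype_matrix` object: list with `values` (sparse P x G
#'   dgCMatrix), `phenotype_ids`, `phenotype_names`, `row_gene_counts`
#'   (in-vocabulary annotated genes per row) and `flagged` (logical:
#'   zero in-vocabulary genes).
#' @export
build_phenotype_matrix <- function(annotations, emb) {
  g_all <- emb$vocabulary
  scal <- apply(emb$vectors, 1, max)
  p_n <- length(annotations)
  ij_i <- integer(0); ij_j <- integer(0); xs <- numeric(0)
  counts <- integer(p_n)
  for (p in seq_len(p_n)) {
    gs <- intersect(annotations[[p]]$genes, g_all)
    counts[p] <- length(gs)
    if (length(gs)) {
      j <- match(gs, g_all)
      ij_i <- c(ij_i, rep.int(p, length(j)))
      ij_j <- c(ij_j, j)
      xs <- c(xs, unname(scal[j]))
    }
  }
  vals <- Matrix::sparseMatrix(i = ij_i, j = ij_j, x = xs,
                               dims = c(p_n, length(g_all)),
                               dimnames = list(NULL, g_all))
  structure(list(values = vals,
                 phenotype_ids = vapply(annotations, `[[`, "", "phenotype_id"),
                 phenotype_names = vapply(annotations, `[[`, "", "name"),
                 row_gene_counts = counts,
                 flagged = counts == 0L),
            class = "phenotype_matrix")
}

#' @export
print.phenotype_matrix <- function(x, ...) {
  cat("Phenotype matrix:", nrow(x$values), "phenotypes x", ncol(x$values),
      "genes;", length(x$values@x), "stored entries;",
      sum(x$flagged), "flagged all-zero rows\n")
  invisible(x)
}

#' Build an individual's gene-set vector over the embedding vocabulary
#'
#' Component g equals [gene_scalar()] of gene g if g is in the individual's
#' variated-gene set and the vocabulary, else 0. Out-of-vocabulary genes are
#' dropped and counted, never imputed.
#'
#' @param genes Character vector (set) of gene symbols.
#' @param emb A `gene_embedding`.
#' @return Sparse numeric vector of length G (class `dsparseVector`) with
#'   attribute `n_dropped` = number of out-of-vocabulary genes.
#' @export
build_individual_vector <- function(genes, emb) {
  genes <- unique(norm_symbol(genes))
  invocab <- intersect(genes, emb$vocabulary)
  j <- match(invocab, emb$vocabulary)
  x <- if (length(j)) apply(emb$vectors[j, , drop = FALSE], 1, max) else numeric(0)
  v <- Matrix::sparseVector(x = unname(x), i = j, length = length(emb$vocabulary))
  attr(v, "n_dropped") <- length(genes) - length(invocab)
  v
}

#' Build the n x G matrix of individual gene-set vectors
#'
#' Stacks [build_individual_vector()] for each individual; row order follows
#' the input list. Individuals whose sets are empty after vocabulary
#' intersection are retained (zero rows) and flagged.
#'
#' @param sets An `individual_gene_sets` object (or named list of gene sets).
#' @param emb A `gene_embedding`.
#' @return Sparse n x G dgCMatrix with individual ids as rownames;
#'   attributes `n_dropped` (total out-of-vocabulary genes) and `flagged`
#'   (logical per individual: empty after intersection).
#' @export
build_individual_matrix <- function(sets, emb) {
  g_all <- emb$vocabulary
  scal <- apply(emb$vectors, 1, max)
  ij_i <- integer(0); ij_j <- integer(0); xs <- numeric(0)
  dropped <- 0L
  flagged <- logical(length(sets))
  for (i in seq_along(sets)) {
    gs <- unique(norm_symbol(sets[[i]]))
    iv <- intersect(gs, g_all)
    dropped <- dropped + length(gs) - length(iv)
    flagged[i] <- length(iv) == 0L
    if (length(iv)) {
      j <- match(iv, g_all)
      ij_i <- c(ij_i, rep.int(i, length(j)))
      ij_j <- c(ij_j, j)
      xs <- c(xs, unname(scal[j]))
    }
  }
  m <- Matrix::sparseMatrix(i = ij_i, j = ij_j, x = xs,
                            dims = c(length(sets), length(g_all)),
                            dimnames = list(names(sets), g_all))
  attr(m, "n_dropped") <- dropped
  attr(m, "flagged") <- flagged
  m
}

#' Export a phenotype matrix in MatrixMarket format
#'
#' Writes the sparse values as MTX plus row (phenotype id) and column (gene
#' symbol) label files alongside.
#'
#' @param pm A `phenotype_matrix`.
#' @param path Output `.mtx` path; labels are written to
#'   `<path>.rows.txt` / `<path>.cols.txt`.
#' @return `path`, invisibly.
#' @export
write_phenotype_mtx <- function(pm, path) {
  Matrix::writeMM(pm$values, path)
  writeLines(pm$phenotype_ids, paste0(path, ".rows.txt"))
  writeLines(colnames(pm$values), paste0(path, ".cols.txt"))
  invisible(path)
}
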