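#' Fold enrichment of a gene set in a term
#'
#' Ratio between the observed overlap and the overlap expected for a random
#' gene set of the same size drawn from the background:
#' `FE = k / (n * K / N)` with `k` cluster genes in the term, `n` cluster
#' genes in the background, `K` term genes in the background and `N` the
#' background size.
#'
#' @param k,n,K,N Integer counts (vectorised); requires `n >= 1`, `K >= 1`,
#'   `N >= max(n, K)`.
#' @return Numeric fold enrichment(s); `k = 0` gives 0.
#' @export
fold_enrichment <- function(k, n, K, N) {
  if (any(n < 1) || any(K < 1))
    stop("undefined term: n and K must be >= 1 (term or query empty in background)")
  if (any(N < pmax(n, K))) stop("inconsistent counts: N < max(n, K)")
  if (any(k > pmin(n, K)) || any(k < 0)) stop("inconsistent counts: k outside [0, min(n, K)]")
  k / (n * K / N)
}

#' Two-tailed Fisher exact p-value for a 2x2 overlap table
#'
#' Exact two-sided test on the table `[[k, n-k], [K-k, N-n-K+k]]`, computed
#' by summing all hypergeometric outcomes whose probability does not exceed
#' that of the observed table (with the customary 1e-7 relative tolerance on
#' the comparison to absorb floating-point ties).
#'
#' @param k,n,K,N Counts as in [fold_enrichment()].
#' @return Two-tailed p-value in [0, 1].
#' @export
fisher_p <- function(k, n, K, N) {
  if (N - n - K + k < 0 || K - k < 0 || n - k < 0 || k < 0)
    stop("inconsistent counts: negative cell in the 2x2 table")
  support <- max(0L, n + K - N):min(n, K)
  pmf <- stats::dhyper(support, K, N - K, n)
  p_obs <- pmf[match(k, support)]
  min(1, sum(pmf[pmf <= p_obs * (1 + 1e-7)]))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment, returned in input order and
#' capped at 1.
#'
#' @param pvals Numeric vector of p-values in [0, 1].
#' @return Adjusted p-values (same length and order).
#' @export
bh_fdr <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Construct a term-annotation database
#'
#' @param terms Named list: term id -> list(name, namespace, genes). The
#'   namespace is one of `biological_process`, `cellular_component`,
#'   `molecular_function` (free text tolerated).
#' @param background Character vector: the gene universe. Term genes outside
#'   it are trimmed at construction.
#' @return A `term_db` object.
#' @export
term_db <- function(terms, background) {
  background <- sort(unique(norm_symbol(background)))
  if (anyDuplicated(names(terms))) stop("duplicate term ids")
  terms <- lapply(terms, function(t) {
    t$genes <- intersect(sort(unique(norm_symbol(t$genes))), background)
    t
  })
  structure(list(terms = terms, background = background), class = "term_db")
}

#' @export
print.term_db <- function(x, ...) {
  cat("Term annotation db:", length(x$terms), "terms over a background of",
      length(x$background), "genes\n")
  invisible(x)
}

#' Read a term-to-gene annotation table
#'
#' Long TSV dialect: one row per (term, gene) with columns `term_id`,
#' `namespace`, `term_name`, `gene_symbol` (header required; extra columns
#' ignored).
#'
#' @param path Path to the TSV.
#' @param background Gene universe for [term_db()]; defaults to all annotated
#'   genes in the file.
#' @return A `term_db`.
#' @export
read_term_annotations <- function(path, background = NULL) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                           colClasses = "character", stringsAsFactors = FALSE)
  need <- c("term_id", "namespace", "term_name", "gene_symbol")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "))
  ids <- unique(tab$term_id)
  terms <- lapply(ids, function(t) {
    sel <- tab$term_id == t
    list(name = tab$term_name[sel][1], namespace = tab$namespace[sel][1],
         genes = tab$gene_symbol[sel])
  })
  names(terms) <- ids
  if (is.null(background)) background <- tab$gene_symbol
  term_db(terms, background)
}

#' Read a flat ASD-linked gene list
#'
#' Accepts one symbol per line, or a delimited table with a symbol column
#' (SFARI-style): if the first line contains the delimiter, the file is read
#' as a table and `symbol_column` is extracted.
#'
#' @param path Path to the list.
#' @param symbol_column Column holding symbols when the file is tabular.
#' @param sep Delimiter for the tabular case.
#' @return Character vector of normalised symbols.
#' @export
read_gene_list <- function(path, symbol_column = "gene_symbol", sep = ",") {
  first <- readLines(path, n = 1L)
  if (grepl(sep, first, fixed = TRUE)) {
    tab <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                             colClasses = "character", stringsAsFactors = FALSE)
    if (!symbol_column %in% names(tab))
      stop("column '", symbol_column, "' not found in ", path)
    sort(unique(norm_symbol(tab[[symbol_column]])))
  } else {
    sort(unique(norm_symbol(readLines(path))))
  }
}

#' Over-representation analysis of one cluster's gene set
#'
#' Tests the cluster gene set against every term in the database with
#' [fold_enrichment()] and [fisher_p()]; all tested terms of the cluster
#' form one Benjamini-Hochberg family (namespaces jointly). Reporting
#' follows the reference rules: the primary report keeps terms with
#' `FDR < fdr_max` and `FE >= fe_min`, ranked by FE descending; when that
#' set is empty but some terms still pass the FDR cut, the fallback report
#' keeps the top `fallback_top` terms by FDR ascending; otherwise the report
#' is empty (a run note, not an error).
#'
#' @param cluster_genes Character vector of gene symbols.
#' @param db A [term_db()].
#' @param fdr_max FDR threshold (default 0.005).
#' @param fe_min Fold-enrichment threshold for the primary report (1.5).
#' @param fallback_top Cap for the fallback report (20).
#' @param min_term_size Drop terms with fewer background genes (default 1 =
#'   no filter).
#' @return Data.frame of all tested terms: `term_id`, `name`, `namespace`,
#'   `k`, `n`, `K`, `N`, `FE`, `p`, `FDR`, `report_tier`
#'   (`"primary"`/`"fallback"`/`"none"`), sorted with the reported tier
#'   first (primary by FE descending, fallback by FDR ascending).
#' @export
enrich_cluster <- function(cluster_genes, db, fdr_max = 0.005, fe_min = 1.5,
                           fallback_top = 20L, min_term_size = 1L) {
  stopifnot(inherits(db, "term_db"))
  q <- intersect(unique(norm_symbol(cluster_genes)), db$background)
  if (!length(q))
    stop("cluster gene set has empty intersection with the background universe")
  n <- length(q); N <- length(db$background)
  keep <- vapply(db$terms, function(t) length(t$genes) >= min_term_size, logical(1))
  terms <- db$terms[keep]
  if (!length(terms)) return(empty_enrichment())
  K <- vapply(terms, function(t) length(t$genes), integer(1))
  k <- vapply(terms, function(t) length(intersect(q, t$genes)), integer(1))
  fe <- fold_enrichment(k, n, K, N)
  p <- vapply(seq_along(terms), function(i) fisher_p(k[i], n, K[i], N), numeric(1))
  fdr <- bh_fdr(p)
  res <- data.frame(term_id = names(terms),
                    name = vapply(terms, function(t) t$name, ""),
                    namespace = vapply(terms, function(t) t$namespace, ""),
                    k = k, n = n, K = K, N = N, FE = fe, p = p, FDR = fdr,
                    report_tier = "none", stringsAsFactors = FALSE,
                    row.names = NULL)
  primary <- res$FDR < fdr_max & res$FE >= fe_min
  if (any(primary)) {
    res$report_tier[primary] <- "primary"
  } else if (any(res$FDR < fdr_max)) {
    sig <- which(res$FDR < fdr_max)
    top <- sig[order(res$FDR[sig])][seq_len(min(fallback_top, length(sig)))]
    res$report_tier[top] <- "fallback"
  }
  tier_rank <- match(res$report_tier, c("primary", "fallback", "none"))
  ord <- order(tier_rank,
               ifelse(res$report_tier == "primary", -res$FE, res$FDR))
  res <- res[ord, , drop = FALSE]
  rownames(res) <- NULL
  res
}

empty_enrichment <- function() {
  data.frame(term_id = character(0), name = character(0),
             namespace = character(0), k = integer(0), n = integer(0),
             K = integer(0), N = integer(0), FE = numeric(0), p = numeric(0),
             FDR = numeric(0), report_tier = character(0),
             stringsAsFactors = FALSE)
}

#' Phenotype fold enrichment of a cluster gene set
#'
#' Fold enrichment between the cluster genes and each phenotype's
#' in-background annotation set (the phenotype plays the role of the term).
#' No p-value is attached: FE is reported as an effect size, filtered to
#' `FE > fe_display` and ranked by FE descending. Phenotypes with no
#' in-background gene are skipped (and counted in attribute `n_skipped`).
#'
#' @param cluster_genes Character vector of gene symbols.
#' @param phenotypes List of `phenotype_annotation` records.
#' @param background Character vector, the gene universe.
#' @param fe_display Display threshold (default 1.0).
#' @return Data.frame `phenotype_id`, `name`, `k`, `n`, `K`, `N`, `FE`,
#'   ranked by FE descending; attribute `n_skipped`.
#' @export
phenotype_fe <- function(cluster_genes, phenotypes, background,
                         fe_display = 1.0) {
  background <- sort(unique(norm_symbol(background)))
  q <- intersect(unique(norm_symbol(cluster_genes)), background)
  if (!length(q))
    stop("cluster gene set has empty intersection with the background universe")
  n <- length(q); N <- length(background)
  rows <- lapply(phenotypes, function(ph) {
    g <- intersect(ph$genes, background)
    if (!length(g)) return(NULL)
    k <- length(intersect(q, g))
    data.frame(phenotype_id = ph$phenotype_id, name = ph$name,
               k = k, n = n, K = length(g), N = N,
               FE = fold_enrichment(k, n, length(g), N),
               stringsAsFactors = FALSE)
  })
  skipped <- sum(vapply(rows, is.null, logical(1)))
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(phenotype_id = character(0), name = character(0),
                      k = integer(0), n = integer(0), K = integer(0),
                      N = integer(0), FE = numeric(0), stringsAsFactors = FALSE)
  out <- out[out$FE > fe_display, , drop = FALSE]
  out <- out[order(-out$FE), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_skipped") <- skipped
  out
}

#' Intersection of a cluster gene set with an ASD-linked gene list
#'
#' @param cluster_genes Character vector of gene symbols.
#' @param asd_list Character vector of ASD-linked symbols.
#' @return List with `count` and `genes` (sorted intersection).
#' @export
sfari_overlap <- function(cluster_genes, asd_list) {
  hit <- intersect(unique(norm_symbol(cluster_genes)),
                   unique(norm_symbol(asd_list)))
  list(count = length(hit), genes = sort(hit))
}
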