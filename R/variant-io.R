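#' Default column-name map for VariCarta-dialect tables
#'
#' Maps the internal field names used throughout the package to the column
#' headers expected in the input CSV. Override individual entries to ingest
#' tables whose headers differ from the VariCarta export.
#'
#' @param individual_id,gene_symbol,sequencing_type,variant_category,chrom,pos,ref,alt,source_ref
#'   Column header holding the corresponding field. `chrom`, `pos`, `ref`,
#'   `alt` and `source_ref` may be `NA` if the table lacks them.
#' @return Named character vector of length 9.
#' @export
varicarta_columns <- function(individual_id = "individual_id",
                              gene_symbol = "gene_symbol",
                              sequencing_type = "sequencing_type",
                              variant_category = "variant_category",
                              chrom = "chromosome",
                              pos = "position",
                              ref = "ref",
                              alt = "alt",
                              source_ref = "source_paper") {
  c(individual_id = individual_id, gene_symbol = gene_symbol,
    sequencing_type = sequencing_type, variant_category = variant_category,
    chrom = chrom, pos = pos, ref = ref, alt = alt, source_ref = source_ref)
}

#' Sequencing-type vocabulary
#'
#' Case-insensitive map from free-text sequencing-type labels to the internal
#' enum \{whole_genome, exome, targeted, other\}. Labels not in the vocabulary
#' are mapped to `NA` and counted as unmapped (never silently dropped).
#'
#' @return Named character vector: names are lower-cased source labels,
#'   values are enum levels.
#' @export
sequencing_vocabulary <- function() {
  c("whole genome sequencing" = "whole_genome",
    "whole-genome sequencing" = "whole_genome",
    "genome sequencing"       = "whole_genome",
    "wgs"                     = "whole_genome",
    "whole_genome"            = "whole_genome",
    "exome sequencing"        = "exome",
    "whole exome sequencing"  = "exome",
    "wes"                     = "exome",
    "exome"                   = "exome",
    "targeted sequencing"     = "targeted",
    "targeted"                = "targeted",
    "other"                   = "other")
}

norm_symbol <- function(x) toupper(trimws(as.character(x)))

#' Read a variant-event table in the VariCarta CSV dialect
#'
#' Each data row becomes one variant event: one literature-reported
#' observation of a variant in one individual. Gene symbols are upper-cased
#' and trimmed; sequencing-type labels are resolved case-insensitively
#' against [sequencing_vocabulary()]. Unresolvable labels are kept with
#' `sequencing_type = NA` and counted in the `n_unmapped_sequencing`
#' attribute. No alias/HGNC resolution and no coordinate arithmetic is
#' performed; `chrom`/`pos`/`ref`/`alt` are pass-through text.
#'
#' @param path Path to a CSV (or TSV, see `sep`) file with a header row.
#' @param columns Column-name map from [varicarta_columns()].
#' @param vocabulary Sequencing-type map from [sequencing_vocabulary()].
#' @param sep Field delimiter; `","` (default) or `"\t"`.
#' @return A `variant_events` data.frame with columns `individual_id`,
#'   `gene_symbol`, `sequencing_type`, `variant_category`, `chrom`, `pos`,
#'   `ref`, `alt`, `source_ref`, and attributes `n_rows_read` and
#'   `n_unmapped_sequencing`.
#' @examples
#' csv <- tempfile(fileext = ".csv")
#' writeLines(c("individual_id,gene_symbol,sequencing_type,variant_category,chromosome,position,ref,alt,source_paper",
#'              "ind1,Shank3,whole genome sequencing,nonsynonymous SNV,22,51160000,A,G,p1"), csv)
#' ev <- read_varicarta(csv)
#' ev$gene_symbol  # "SHANK3"
#' @export
read_varicarta <- function(path, columns = varicarta_columns(),
                           vocabulary = sequencing_vocabulary(), sep = ",") {
  if (!file.exists(path)) stop("variant table not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           colClasses = "character", comment.char = "",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           fileEncoding = "UTF-8")
  required <- c("individual_id", "gene_symbol", "sequencing_type")
  for (f in required) {
    cn <- columns[[f]]
    if (is.na(cn) || !cn %in% names(raw))
      stop("required column missing from ", path, ": '", cn, "' (field ", f, ")")
  }
  get_col <- function(f) {
    cn <- columns[[f]]
    if (!is.na(cn) && cn %in% names(raw)) raw[[cn]] else rep(NA_character_, nrow(raw))
  }
  seq_raw <- tolower(trimws(get_col("sequencing_type")))
  seq_mapped <- unname(vocabulary[seq_raw])
  ev <- data.frame(
    individual_id    = trimws(get_col("individual_id")),
    gene_symbol      = norm_symbol(get_col("gene_symbol")),
    sequencing_type  = seq_mapped,
    variant_category = get_col("variant_category"),
    chrom            = get_col("chrom"),
    pos              = get_col("pos"),
    ref              = get_col("ref"),
    alt              = get_col("alt"),
    source_ref       = get_col("source_ref"),
    stringsAsFactors = FALSE)
  if (nrow(ev) > 0 && any(!nzchar(ev$individual_id) | !nzchar(ev$gene_symbol)))
    stop("rows with empty individual id or gene symbol: ",
         sum(!nzchar(ev$individual_id) | !nzchar(ev$gene_symbol)))
  attr(ev, "n_rows_read") <- nrow(ev)
  attr(ev, "n_unmapped_sequencing") <- if (nrow(ev)) sum(is.na(seq_mapped)) else 0L
  class(ev) <- c("variant_events", "data.frame")
  ev
}

as_variant_events <- function(df) {
  stopifnot(is.data.frame(df))
  class(df) <- unique(c("variant_events", class(df)))
  df
}

#' Remove duplicated variant events
#'
#' The same variant in the same individual may be reported by several source
#' papers; one representative per duplicate group is kept (first occurrence
#' in input order). The duplicate key is `(individual_id, chrom, pos, ref,
#' alt)` when the genomic descriptor is complete, falling back to
#' `(individual_id, gene_symbol, variant_category)` when any coordinate field
#' is missing.
#'
#' @param events A `variant_events` data.frame.
#' @return Deduplicated `variant_events` with attribute `n_removed`.
#' @export
deduplicate_events <- function(events) {
  if (nrow(events) == 0) {
    attr(events, "n_removed") <- 0L
    return(events)
  }
  coord_ok <- !is.na(events$chrom) & nzchar(events$chrom) &
    !is.na(events$pos) & nzchar(events$pos) &
    !is.na(events$ref) & nzchar(events$ref) &
    !is.na(events$alt) & nzchar(events$alt)
  key <- ifelse(coord_ok,
                paste("g", events$individual_id, events$chrom, events$pos,
                      events$ref, events$alt, sep = "\r"),
                paste("f", events$individual_id, events$gene_symbol,
                      events$variant_category, sep = "\r"))
  keep <- !duplicated(key)
  out <- events[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(!keep)
  attr(out, "n_rows_read") <- attr(events, "n_rows_read")
  attr(out, "n_unmapped_sequencing") <- attr(events, "n_unmapped_sequencing")
  class(out) <- class(events)
  out
}

#' Filter variant events by sequencing type
#'
#' Variant yield depends strongly on the assay, so analyses are restricted to
#' comparable sequencing types (the reference analysis keeps whole-genome
#' events only).
#'
#' @param events A `variant_events` data.frame.
#' @param keep Non-empty character vector of enum levels to retain
#'   (subset of `whole_genome`, `exome`, `targeted`, `other`).
#' @return Filtered `variant_events`; attribute `retained_fraction` holds the
#'   kept/total ratio.
#' @export
filter_by_sequencing <- function(events, keep = "whole_genome") {
  if (length(keep) == 0) stop("'keep' must name at least one sequencing type")
  bad <- setdiff(keep, c("whole_genome", "exome", "targeted", "other"))
  if (length(bad)) stop("unknown sequencing type(s): ", paste(bad, collapse = ", "))
  sel <- !is.na(events$sequencing_type) & events$sequencing_type %in% keep
  out <- events[sel, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "retained_fraction") <- if (nrow(events)) sum(sel) / nrow(events) else NA_real_
  class(out) <- class(events)
  out
}

#' Per-sequencing-type event counts
#'
#' Tabulates events by sequencing type (including unmapped, reported as
#' `unmapped`). Useful before and after deduplication since reported
#' per-type shares can differ between the raw and deduplicated tables.
#'
#' @param events A `variant_events` data.frame.
#' @return Named integer vector of counts.
#' @export
sequencing_census <- function(events) {
  lab <- ifelse(is.na(events$sequencing_type), "unmapped", events$sequencing_type)
  table(factor(lab, levels = c("whole_genome", "exome", "targeted", "other", "unmapped")))
}

#' Group variant events into per-individual gene sets
#'
#' Collapses a (deduplicated) event table to one record per individual with
#' the set of distinct variated gene symbols. Order and multiplicity carry no
#' information downstream: the encoder input is a fixed-width vector over the
#' embedding vocabulary.
#'
#' @param events A `variant_events` data.frame (deduplicate first).
#' @return An `individual_gene_sets` object: named list of character vectors
#'   (sorted unique gene symbols), names are individual ids in first-seen
#'   order; attribute `n_individuals`.
#' @export
group_individuals <- function(events) {
  ids <- unique(events$individual_id)
  sets <- lapply(split(events$gene_symbol, factor(events$individual_id, levels = ids)),
                 function(g) sort(unique(g)))
  attr(sets, "n_individuals") <- length(sets)
  class(sets) <- "individual_gene_sets"
  sets
}

#' @export
print.individual_gene_sets <- function(x, ...) {
  sizes <- lengths(x)
  cat("Individual gene sets:", length(x), "individuals;",
      "gene-set sizes", if (length(x)) paste0("[", min(sizes), ", ", max(sizes), "]") else "[]",
      "\n")
  invisible(x)
}

#' Write a deduplicated event table as TSV
#'
#' @param events A `variant_events` data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events_tsv <- function(events, path) {
  utils::write.table(as.data.frame(events), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Ingestion report for a variant table
#'
#' Summarises one ingestion run: rows read, duplicates removed, unmapped
#' sequencing types, per-type counts raw and after deduplication, individuals.
#'
#' @param raw Events as returned by [read_varicarta()].
#' @param dedup Events after [deduplicate_events()].
#' @return A list suitable for JSON serialisation.
#' @export
ingestion_report <- function(raw, dedup) {
  list(rows_read = nrow(raw),
       duplicates_removed = attr(dedup, "n_removed"),
       unmapped_sequencing = attr(raw, "n_unmapped_sequencing"),
       per_type_raw = as.list(sequencing_census(raw)),
       per_type_dedup = as.list(sequencing_census(dedup)),
       individuals = length(unique(dedup$individual_id)))
}
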