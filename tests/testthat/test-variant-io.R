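test_that("toy tables parse with normalised fields and counted unmapped types", {
  path <- write_toy_varicarta(c(
    "i1, shank3 ,whole genome sequencing,nonsynonymous SNV,22,51160000,A,G,p1",
    "i2,CHD8,Exome Sequencing,stopgain,14,21850000,C,T,p1",
    "i3,SCN2A,ion torrent,frameshift insertion,2,165290000,G,GA,p2"))
  ev <- read_varicarta(path)
  expect_s3_class(ev, "variant_events")
  expect_equal(nrow(ev), 3L)
  expect_equal(ev$gene_symbol, c("SHANK3", "CHD8", "SCN2A"))
  expect_equal(ev$sequencing_type, c("whole_genome", "exome", NA))
  expect_equal(attr(ev, "n_rows_read"), 3L)
  expect_equal(attr(ev, "n_unmapped_sequencing"), 1L)
  expect_equal(unname(sequencing_census(ev)[["unmapped"]]), 1L)
})

test_that("header-only files give an empty event list, missing columns are fatal", {
  path <- write_toy_varicarta(character(0))
  ev <- read_varicarta(path)
  expect_equal(nrow(ev), 0L)
  bad <- tempfile(fileext = ".csv")
  writeLines(c("individual_id,sequencing_type", "i1,wgs"), bad)
  expect_error(read_varicarta(bad), "gene_symbol")
})

test_that("deduplication keys on coordinates when complete, else gene+category", {
  path <- write_toy_varicarta(c(
    "i1,SHANK3,wgs,nonsynonymous SNV,22,51160000,A,G,p1",
    "i1,SHANK3,wgs,nonsynonymous SNV,22,51160000,A,G,p2",   # same event, other paper
    "i1,SHANK3,wgs,nonsynonymous SNV,22,51160999,A,G,p1",   # different position
    "i2,CHD8,wgs,stopgain,,,,,p1",
    "i2,CHD8,wgs,stopgain,,,,,p3",                          # fallback-key duplicate
    "i2,CHD8,wgs,frameshift insertion,,,,,p1"))             # different category
  ev <- read_varicarta(path)
  dd <- deduplicate_events(ev)
  expect_equal(nrow(dd), 4L)
  expect_equal(attr(dd, "n_removed"), 2L)
  expect_equal(dd$source_ref[1], "p1")   # first occurrence retained
  # idempotence
  dd2 <- deduplicate_events(dd)
  expect_equal(as.data.frame(dd2), as.data.frame(dd), ignore_attr = TRUE)
  expect_equal(attr(dd2, "n_removed"), 0L)
})

test_that("already-unique tables pass through deduplication unchanged", {
  path <- write_toy_varicarta(c(
    "i1,A,wgs,snv,1,100,A,G,p1",
    "i2,A,wgs,snv,1,100,A,G,p1",
    "i1,B,wgs,snv,1,200,C,T,p1"))
  ev <- read_varicarta(path)
  expect_equal(as.data.frame(deduplicate_events(ev)), as.data.frame(ev),
               ignore_attr = TRUE)
})

test_that("sequencing filter keeps exactly the requested types and reports the fraction", {
  path <- write_toy_varicarta(c(
    "i1,A,whole genome sequencing,snv,1,1,A,G,p1",
    "i2,B,exome sequencing,snv,1,2,A,G,p1",
    "i3,C,targeted sequencing,snv,1,3,A,G,p1",
    "i4,D,whole genome sequencing,snv,1,4,A,G,p1"))
  ev <- read_varicarta(path)
  keep_all <- filter_by_sequencing(ev, c("whole_genome", "exome", "targeted", "other"))
  expect_equal(keep_all$individual_id, ev$individual_id)
  wgs <- filter_by_sequencing(ev, "whole_genome")
  expect_equal(nrow(wgs), 2L)
  expect_equal(attr(wgs, "retained_fraction"), 0.5)
  expect_error(filter_by_sequencing(ev, character(0)), "at least one")
  expect_error(filter_by_sequencing(ev, "nanopore"), "unknown")
})

test_that("grouping collapses events to per-individual gene sets", {
  path <- write_toy_varicarta(c(
    "i1,A,wgs,snv,1,1,A,G,p1",
    "i1,A,wgs,snv,1,2,A,G,p1",   # same gene again
    "i1,B,wgs,snv,1,3,A,G,p1",
    "i2,C,wgs,snv,1,4,A,G,p1"))
  sets <- group_individuals(deduplicate_events(read_varicarta(path)))
  expect_equal(length(sets), 2L)
  expect_equal(sets[["i1"]], c("A", "B"))
  expect_equal(sets[["i2"]], "C")
  expect_equal(attr(sets, "n_individuals"), 2L)
})

test_that("gene-set sizes never exceed the deduplicated event count, and filtering commutes with grouping", {
  set.seed(31)
  for (rep in 1:5) {
    cfg <- synthetic_config(n_genes = 50, embed_dim = 10, n_modules = 2,
                            n_subtypes = 2, individuals_per_subtype = 8,
                            genes_per_individual = 6, duplicate_rate = 0.2,
                            oov_rate = 0, seed = 100 + rep)
    ge <- make_gene_embedding(cfg)
    coh <- make_variant_cohort(cfg, ge$modules)
    csv <- tempfile(fileext = ".csv")
    utils::write.table(coh$events, csv, sep = ",", quote = FALSE, row.names = FALSE)
    ev <- deduplicate_events(read_varicarta(csv))
    sets <- group_individuals(ev)
    expect_lte(sum(lengths(sets)), nrow(ev))
    # filter-then-group equals group of the filtered table
    filt <- filter_by_sequencing(ev, "whole_genome")
    s1 <- group_individuals(filt)
    keep <- ev$sequencing_type %in% "whole_genome"
    s2 <- group_individuals(ev[keep, , drop = FALSE])
    expect_equal(unclass(s1)[order(names(s1))], unclass(s2)[order(names(s2))],
                 ignore_attr = TRUE)
  }
})
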