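test_that("Gene2Vec-format files load with exact values and strict validation", {
  path <- tempfile()
  writeLines(c("g1 0.1 -0.5 0.3 0.0",
               "G2 1 2 3 4",
               "g3 -1.5 0 0 2.5"), path)
  emb <- load_gene_embedding(path)
  expect_equal(length(emb$vocabulary), 3L)
  expect_equal(emb$dim, 4L)
  expect_equal(unname(emb$vectors["G1", ]), c(0.1, -0.5, 0.3, 0.0))
  expect_equal(unname(emb$vectors["G3", ]), c(-1.5, 0, 0, 2.5))

  dup <- tempfile(); writeLines(c("g1 1 2", "G1 3 4"), dup)
  expect_error(load_gene_embedding(dup), "G1")
  ragged <- tempfile(); writeLines(c("g1 1 2", "g2 3"), ragged)
  expect_error(load_gene_embedding(ragged), "line 2")
  nonnum <- tempfile(); writeLines(c("g1 1 2", "g2 3 x"), nonnum)
  expect_error(load_gene_embedding(nonnum), "non-numeric")
})

test_that("gene_scalar is the true per-gene component maximum", {
  emb <- toy_embedding()
  expect_equal(unname(gene_scalar("A", emb)), 0.3)
  expect_equal(unname(gene_scalar("B", emb)), -0.1)  # maximum may be negative
  expect_equal(unname(gene_scalar("C", emb)), 0)
  expect_error(gene_scalar("ZZZ", emb), "vocabulary")
  # brute-force linear-scan oracle on a random 200-dim vector
  set.seed(4)
  v <- matrix(rnorm(200), 1, dimnames = list("R1", NULL))
  emb200 <- gene_embedding(v)
  scan_max <- -Inf
  for (x in v[1, ]) if (x > scan_max) scan_max <- x
  expect_identical(unname(gene_scalar("R1", emb200)), scan_max)
})

test_that("phenotype matrix follows the max-of-components rule entry by entry", {
  emb <- toy_embedding()
  ann <- list(phenotype_annotation("HP:1", "p1", c("A", "C")),
              phenotype_annotation("HP:2", "p2", c("B", "NOTAGENE")),
              phenotype_annotation("HP:3", "p3", c("OOV1", "OOV2")))
  pm <- build_phenotype_matrix(ann, emb)
  m <- as.matrix(pm$values)
  expect_equal(unname(m), rbind(c(0.3, 0, 0), c(0, -0.1, 0), c(0, 0, 0)))
  # annotated gene with a 0.0 maximum is still a stored entry
  expect_equal(length(pm$values@x), 3L)  # A, C (0.0), B stored; OOV row empty
  expect_equal(pm$row_gene_counts, c(2L, 1L, 0L))
  expect_equal(pm$flagged, c(FALSE, FALSE, TRUE))
  expect_equal(colnames(pm$values), emb$vocabulary)
  # stored entries = sum over rows of in-vocabulary annotation counts
  expect_equal(length(pm$values@x), sum(pm$row_gene_counts))
})

test_that("individual vectors share the phenotype column space and drop OOV genes", {
  emb <- toy_embedding()
  v0 <- build_individual_vector(character(0), emb)
  expect_equal(sum(v0 != 0), 0)
  expect_equal(length(v0), 3L)
  v1 <- build_individual_vector("A", emb)
  expect_equal(as.numeric(v1), c(0.3, 0, 0))
  vm <- build_individual_vector(c("A", "B", "NOPE1", "NOPE2"), emb)
  expect_equal(as.numeric(vm), c(0.3, -0.1, 0))
  expect_equal(attr(vm, "n_dropped"), 2L)
  # monotone: adding a gene never removes a stored component
  sup1 <- which(as.numeric(v1) != 0)
  supm <- which(as.numeric(vm) != 0)
  expect_true(all(sup1 %in% supm))
  # a gene set equal to a phenotype's in-vocabulary annotation equals that row
  ann <- list(phenotype_annotation("HP:1", "p1", c("A", "B")))
  pm <- build_phenotype_matrix(ann, emb)
  vset <- build_individual_vector(c("A", "B"), emb)
  expect_equal(as.numeric(vset), as.numeric(pm$values[1, ]))
})

test_that("the individual matrix stacks individual vectors and flags empty sets", {
  emb <- toy_embedding()
  sets <- list(i1 = c("A", "B"), i2 = "OOVX", i3 = "C")
  m <- build_individual_matrix(sets, emb)
  expect_equal(dim(m), c(3L, 3L))
  expect_equal(as.numeric(m["i1", ]), as.numeric(build_individual_vector(c("A", "B"), emb)))
  expect_equal(attr(m, "flagged"), c(FALSE, TRUE, FALSE))
  expect_equal(attr(m, "n_dropped"), 1L)
})

test_that("phenotype annotation files in genes_to_phenotype dialect aggregate per term", {
  path <- tempfile()
  writeLines(c("gene_symbol\thpo_id\thpo_name",
               "shank3\tHP:0001250\tSeizure",
               "SCN2A\tHP:0001250\tSeizure",
               "CHD8\tHP:0000256\tMacrocephaly"), path)
  ann <- read_phenotype_annotations(path)
  expect_equal(length(ann), 2L)
  expect_equal(ann[[1]]$phenotype_id, "HP:0001250")
  expect_equal(ann[[1]]$genes, c("SCN2A", "SHANK3"))
  expect_equal(ann[[2]]$name, "Macrocephaly")
})
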