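test_that("fold enrichment is the observed/expected ratio with strict count checks", {
  expect_equal(fold_enrichment(0, 10, 20, 100), 0)
  expect_equal(fold_enrichment(20, 100, 20, 100), 1)     # cluster = background
  expect_equal(fold_enrichment(5, 50, 20, 1000), 5)      # expected 1, observed 5
  expect_error(fold_enrichment(1, 0, 20, 100), "undefined")
  expect_error(fold_enrichment(1, 10, 0, 100), "undefined")
  expect_error(fold_enrichment(15, 10, 20, 100), "inconsistent")
  # mixture property: FE of a union of disjoint clusters is the n-weighted
  # mean of the parts, hence lies between them
  set.seed(30)
  for (i in 1:20) {
    N <- 500; K <- sample(10:100, 1)
    nA <- sample(5:60, 1); nB <- sample(5:60, 1)
    kA <- sample(0:min(nA, K), 1)
    kB <- sample(0:min(nB, K - kA), 1)   # disjoint clusters share the term's K
    feA <- fold_enrichment(kA, nA, K, N)
    feB <- fold_enrichment(kB, nB, K, N)
    feU <- fold_enrichment(kA + kB, nA + nB, K, N)
    expect_gte(feU, min(feA, feB) - 1e-12)
    expect_lte(feU, max(feA, feB) + 1e-12)
  }
})

test_that("two-tailed Fisher p matches full hypergeometric enumeration", {
  # margins 4/4 in N=8 at k=3: enumeration gives 34/70
  expect_equal(fisher_p(3, 4, 4, 8), 34 / 70, tolerance = 1e-12)
  # margins 2/2 in N=4 at k=2: support probs {1/6, 4/6, 1/6} -> p = 1/3
  expect_equal(fisher_p(2, 2, 2, 4), 1 / 3, tolerance = 1e-12)
  # independence-exact table: observed probability is the modal one -> p = 1
  expect_equal(fisher_p(2, 10, 20, 100), 1)
  expect_error(fisher_p(0, 10, 95, 100), "negative cell")
  # random tables vs stats::fisher.test (N <= 200)
  set.seed(31)
  for (i in 1:60) {
    N <- sample(10:200, 1)
    K <- sample(1:(N - 1), 1)
    n <- sample(1:(N - 1), 1)
    k <- sample(max(0, n + K - N):min(n, K), 1)
    ref <- stats::fisher.test(matrix(c(k, n - k, K - k, N - n - K + k), 2))$p.value
    expect_lt(abs(fisher_p(k, n, K, N) - ref), 1e-12)
  }
})

test_that("Benjamini-Hochberg adjustment follows the step-up rule in input order", {
  expect_equal(bh_fdr(0.02), 0.02)
  expect_equal(bh_fdr(rep(0.3, 4)), rep(0.3, 4))
  expect_equal(bh_fdr(c(0.01, 0.04, 0.03)), c(0.03, 0.04, 0.04))
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(32)
  p <- runif(25)
  perm <- sample(25)
  expect_equal(bh_fdr(p)[perm], bh_fdr(p[perm]))
  expect_true(all(bh_fdr(p) >= p) && all(bh_fdr(p) <= 1))
})

test_that("cluster enrichment computes counts by hand-checkable construction and tiers the report", {
  bg <- sprintf("G%03d", 1:100)
  terms <- list("T:1" = list(name = "planted", namespace = "biological_process",
                             genes = bg[1:10]),
                "T:2" = list(name = "everything", namespace = "cellular_component",
                             genes = bg))
  db <- term_db(terms, bg)
  cluster <- c(bg[1:8], bg[90:91])          # 8 of the 10 term genes, n = 10
  res <- enrich_cluster(cluster, db)
  r1 <- res[res$term_id == "T:1", ]
  expect_equal(r1$k, 8L)
  expect_equal(r1$FE, 8 / (10 * 10 / 100))  # = 8
  expect_equal(r1$p, fisher_p(8, 10, 10, 100))
  expect_equal(res$FDR, bh_fdr(res$p))   # one family across namespaces
  expect_equal(r1$report_tier, "primary")
  # a term covering the whole background has FE exactly 1, never primary
  r2 <- res[res$term_id == "T:2", ]
  expect_equal(r2$FE, 1)
  expect_false(r2$report_tier == "primary")
  expect_error(enrich_cluster("NOTHERE", db), "empty intersection")
})

test_that("report falls back to top terms by FDR when nothing clears the FE bar, and may be empty", {
  set.seed(33)
  bg <- sprintf("G%03d", 1:200)
  # mildly enriched big term: significant FDR but FE < 1.5
  terms <- list("T:big" = list(name = "big", namespace = "biological_process",
                               genes = bg[1:120]),
                "T:null" = list(name = "null", namespace = "molecular_function",
                                genes = bg[150:170]))
  db <- term_db(terms, bg)
  cluster <- bg[1:60]                       # k = 60 of K = 120, FE = 60/(60*120/200) = 1.67?
  res <- enrich_cluster(cluster, db, fe_min = 2.0)
  sig <- res$FDR < 0.005
  expect_true(any(sig))
  expect_true(all(res$report_tier[sig] == "fallback"))
  expect_true(all(res$report_tier[!sig] == "none"))
  # a cluster matching the null expectation of every term (two-tailed tests
  # also flag depletion, so "disjoint" would not be null here)
  res2 <- enrich_cluster(bg[c(1:15, 121:128, 150:151)], db)
  expect_true(all(res2$FDR > 0.5))
  expect_true(all(res2$report_tier == "none"))
})

test_that("phenotype fold enrichment reports FE only, filtered and ranked", {
  bg <- sprintf("G%04d", 1:1000)
  ph <- list(phenotype_annotation("HP:1", "match", bg[1:10]),
             phenotype_annotation("HP:2", "disjoint", bg[900:920]),
             phenotype_annotation("HP:3", "oov", "NOTINBG"))
  out <- phenotype_fe(bg[1:10], ph, bg)
  expect_equal(out$phenotype_id, "HP:1")
  expect_equal(out$FE, 10 / (10 * 10 / 1000))   # = 100
  expect_equal(attr(out, "n_skipped"), 1L)      # HP:3 skipped
  expect_false("HP:2" %in% out$phenotype_id)    # FE 0 filtered by FE > 1
  expect_false("p" %in% names(out))
})

test_that("randomised clusters have mean phenotype FE compatible with 1", {
  set.seed(34)
  bg <- sprintf("G%04d", 1:500)
  ph <- list(phenotype_annotation("HP:1", "a", sample(bg, 40)),
             phenotype_annotation("HP:2", "b", sample(bg, 25)))
  n_perm <- 300
  fes <- replicate(n_perm, {
    cl <- sample(bg, 30)
    vapply(ph, function(p)
      fold_enrichment(length(intersect(cl, p$genes)), 30, length(p$genes), 500),
      numeric(1))
  })
  m <- mean(fes)
  se <- sd(colMeans(fes)) / sqrt(n_perm)
  expect_lt(abs(m - 1), 3 * se)
})

test_that("ASD-list overlap is exact set intersection", {
  expect_equal(sfari_overlap(c("A", "B"), c("C", "D"))$count, 0)
  expect_equal(sfari_overlap(c("A", "B"), c("A", "B", "C"))$count, 2)
  set.seed(35)
  U <- sprintf("G%03d", 1:300)
  for (i in 1:10) {
    a <- sample(U, sample(10:50, 1))
    b <- sample(U, sample(10:50, 1))
    ref <- sum(!is.na(match(unique(a), unique(b))))   # independent route
    expect_equal(sfari_overlap(a, b)$count, ref)
    expect_equal(sfari_overlap(a, b)$genes, sort(intersect(a, b)))
  }
})
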