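Package: asdclust
Title: Genetic Subtyping of ASD Cohorts from Variant-Event Catalogues
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Stratifies individuals with autism spectrum disorder (ASD) into
    genetic subtypes from literature-curated variant-event tables. Per-individual
    variated-gene sets are embedded through a gene co-expression embedding
    combined with phenotype-to-gene annotations (max-of-components phenotype
    matrix), compressed to a 64-dimensional latent space by a dense autoencoder,
    projected with UMAP and clustered with HDBSCAN under an exhaustive grid
    search scored by the density-based clustering validation (DBCV) index.
    Resulting clusters are profiled by fold-enrichment analysis against ontology
    terms and phenotypes and intersected with curated ASD gene lists. Includes a
    synthetic-data generator with planted gene modules and latent subtypes so
    the full pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    tools,
    uwot
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
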