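test_that("config derives a strictly decreasing geometric funnel ending at the latent width", {
  cfg <- autoencoder_config(500, seed = 1)
  expect_equal(length(cfg$layer_widths), 6L)
  expect_equal(cfg$layer_widths[6], 64L)
  expect_true(all(diff(c(500L, cfg$layer_widths)) < 0))
  expect_error(autoencoder_config(500), "seed")
  expect_error(autoencoder_config(500, layer_widths = c(400, 300, 200, 100, 80, 70),
                                  seed = 1), "latent_dim")
})

test_that("training is deterministic under a fixed seed and the loss decreases", {
  set.seed(2)
  X <- matrix(rnorm(60 * 120), 60, 120)
  cfg <- autoencoder_config(120, epochs = 30, seed = 7)
  m1 <- train_autoencoder(X, cfg)
  m2 <- train_autoencoder(X, cfg)
  probe <- matrix(rnorm(5 * 120), 5, 120)
  expect_identical(predict(m1, probe), predict(m2, probe))
  expect_lte(m1$history[length(m1$history)], m1$history[1])
  expect_error(train_autoencoder(X[1, , drop = FALSE], cfg), "at least 2")
})

test_that("a 64-dim bottleneck reconstructs low-rank data almost exactly", {
  set.seed(5)
  W <- matrix(rnorm(5 * 500), 5, 500)
  X <- matrix(rnorm(200 * 5), 200, 5) %*% W
  m <- train_autoencoder(X, autoencoder_config(500, seed = 9))
  R <- predict(m, X, type = "reconstruction")
  expect_lt(mean((R - X)^2), 0.05 * mean((X - mean(X))^2))
  # latent geometry preserves input-space distances on held-out probes
  probes <- matrix(rnorm(30 * 5), 30, 5) %*% W
  Z <- predict(m, probes)
  d_in <- as.numeric(dist(probes))
  d_lat <- as.numeric(dist(Z))
  expect_gt(cor(d_in, d_lat, method = "spearman"), 0.7)
})

test_that("encoding individuals yields one 64-vector per individual, equal for equal sets", {
  emb <- gene_embedding(matrix(rnorm(80 * 10), 80, 10,
                               dimnames = list(sprintf("G%02d", 1:80), NULL)))
  ann <- lapply(1:40, function(p)
    phenotype_annotation(sprintf("HP:%d", p), "x",
                         sample(emb$vocabulary, 8)))
  pm <- build_phenotype_matrix(ann, emb)
  model <- train_autoencoder(pm, autoencoder_config(80, latent_dim = 16,
                                                    n_layers = 2, epochs = 30,
                                                    seed = 3))
  sets <- list(a = c("G01", "G02"), b = c("G02", "G01"), c = character(0),
               d = "G05")
  lat <- encode_individuals(sets, emb, model)
  expect_equal(dim(lat), c(4L, 16L))
  expect_equal(lat["a", ], lat["b", ])                       # set semantics
  zero_img <- predict(model, matrix(0, 1, 80))
  expect_equal(unname(lat["c", ]), unname(zero_img[1, ]))    # empty set
  expect_true(all(is.finite(lat)))
  # permutation of the individual list permutes rows identically
  lat2 <- encode_individuals(sets[c(4, 2, 1, 3)], emb, model)
  expect_equal(lat2["d", ], lat["d", ])
  expect_error(encode_individuals(sets, toy_embedding(), model), "vocabulary size")
})

test_that("a saved model restores to identical predictions", {
  set.seed(8)
  X <- matrix(rnorm(40 * 60), 40, 60)
  m <- train_autoencoder(X, autoencoder_config(60, latent_dim = 8, n_layers = 3,
                                               epochs = 10, seed = 4))
  f <- tempfile(fileext = ".json")
  save_autoencoder(m, f)
  m2 <- load_autoencoder(f)
  probe <- matrix(rnorm(3 * 60), 3, 60)
  expect_equal(predict(m2, probe), predict(m, probe), tolerance = 1e-12)
  expect_equal(predict(m2, probe, type = "reconstruction"),
               predict(m, probe, type = "reconstruction"), tolerance = 1e-12)
})
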