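#' Configuration for the dense autoencoder
#'
#' A symmetric funnel: 6 dense encoder layers narrowing from the input width
#' to the 64-component latent space, mirrored by 6 decoder layers. Unless
#' given, layer widths follow geometric interpolation between `input_dim` and
#' `latent_dim` (each width is the rounded geometric step), the standard
#' reading of a symmetric deep autoencoder. Hidden units are rectifiers; the
#' latent layer and the output are linear so the code space and the
#' reconstruction are unconstrained. Loss is per-entry mean squared error.
#'
#' @param input_dim Number of input components (G, the vocabulary size).
#' @param latent_dim Latent width; default 64.
#' @param n_layers Encoder depth (same for the decoder); default 6.
#' @param layer_widths Optional integer vector of length `n_layers` ending at
#'   `latent_dim`, strictly decreasing from below `input_dim`.
#' @param epochs,batch_size,learning_rate Training scalars (defaults 200, 32,
#'   1e-3, conventional for a dense autoencoder with adaptive-moment updates).
#' @param scale_input Min–max scale inputs to [0, 1] before training/encoding;
#'   off by default because embedding components already share a scale.
#' @param seed Integer seed (required); training is deterministic given
#'   (config, data, seed).
#' @return An `autoencoder_config` list.
#' @export
autoencoder_config <- function(input_dim, latent_dim = 64, n_layers = 6,
                               layer_widths = NULL, epochs = 200,
                               batch_size = 32, learning_rate = 1e-3,
                               scale_input = FALSE, seed) {
  if (missing(seed)) stop("'seed' is required")
  stopifnot(input_dim > latent_dim, latent_dim >= 1, n_layers >= 1)
  if (is.null(layer_widths)) {
    r <- (latent_dim / input_dim)^(1 / n_layers)
    layer_widths <- round(input_dim * r^(seq_len(n_layers)))
    layer_widths[n_layers] <- latent_dim
  }
  if (length(layer_widths) != n_layers || layer_widths[n_layers] != latent_dim)
    stop("layer_widths must have length n_layers and end at latent_dim")
  if (any(diff(c(input_dim, layer_widths)) >= 0))
    stop("layer widths must decrease strictly from input_dim to latent_dim")
  structure(list(input_dim = as.integer(input_dim),
                 latent_dim = as.integer(latent_dim),
                 n_layers = as.integer(n_layers),
                 layer_widths = as.integer(layer_widths),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 scale_input = isTRUE(scale_input),
                 seed = as.integer(seed)),
            class = "autoencoder_config")
}

relu <- function(x) { x[x < 0] <- 0; x }

ae_forward <- function(W, b, act_relu, X) {
  acts <- vector("list", length(W) + 1L)
  acts[[1]] <- X
  for (l in seq_along(W)) {
    z <- acts[[l]] %*% W[[l]]
    z <- sweep(z, 2, b[[l]], `+`)
    acts[[l + 1L]] <- if (act_relu[l]) relu(z) else z
  }
  acts
}

#' Train the dense autoencoder on phenotype vectors
#'
#' Trains on the rows of the phenotype matrix (flagged all-zero rows are
#' excluded by default) to reconstruct them through the latent bottleneck;
#' the frozen encoder half is then used to embed individuals. Individual
#' vectors are never used for training: the representation is learned from
#' phenotype structure alone, and applied to individuals afterwards.
#'
#' @param matrix A `phenotype_matrix`, or a numeric matrix of training rows.
#' @param cfg An [autoencoder_config()]; if `NULL`, defaults are derived from
#'   the data with `seed` taken from `seed`.
#' @param seed Convenience seed used only when `cfg` is `NULL`.
#' @param include_flagged Train on flagged all-zero phenotype rows too
#'   (default `FALSE`).
#' @return A `gene_autoencoder` object with the frozen parameters, the
#'   per-epoch training loss (`history`) and the config echo.
#' @export
train_autoencoder <- function(matrix, cfg = NULL, seed = NULL,
                              include_flagged = FALSE) {
  X <- if (inherits(matrix, "phenotype_matrix")) {
    keep <- if (include_flagged) rep(TRUE, nrow(matrix$values)) else !matrix$flagged
    as.matrix(matrix$values[keep, , drop = FALSE])
  } else as.matrix(matrix)
  if (nrow(X) < 2) stop("need at least 2 usable training rows, got ", nrow(X))
  if (is.null(cfg)) {
    if (is.null(seed)) stop("provide 'cfg' or 'seed'")
    cfg <- autoencoder_config(input_dim = ncol(X), seed = seed)
  }
  if (cfg$input_dim != ncol(X))
    stop("config input_dim (", cfg$input_dim, ") != data columns (", ncol(X), ")")

  scale_range <- NULL
  if (cfg$scale_input) {
    lo <- min(X); hi <- max(X)
    if (hi > lo) X <- (X - lo) / (hi - lo)
    scale_range <- c(lo, hi)
  }

  dims <- c(cfg$input_dim, cfg$layer_widths,
            rev(cfg$layer_widths)[-1], cfg$input_dim)
  n_w <- length(dims) - 1L
  # rectifiers on hidden layers; linear at the latent bottleneck and output
  act_relu <- rep(TRUE, n_w)
  act_relu[cfg$n_layers] <- FALSE
  act_relu[n_w] <- FALSE

  set.seed(cfg$seed)
  W <- vector("list", n_w); b <- vector("list", n_w)
  for (l in seq_len(n_w)) {
    W[[l]] <- matrix(stats::rnorm(dims[l] * dims[l + 1], sd = sqrt(2 / dims[l])),
                     dims[l], dims[l + 1])
    b[[l]] <- numeric(dims[l + 1])
  }
  mW <- lapply(W, function(w) w * 0); vW <- mW
  mb <- lapply(b, function(x) x * 0); vb <- mb
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; lr <- cfg$learning_rate
  t_step <- 0L

  n <- nrow(X)
  history <- numeric(cfg$epochs)
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    starts <- seq(1, n, by = cfg$batch_size)
    ep_loss <- 0
    for (s in starts) {
      idx <- ord[s:min(s + cfg$batch_size - 1L, n)]
      Xb <- X[idx, , drop = FALSE]
      acts <- ae_forward(W, b, act_relu, Xb)
      out <- acts[[n_w + 1L]]
      err <- out - Xb
      ep_loss <- ep_loss + sum(err^2)
      delta <- 2 * err / (length(idx) * cfg$input_dim)
      t_step <- t_step + 1L
      corr1 <- 1 - beta1^t_step; corr2 <- 1 - beta2^t_step
      for (l in rev(seq_len(n_w))) {
        gW <- crossprod(acts[[l]], delta)
        gb <- colSums(delta)
        if (l > 1) {
          delta <- delta %*% t(W[[l]])
          if (act_relu[l - 1L]) delta <- delta * (acts[[l]] > 0)
        }
        mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
        vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
        mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
        vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
        W[[l]] <- W[[l]] - lr * (mW[[l]] / corr1) / (sqrt(vW[[l]] / corr2) + eps)
        b[[l]] <- b[[l]] - lr * (mb[[l]] / corr1) / (sqrt(vb[[l]] / corr2) + eps)
      }
    }
    history[epoch] <- ep_loss / (n * cfg$input_dim)
    if (!is.finite(history[epoch]))
      stop("non-finite training loss at epoch ", epoch)
  }
  if (cfg$epochs >= 2 && history[cfg$epochs] > history[1])
    warning("final training loss exceeds initial loss; consider more epochs or a lower learning rate")

  structure(list(weights = W, biases = b, dims = dims, act_relu = act_relu,
                 n_encoder_layers = cfg$n_layers, config = cfg,
                 history = history, scale_range = scale_range,
                 n_training_rows = n),
            class = "gene_autoencoder")
}

#' @export
print.gene_autoencoder <- function(x, ...) {
  cat("Dense autoencoder:", x$config$input_dim, "->",
      paste(x$config$layer_widths, collapse = " -> "),
      "(latent) -> mirrored decoder\n")
  cat("Trained on", x$n_training_rows, "rows for", x$config$epochs,
      "epochs; final MSE", format(x$history[length(x$history)], digits = 4), "\n")
  invisible(x)
}

#' Encode or reconstruct vectors with a trained autoencoder
#'
#' @param object A `gene_autoencoder`.
#' @param newdata Numeric matrix (rows = observations, columns = G) or
#'   anything coercible via `as.matrix`.
#' @param type `"latent"` (default) for the 64-component encoding,
#'   `"reconstruction"` for the decoder output.
#' @param ... Unused.
#' @return Numeric matrix: n x latent_dim or n x G.
#' @export
predict.gene_autoencoder <- function(object, newdata,
                                     type = c("latent", "reconstruction"), ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata)
  if (ncol(X) != object$config$input_dim)
    stop("input has ", ncol(X), " columns; model expects ", object$config$input_dim)
  if (!is.null(object$scale_range)) {
    lo <- object$scale_range[1]; hi <- object$scale_range[2]
    if (hi > lo) X <- (X - lo) / (hi - lo)
  }
  n_use <- if (type == "latent") object$n_encoder_layers else length(object$weights)
  acts <- ae_forward(object$weights[seq_len(n_use)],
                     object$biases[seq_len(n_use)],
                     object$act_relu[seq_len(n_use)], X)
  out <- acts[[n_use + 1L]]
  rownames(out) <- rownames(newdata)
  out
}

#' Encode individuals into the latent space
#'
#' Builds each individual's G-dimensional gene-set vector and passes it
#' through the frozen encoder. Identical gene sets map to identical rows; an
#' empty set encodes the zero vector's image.
#'
#' @param sets An `individual_gene_sets` object (or named list of gene sets).
#' @param emb The `gene_embedding` whose vocabulary defines the input space.
#' @param model A trained `gene_autoencoder` with matching `input_dim`.
#' @return n x latent_dim numeric matrix, rows named by individual id;
#'   attribute `n_dropped_genes` counts out-of-vocabulary genes dropped.
#' @export
encode_individuals <- function(sets, emb, model) {
  if (model$config$input_dim != length(emb$vocabulary))
    stop("model input_dim (", model$config$input_dim,
         ") != embedding vocabulary size (", length(emb$vocabulary), ")")
  im <- build_individual_matrix(sets, emb)
  lat <- predict(model, as.matrix(im), type = "latent")
  rownames(lat) <- names(sets)
  attr(lat, "n_dropped_genes") <- attr(im, "n_dropped")
  attr(lat, "flagged") <- attr(im, "flagged")
  lat
}

#' Save / load a trained autoencoder as a self-describing JSON archive
#'
#' @param model A `gene_autoencoder`.
#' @param path Output path (JSON).
#' @return `path` (save) or the restored `gene_autoencoder` (load).
#' @export
save_autoencoder <- function(model, path) {
  payload <- list(config = unclass(model$config),
                  dims = model$dims, act_relu = model$act_relu,
                  n_encoder_layers = model$n_encoder_layers,
                  history = model$history,
                  scale_range = model$scale_range,
                  n_training_rows = model$n_training_rows,
                  weights = lapply(model$weights, function(w)
                    list(nrow = nrow(w), data = as.numeric(w))),
                  biases = model$biases)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_autoencoder
#' @export
load_autoencoder <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  W <- lapply(p$weights$data, identity)
  W <- Map(function(d, nr) matrix(d, nrow = nr), p$weights$data, p$weights$nrow)
  cfg <- p$config
  cfg$layer_widths <- as.integer(cfg$layer_widths)
  class(cfg) <- "autoencoder_config"
  structure(list(weights = W,
                 biases = lapply(p$biases, as.numeric),
                 dims = as.integer(p$dims), act_relu = as.logical(p$act_relu),
                 n_encoder_layers = as.integer(p$n_encoder_layers),
                 config = cfg, history = as.numeric(p$history),
                 scale_range = if (length(p$scale_range)) as.numeric(p$scale_range) else NULL,
                 n_training_rows = as.integer(p$n_training_rows)),
            class = "gene_autoencoder")
}
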