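#' Denoising-autoencoder configuration
#'
#' The network is a fully connected autoencoder with tanh activation on
#' every layer, including the output — hence inputs must be scaled to
#' [-1, 1] (see \code{\link{scale_features}}). The default architecture has
#' five hidden layers of 200, 50, 2, 50 and 200 units (seven layers
#' counting input and output), a 2-unit bottleneck, and is trained with
#' Adam at learning rate 0.001, batch size 256, for 100 epochs.
#'
#' Corruption defaults to masking noise: each input cell is independently
#' zeroed with probability \code{corruption_rate}, resampled afresh for
#' every batch. Masking keeps corrupted inputs inside tanh's range;
#' \code{"gaussian"} instead adds \eqn{N(0, rate \cdot sd_j)} noise, with
#' \eqn{sd_j} the per-feature standard deviation.
#'
#' @param hidden_sizes Hidden-layer widths; must be palindromic with odd
#'   length, the middle entry being the bottleneck dimension.
#' @param learning_rate Adam step size.
#' @param batch_size Mini-batch size (capped at the sample count).
#' @param epochs Training epochs.
#' @param corruption_rate Corruption probability/scale in [0, 1].
#' @param corruption_kind \code{"masking"} or \code{"gaussian"}.
#' @param seed Integer seed controlling weight initialization, batch
#'   shuffling and corruption draws.
#' @return A \code{dae_config} list.
#' @export
dae_config <- function(hidden_sizes = c(200L, 50L, 2L, 50L, 200L),
                       learning_rate = 0.001,
                       batch_size = 256L,
                       epochs = 100L,
                       corruption_rate = 0.2,
                       corruption_kind = c("masking", "gaussian"),
                       seed = 1L) {
  corruption_kind <- match.arg(corruption_kind)
  h <- as.integer(hidden_sizes)
  if (length(h) %% 2L == 0L || !identical(h, rev(h)))
    stop_("'hidden_sizes' must be palindromic with odd length (middle = bottleneck)")
  if (any(h < 1L)) stop_("'hidden_sizes' must be positive")
  if (corruption_rate < 0 || corruption_rate > 1)
    stop_("'corruption_rate' must be in [0, 1]")
  if (learning_rate <= 0 || batch_size < 1L || epochs < 1L)
    stop_("invalid optimizer settings")
  structure(list(hidden_sizes = h, activation = "tanh",
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 corruption_rate = corruption_rate,
                 corruption_kind = corruption_kind,
                 seed = as.integer(seed)),
            class = "dae_config")
}

#' Corrupt an input matrix
#'
#' The stochastic corruption step of denoising-autoencoder training. Pure
#' with respect to its input; draws come from the current RNG stream.
#'
#' @param x Numeric matrix.
#' @param rate Corruption probability (masking) or noise scale multiplier
#'   (gaussian), in [0, 1].
#' @param kind \code{"masking"}: each cell independently set to 0 with
#'   probability \code{rate}; \code{"gaussian"}: additive
#'   \eqn{N(0, rate \cdot sd_j)} noise per feature \eqn{j}.
#' @param feature_scale Optional per-feature scale for gaussian corruption;
#'   defaults to the column standard deviations of \code{x}.
#' @return Corrupted copy of \code{x}.
#' @export
corrupt <- function(x, rate, kind = c("masking", "gaussian"),
                    feature_scale = NULL) {
  kind <- match.arg(kind)
  if (rate < 0 || rate > 1) stop_("'rate' must be in [0, 1]")
  if (rate == 0) return(x)
  if (kind == "masking") {
    x[matrix(stats::runif(length(x)) < rate, nrow(x), ncol(x))] <- 0
    x
  } else {
    sc <- feature_scale %||% apply(x, 2L, stats::sd)
    sc[!is.finite(sc)] <- 0
    x + matrix(stats::rnorm(length(x)), nrow(x), ncol(x)) *
      rep(rate * sc, each = nrow(x))
  }
}

#' Mean per-sample squared reconstruction error
#'
#' The autoencoder loss: the squared Euclidean norm of the difference
#' between each clean sample and its reconstruction, averaged over samples.
#'
#' @param x,x_prime Matrices of identical dimension (samples in rows).
#' @return A single number.
#' @export
reconstruction_loss <- function(x, x_prime) {
  if (!identical(dim(x), dim(x_prime)))
    stop_("dimension mismatch: %s vs %s",
          paste(dim(x), collapse = "x"), paste(dim(x_prime), collapse = "x"))
  mean(rowSums((x - x_prime)^2))
}

## ---- network internals ------------------------------------------------

init_network <- function(layer_sizes) {
  lapply(seq_len(length(layer_sizes) - 1L), function(l) {
    fan_in <- layer_sizes[l]
    s <- 1 / sqrt(fan_in)
    list(W = matrix(stats::runif(fan_in * layer_sizes[l + 1L], -s, s),
                    fan_in, layer_sizes[l + 1L]),
         b = rep(0, layer_sizes[l + 1L]))
  })
}

nn_forward <- function(layers, x) {
  acts <- vector("list", length(layers) + 1L)
  acts[[1L]] <- x
  for (l in seq_along(layers))
    acts[[l + 1L]] <- tanh(acts[[l]] %*% layers[[l]]$W +
                             rep(layers[[l]]$b, each = nrow(x)))
  acts
}

## gradient of mean-over-samples sum-of-squares loss against clean x
nn_backward <- function(layers, acts, x_clean) {
  L <- length(layers)
  grads <- vector("list", L)
  out <- acts[[L + 1L]]
  delta <- (2 / nrow(x_clean)) * (out - x_clean) * (1 - out^2)
  for (l in L:1) {
    grads[[l]] <- list(W = crossprod(acts[[l]], delta),
                       b = colSums(delta))
    if (l > 1L)
      delta <- (delta %*% t(layers[[l]]$W)) * (1 - acts[[l]]^2)
  }
  grads
}

adam_init <- function(layers) {
  list(m = lapply(layers, function(p) list(W = p$W * 0, b = p$b * 0)),
       v = lapply(layers, function(p) list(W = p$W * 0, b = p$b * 0)),
       t = 0L)
}

adam_step <- function(layers, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (l in seq_along(layers)) {
    for (p in c("W", "b")) {
      state$m[[l]][[p]] <- beta1 * state$m[[l]][[p]] + (1 - beta1) * grads[[l]][[p]]
      state$v[[l]][[p]] <- beta2 * state$v[[l]][[p]] + (1 - beta2) * grads[[l]][[p]]^2
      layers[[l]][[p]] <- layers[[l]][[p]] -
        lr * (state$m[[l]][[p]] / bc1) / (sqrt(state$v[[l]][[p]] / bc2) + eps)
    }
  }
  list(layers = layers, state = state)
}

train_autoencoder <- function(x, config, denoise) {
  p <- ncol(x)
  layer_sizes <- c(p, config$hidden_sizes, p)
  rate <- if (denoise) config$corruption_rate else 0
  feature_scale <- if (rate > 0 && config$corruption_kind == "gaussian")
    apply(x, 2L, stats::sd) else NULL
  with_seed(config$seed, {
    layers <- init_network(layer_sizes)
    state <- adam_init(layers)
    n <- nrow(x)
    bs <- min(config$batch_size, n)
    loss_history <- numeric(config$epochs)
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      loss_sum <- 0
      for (start in seq(1L, n, by = bs)) {
        idx <- ord[start:min(start + bs - 1L, n)]
        xb <- x[idx, , drop = FALSE]
        xin <- if (rate > 0)
          corrupt(xb, rate, config$corruption_kind, feature_scale) else xb
        acts <- nn_forward(layers, xin)
        loss_sum <- loss_sum + sum(rowSums((xb - acts[[length(acts)]])^2))
        grads <- nn_backward(layers, acts, xb)
        upd <- adam_step(layers, grads, state, config$learning_rate)
        layers <- upd$layers
        state <- upd$state
      }
      loss_history[epoch] <- loss_sum / n
      if (!is.finite(loss_history[epoch]))
        stop_("training diverged (non-finite loss) at epoch %d", epoch)
    }
    list(layers = layers, loss_history = loss_history)
  })
}

as_input_matrix <- function(dataset) {
  x <- if (inherits(dataset, "multiomics_dataset")) dataset$x
  else if (inherits(dataset, "omics_matrix")) dataset$values
  else if (is.matrix(dataset)) dataset
  else stop_("expected a multiomics_dataset, omics_matrix, or matrix")
  if (anyNA(x)) stop_("input contains missing values; impute first")
  x
}

#' Fit a (denoising) autoencoder
#'
#' Trains the network by back-propagation with the Adam optimizer,
#' minimizing the mean squared reconstruction error of the CLEAN input from
#' its corrupted version (\code{fit_dae}) or from the input itself
#' (\code{fit_ae}). Corruption is resampled afresh for every mini-batch.
#' Training is bit-reproducible for a fixed seed under single-threaded
#' BLAS. With \code{corruption_rate = 0}, \code{fit_dae} and \code{fit_ae}
#' follow the identical computation path, so their per-epoch losses agree
#' exactly.
#'
#' @param dataset A preprocessed \code{multiomics_dataset} (no missing
#'   values, features in [-1, 1]), an \code{omics_matrix}, or a bare
#'   matrix.
#' @param config A \code{\link{dae_config}}.
#' @return An \code{embedding_model}: trained layers, per-epoch
#'   \code{loss_history} (mean per-sample squared error on clean inputs),
#'   the feature names it expects, and the config.
#' @export
fit_dae <- function(dataset, config = dae_config()) {
  x <- as_input_matrix(dataset)
  fit <- train_autoencoder(x, config, denoise = TRUE)
  new_embedding_model(fit, config, colnames(x),
                      kind = if (config$corruption_rate > 0) "dae" else "ae")
}

#' @rdname fit_dae
#' @export
fit_ae <- function(dataset, config = dae_config()) {
  x <- as_input_matrix(dataset)
  fit <- train_autoencoder(x, config, denoise = FALSE)
  new_embedding_model(fit, config, colnames(x), kind = "ae")
}

new_embedding_model <- function(fit, config, feature_names, kind) {
  structure(list(layers = fit$layers, loss_history = fit$loss_history,
                 config = config, feature_names = feature_names,
                 bottleneck = config$hidden_sizes[(length(config$hidden_sizes) + 1L) %/% 2L],
                 kind = kind),
            class = "embedding_model")
}

#' @export
print.embedding_model <- function(x, ...) {
  cat(sprintf("%s embedding_model: %d -> %s -> %d, bottleneck %d; final loss %.4f\n",
              toupper(x$kind), length(x$feature_names),
              paste(x$config$hidden_sizes, collapse = "-"),
              length(x$feature_names), x$bottleneck,
              x$loss_history[length(x$loss_history)]))
  invisible(x)
}

#' Project samples into the bottleneck space
#'
#' Applies the trained encoder to clean (uncorrupted) inputs and returns
#' the bottleneck activations, the low-dimensional representation used for
#' clustering.
#'
#' @param model An \code{embedding_model}.
#' @param dataset Data with the same feature space the model was trained
#'   on.
#' @return An \code{embedding}: list with \code{sample_ids} and
#'   \code{coordinates} (samples x bottleneck matrix).
#' @export
embed_samples <- function(model, dataset) {
  stopifnot(inherits(model, "embedding_model"))
  x <- as_input_matrix(dataset)
  if (!is.null(colnames(x))) {
    miss <- setdiff(model$feature_names, colnames(x))
    if (length(miss))
      stop_("input lacks %d model feature(s), e.g. %s", length(miss),
            paste(utils::head(miss, 5L), collapse = ", "))
    x <- x[, model$feature_names, drop = FALSE]
  } else if (ncol(x) != length(model$feature_names)) {
    stop_("input has %d features; model expects %d", ncol(x),
          length(model$feature_names))
  }
  n_enc <- (length(model$layers) + 1L) %/% 2L  # encoder half
  a <- x
  for (l in seq_len(n_enc))
    a <- tanh(a %*% model$layers[[l]]$W + rep(model$layers[[l]]$b, each = nrow(a)))
  new_embedding(rownames(x) %||% as.character(seq_len(nrow(x))), a)
}

new_embedding <- function(ids, coords) {
  rownames(coords) <- ids
  colnames(coords) <- paste0("z", seq_len(ncol(coords)))
  structure(list(sample_ids = ids, coordinates = coords), class = "embedding")
}

#' @export
print.embedding <- function(x, ...) {
  cat(sprintf("embedding: %d samples x %d dimensions\n",
              nrow(x$coordinates), ncol(x$coordinates)))
  invisible(x)
}

#' Save or load a trained embedding model
#'
#' Models are stored with R's native serialization.
#'
#' @param model An \code{embedding_model}.
#' @param path File path.
#' @export
save_embedding_model <- function(model, path) {
  stopifnot(inherits(model, "embedding_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_embedding_model
#' @export
load_embedding_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "embedding_model")) stop_("%s is not an embedding_model", path)
  m
}

#' Write an embedding as CSV
#'
#' Columns: sample_id, z1..zd.
#' @param embedding An \code{embedding}.
#' @param path Output file.
#' @export
write_embedding <- function(embedding, path) {
  df <- data.frame(sample_id = embedding$sample_ids, embedding$coordinates,
                   check.names = FALSE)
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}
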