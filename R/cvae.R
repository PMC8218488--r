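#' Configuration for the convolutional variational autoencoder
#'
#' The architecture follows the reference setup for contact-tensor embedding:
#' four valid (no padding, no pooling) convolutional layers with `filters`
#' filters of size 1 x `kernel_length`, stride `stride` along the protein-atom
#' axis and 1 along the channel/row axis, a `latent_dim`-dimensional Gaussian
#' latent space, and a decoder that mirrors the encoder with transposed
#' convolutions. Training uses summed binary cross-entropy plus KL divergence,
#' RMSprop at learning rate 0.005, at most 600 epochs with early stopping
#' after 10 epochs without improvement (strict decrease) of the training
#' loss.
#'
#' @param filters Number of convolution filters per layer (grid used for the
#'   ensemble: 32 and 64).
#' @param latent_dim Latent dimension (ensemble grid: 3, 5, 10).
#' @param kernel_length Convolution window along the protein-atom axis.
#' @param stride Stride along the protein-atom axis.
#' @param n_conv_layers Number of convolution layers.
#' @param learning_rate RMSprop learning rate.
#' @param max_epochs,patience Early-stopping schedule.
#' @param batch_size Minibatch size.
#' @param seed Integer seed for initialization, shuffling and sampling noise.
#' @return Object of class `cvae_config`.
#' @export
cvae_config <- function(filters = 32, latent_dim = 5, kernel_length = 7,
                        stride = 2, n_conv_layers = 4, learning_rate = 0.005,
                        max_epochs = 600, patience = 10, batch_size = 64,
                        seed = 1) {
  stopifnot(filters >= 1, latent_dim >= 1, kernel_length >= 1, stride >= 1,
            n_conv_layers >= 1, learning_rate > 0, max_epochs >= 1,
            patience >= 1, batch_size >= 1)
  structure(list(filters = as.integer(filters), latent_dim = as.integer(latent_dim),
                 kernel_length = as.integer(kernel_length), stride = as.integer(stride),
                 n_conv_layers = as.integer(n_conv_layers),
                 learning_rate = learning_rate, max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "cvae_config")
}

# smallest input length that survives n valid conv layers
min_input_length <- function(kernel, stride, n_layers) {
  need <- 1L
  for (l in seq_len(n_layers)) need <- kernel + stride * (need - 1L)
  need
}

#' Build an (untrained) convolutional VAE for a given input shape
#'
#' Validates that the protein-atom axis is long enough for the configured
#' stack of valid convolutions and initializes weights (Glorot-uniform, from
#' the config seed).
#'
#' @param config A [cvae_config()].
#' @param input_shape Integer vector `(channels, rows, M)`.
#' @return Object of class `cvae_model`: list with `config`, `input_shape`,
#'   `shape_trace` (per-layer lengths) and `weights`.
#' @export
build_cvae <- function(config, input_shape) {
  stopifnot(inherits(config, "cvae_config"), length(input_shape) == 3L)
  C <- as.integer(input_shape[1]); R_ <- as.integer(input_shape[2])
  M <- as.integer(input_shape[3])
  need <- min_input_length(config$kernel_length, config$stride, config$n_conv_layers)
  if (M < need) {
    stop("protein-atom axis too short: M = ", M, " but ", config$n_conv_layers,
         " valid conv layers with kernel ", config$kernel_length, ", stride ",
         config$stride, " require M >= ", need, call. = FALSE)
  }
  trace <- M
  for (l in seq_len(config$n_conv_layers)) {
    trace <- c(trace, (trace[length(trace)] - config$kernel_length) %/% config$stride + 1L)
  }
  set.seed(config$seed)
  w <- cpp_cvae_init(C, R_, M, config$filters, config$latent_dim,
                     config$kernel_length, config$stride, config$n_conv_layers)
  structure(list(config = config, input_shape = c(C, R_, M),
                 shape_trace = trace, weights = w, trained = FALSE),
            class = "cvae_model")
}

#' @export
print.cvae_model <- function(x, ...) {
  cat("<cvae_model> f=", x$config$filters, ", d=", x$config$latent_dim,
      ", input (", paste(x$input_shape, collapse = " x "), "), lengths ",
      paste(x$shape_trace, collapse = " -> "),
      if (x$trained) " [trained]" else " [untrained]", "\n", sep = "")
  invisible(x)
}

dyn_values <- function(dyn) {
  v <- if (inherits(dyn, "dynamism_series")) dyn$values else dyn
  stopifnot(length(dim(v)) == 4L)
  if (!all(v %in% c(0L, 1L))) {
    stop("autoencoder inputs must be binary (cross-entropy reconstruction)", call. = FALSE)
  }
  storage.mode(v) <- "double"
  v
}

#' Train a convolutional VAE on a dynamism series
#'
#' @param model A `cvae_model` from [build_cvae()]; its shape must match the
#'   series.
#' @param dyn A `dynamism_series` (T x 2 x R x M binary array) or a plain 4-d
#'   binary array.
#' @return Object of class `latent_embedding`: list with `z` (T x d matrix of
#'   latent means, used for clustering — deterministic, no sampling),
#'   `loss_history` (tibble with per-epoch totals: `epoch`, `total`, `bce`,
#'   `kl`), `epochs`, `model_tag` (f, d, seed) and the trained `model`.
#' @export
train_cvae <- function(model, dyn) {
  stopifnot(inherits(model, "cvae_model"))
  v <- dyn_values(dyn)
  d <- dim(v)
  if (!all(d[2:4] == model$input_shape)) {
    stop("dynamism shape (", paste(d[2:4], collapse = " x "),
         ") does not match model input (", paste(model$input_shape, collapse = " x "),
         ")", call. = FALSE)
  }
  cfg <- model$config
  if (d[1] < 2L * 50L) {
    warning("short series (T = ", d[1], "): downstream clustering at the default ",
            "minimum cluster size of 50 may label everything noise", call. = FALSE)
  }
  set.seed(cfg$seed)   # governs shuffling + reparameterization noise
  fit <- cpp_cvae_train(v, model$weights, cfg$learning_rate, cfg$max_epochs, cfg$patience,
                        cfg$batch_size, cfg$kernel_length, cfg$stride,
                        cfg$n_conv_layers)
  model$weights <- fit$weights
  model$trained <- TRUE
  structure(list(
    z = fit$mu,
    loss_history = tibble::tibble(epoch = seq_along(fit$loss),
                                  total = fit$loss, bce = fit$bce, kl = fit$kl),
    epochs = fit$epochs,
    model_tag = list(f = cfg$filters, d = cfg$latent_dim, seed = cfg$seed),
    model = model
  ), class = "latent_embedding")
}

#' @export
print.latent_embedding <- function(x, ...) {
  cat("<latent_embedding> T=", nrow(x$z), ", d=", ncol(x$z),
      " (f=", x$model_tag$f, ", seed=", x$model_tag$seed, "), ",
      x$epochs, " epochs, final loss ",
      signif(x$loss_history$total[x$epochs], 6), "\n", sep = "")
  invisible(x)
}

#' Encode / reconstruct with a trained model
#'
#' `encode()` returns the latent means for every frame; `reconstruct()` runs
#' the full autoencoder (deterministic latent, sigmoid output in (0,1)).
#'
#' @param model A trained (or freshly built) `cvae_model`.
#' @param dyn A `dynamism_series` or 4-d binary array matching the model.
#' @return `encode()`: T x d matrix; `reconstruct()`: array shaped like the
#'   input.
#' @export
encode <- function(model, dyn) {
  v <- dyn_values(dyn)
  out <- cpp_cvae_forward(v, model$weights, model$config$kernel_length,
                          model$config$stride, model$config$n_conv_layers)
  out$mu
}

#' @rdname encode
#' @export
reconstruct <- function(model, dyn) {
  v <- dyn_values(dyn)
  out <- cpp_cvae_forward(v, model$weights, model$config$kernel_length,
                          model$config$stride, model$config$n_conv_layers)
  out$recon
}

#' Train the hyperparameter ensemble for one subtype
#'
#' Trains one model per (filters, latent_dim) combination — by default the
#' 2 x 3 grid {32, 64} x {3, 5, 10}, i.e. 6 architectures — with seeds
#' derived deterministically from `base_seed` so each member is reproducible
#' independently. Averaging comparison metrics over the ensemble, and using
#' their spread as an agreement score, buffers the unsupervised pipeline
#' against any single architecture's quirks.
#'
#' @param dyn A `dynamism_series` for one subtype (T x 2 x 1 x M) or any
#'   4-d binary array.
#' @param filters_grid,latent_grid Hyperparameter grids.
#' @param base_seed Base seed; member k trains with seed `base_seed + k`.
#' @param ... Further arguments passed to [cvae_config()].
#' @return List of `latent_embedding`s, one per grid point, named `f<f>_d<d>`.
#' @export
build_ensemble <- function(dyn, filters_grid = c(32, 64), latent_grid = c(3, 5, 10),
                           base_seed = 1, ...) {
  stopifnot(length(filters_grid) >= 1, length(latent_grid) >= 1)
  v <- dyn_values(dyn)
  d <- dim(v)
  grid <- expand.grid(d_ = latent_grid, f_ = filters_grid)[, c("f_", "d_")]
  out <- vector("list", nrow(grid))
  for (k in seq_len(nrow(grid))) {
    cfg <- cvae_config(filters = grid$f_[k], latent_dim = grid$d_[k],
                       seed = (base_seed + k) %% .Machine$integer.max, ...)
    model <- build_cvae(cfg, d[2:4])
    out[[k]] <- train_cvae(model, v)
  }
  names(out) <- sprintf("f%d_d%d", grid$f_, grid$d_)
  out
}
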