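# Denoising autoencoder for dense feature tables, implemented as a plain
# feedforward network (matrix backpropagation + Adam) at desk scale.
#
# The encoder widths are given by `layer_sizes`; the decoder mirrors them
# symmetrically with untied weights, e.g. layer_sizes = c(800, 300, 100) on
# f-dimensional input gives the stack f-800-300-100-300-800-f. Inputs are
# corrupted with additive Gaussian noise (or feature masking) and the
# network is trained to reconstruct the clean input under mean squared
# error.

#' Configuration for a denoising autoencoder
#'
#' @param layer_sizes Integer vector of encoder hidden widths; the last
#'   entry is the code dimension. The decoder mirrors these symmetrically
#'   (untied weights).
#' @param noise_factor Corruption scale: the standard deviation of additive
#'   Gaussian noise (default 0.2), or the masking probability when
#'   `corruption = "mask"`.
#' @param activation `"sigmoid"` (default; expects inputs scaled to
#'   `[0, 1]`) or `"linear"`.
#' @param batch_size Minibatch size, default 150.
#' @param epochs Training epochs, default 100.
#' @param learning_rate Adam step size, default 1e-3.
#' @param seed RNG seed controlling initialization, shuffling and corruption
#'   draws; training is fully reproducible given the seed.
#' @param corruption `"gaussian"` additive noise (default) or `"mask"`
#'   (randomly zero a feature, dropout-style).
#' @param scale_features If `TRUE` (default), per-feature min-max scaling to
#'   `[0, 1]` is applied before training and stored with the model for
#'   reuse at encoding time.
#' @return A list of class `dae_config`.
#' @export
dae_config <- function(layer_sizes, noise_factor = 0.2,
                       activation = c("sigmoid", "linear"),
                       batch_size = 150L, epochs = 100L,
                       learning_rate = 1e-3, seed = 1L,
                       corruption = c("gaussian", "mask"),
                       scale_features = TRUE) {
  activation <- match.arg(activation)
  corruption <- match.arg(corruption)
  layer_sizes <- as.integer(layer_sizes)
  if (length(layer_sizes) == 0L || any(is.na(layer_sizes)) ||
      any(layer_sizes < 1L)) {
    stop("`layer_sizes` must be a non-empty vector of positive integers",
         call. = FALSE)
  }
  if (noise_factor < 0) stop("`noise_factor` must be >= 0", call. = FALSE)
  if (batch_size < 1L) stop("`batch_size` must be positive", call. = FALSE)
  if (epochs < 1L) stop("`epochs` must be positive", call. = FALSE)
  if (learning_rate <= 0) stop("`learning_rate` must be positive", call. = FALSE)
  structure(
    list(layer_sizes = layer_sizes, noise_factor = noise_factor,
         activation = activation, batch_size = as.integer(batch_size),
         epochs = as.integer(epochs), learning_rate = learning_rate,
         seed = as.integer(seed), corruption = corruption,
         scale_features = isTRUE(scale_features)),
    class = "dae_config")
}

#' Corrupt a data matrix
#'
#' Adds i.i.d. Gaussian noise with standard deviation `noise_factor`
#' (default corruption), or randomly zeroes entries with probability
#' `noise_factor` when `corruption = "mask"`. Deterministic given `seed`.
#'
#' @param data Numeric matrix.
#' @param noise_factor Corruption scale; 0 returns `data` unchanged.
#' @param seed RNG seed.
#' @param corruption `"gaussian"` or `"mask"`.
#' @return Matrix of the same shape.
#' @export
corrupt <- function(data, noise_factor, seed,
                    corruption = c("gaussian", "mask")) {
  corruption <- match.arg(corruption)
  data <- check_numeric_matrix(data, "data")
  if (noise_factor < 0) stop("`noise_factor` must be >= 0", call. = FALSE)
  if (noise_factor == 0) return(data)
  with_seed(seed, corrupt_stream(data, noise_factor, corruption))
}

# Corruption drawing from the current RNG stream (used inside training).
corrupt_stream <- function(data, noise_factor, corruption) {
  if (noise_factor == 0) return(data)
  if (corruption == "gaussian") {
    data + matrix(stats::rnorm(length(data), sd = noise_factor), nrow(data))
  } else {
    data * (matrix(stats::runif(length(data)), nrow(data)) >= noise_factor)
  }
}

dae_activate <- function(z, activation) {
  if (activation == "sigmoid") 1 / (1 + exp(-z)) else z
}

# derivative wrt pre-activation, expressed through the activation value
dae_activate_grad <- function(a, activation) {
  if (activation == "sigmoid") a * (1 - a) else 1
}

dae_forward <- function(X, weights, biases, activation) {
  acts <- vector("list", length(weights) + 1L)
  acts[[1L]] <- X
  for (l in seq_along(weights)) {
    z <- acts[[l]] %*% weights[[l]]
    z <- sweep(z, 2L, biases[[l]], `+`)
    acts[[l + 1L]] <- dae_activate(z, activation)
  }
  acts
}

#' Train a denoising autoencoder
#'
#' Minimizes the mean squared error between the clean input and the
#' reconstruction of its corrupted version, `z = g(f(x_tilde))`, with Adam
#' on minibatches. Fresh corruption noise is drawn for every minibatch.
#' The per-epoch mean training loss (against clean targets, in the scaled
#' domain when `scale_features` is on) is recorded in `loss_history`.
#'
#' @param data Numeric matrix, rows = entities, columns = features. With
#'   `activation = "sigmoid"` values should lie in `[0, 1]` after scaling.
#' @param cfg A [dae_config()].
#' @return Object of class `puimc_dae`: encoder/decoder weights and biases,
#'   the scaling parameters, the config, and `loss_history` (length
#'   `cfg$epochs`).
#' @export
train_dae <- function(data, cfg) {
  if (!inherits(cfg, "dae_config")) stop("`cfg` must be a dae_config")
  data <- check_numeric_matrix(data, "data")
  if (nrow(data) == 0L) stop("`data` is empty", call. = FALSE)
  f <- ncol(data)

  if (cfg$scale_features) {
    mins <- apply(data, 2L, min)
    ranges <- apply(data, 2L, max) - mins
    ranges[ranges == 0] <- 1
  } else {
    mins <- rep(0, f)
    ranges <- rep(1, f)
  }
  X <- sweep(sweep(data, 2L, mins, `-`), 2L, ranges, `/`)

  widths <- c(f, cfg$layer_sizes,
              rev(cfg$layer_sizes[-length(cfg$layer_sizes)]), f)
  L <- length(widths) - 1L
  n <- nrow(X)
  bs <- min(cfg$batch_size, n)

  with_seed(cfg$seed, {
    weights <- vector("list", L)
    biases <- vector("list", L)
    for (l in seq_len(L)) {
      lim <- sqrt(6 / (widths[l] + widths[l + 1L]))
      weights[[l]] <- matrix(stats::runif(widths[l] * widths[l + 1L],
                                          -lim, lim),
                             widths[l], widths[l + 1L])
      biases[[l]] <- rep(0, widths[l + 1L])
    }
    init_weights <- weights
    init_biases <- biases

    mW <- lapply(weights, function(w) w * 0)
    vW <- mW
    mb <- lapply(biases, function(b) b * 0)
    vb <- mb
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
    step <- 0L
    loss_history <- numeric(cfg$epochs)

    for (epoch in seq_len(cfg$epochs)) {
      perm <- sample.int(n)
      total <- 0
      for (start in seq(1L, n, by = bs)) {
        idx <- perm[start:min(start + bs - 1L, n)]
        xb <- X[idx, , drop = FALSE]
        xt <- corrupt_stream(xb, cfg$noise_factor, cfg$corruption)
        acts <- dae_forward(xt, weights, biases, cfg$activation)
        z <- acts[[L + 1L]]
        resid <- z - xb
        total <- total + sum(resid^2) / f
        # backprop (loss = mean over batch entries)
        dA <- 2 * resid / (length(idx) * f)
        step <- step + 1L
        corr1 <- 1 - beta1^step
        corr2 <- 1 - beta2^step
        grads_W <- vector("list", L)
        grads_b <- vector("list", L)
        for (l in L:1) {
          dZ <- dA * dae_activate_grad(acts[[l + 1L]], cfg$activation)
          grads_W[[l]] <- crossprod(acts[[l]], dZ)
          grads_b[[l]] <- colSums(dZ)
          if (l > 1L) dA <- dZ %*% t(weights[[l]])
        }
        for (l in seq_len(L)) {
          mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * grads_W[[l]]
          vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * grads_W[[l]]^2
          weights[[l]] <- weights[[l]] - cfg$learning_rate *
            (mW[[l]] / corr1) / (sqrt(vW[[l]] / corr2) + eps)
          mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * grads_b[[l]]
          vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * grads_b[[l]]^2
          biases[[l]] <- biases[[l]] - cfg$learning_rate *
            (mb[[l]] / corr1) / (sqrt(vb[[l]] / corr2) + eps)
        }
      }
      loss_history[epoch] <- total / n
    }

    structure(
      list(weights = weights, biases = biases,
           init_weights = init_weights, init_biases = init_biases,
           widths = widths, n_encoder_layers = length(cfg$layer_sizes),
           mins = mins, ranges = ranges, config = cfg,
           loss_history = loss_history),
      class = "puimc_dae")
  })
}

#' @export
print.puimc_dae <- function(x, ...) {
  cat(sprintf("Denoising autoencoder %s; final loss %.4g (epoch 1: %.4g)\n",
              paste(x$widths, collapse = "-"),
              x$loss_history[length(x$loss_history)], x$loss_history[1L]))
  invisible(x)
}

dae_scale <- function(data, model) {
  sweep(sweep(data, 2L, model$mins, `-`), 2L, model$ranges, `/`)
}

#' Encode data with a trained autoencoder
#'
#' Forward pass through the encoder half only; no corruption is applied at
#' inference time. The stored feature scaling is applied first.
#'
#' @param data Numeric matrix with the training feature width.
#' @param model A `puimc_dae` from [train_dae()].
#' @return `n x d` matrix of codes, `d` = last encoder width.
#' @export
encode <- function(data, model) {
  stopifnot(inherits(model, "puimc_dae"))
  data <- check_numeric_matrix(data, "data")
  if (ncol(data) != model$widths[1L]) {
    stop(sprintf("`data` has %d features but the model was trained on %d",
                 ncol(data), model$widths[1L]), call. = FALSE)
  }
  a <- dae_scale(data, model)
  for (l in seq_len(model$n_encoder_layers)) {
    z <- sweep(a %*% model$weights[[l]], 2L, model$biases[[l]], `+`)
    a <- dae_activate(z, model$config$activation)
  }
  rownames(a) <- rownames(data)
  a
}

#' Reconstruct data with a trained autoencoder
#'
#' Clean forward pass through the full encoder-decoder stack. Output is
#' mapped back to the original feature scale.
#'
#' @param data Numeric matrix with the training feature width.
#' @param model A `puimc_dae`.
#' @param use_init_weights If `TRUE`, run the untrained (initialization)
#'   weights instead — useful as a baseline when quantifying how much
#'   training denoised.
#' @return Matrix of the same shape as `data`.
#' @export
reconstruct <- function(data, model, use_init_weights = FALSE) {
  stopifnot(inherits(model, "puimc_dae"))
  data <- check_numeric_matrix(data, "data")
  W <- if (use_init_weights) model$init_weights else model$weights
  b <- if (use_init_weights) model$init_biases else model$biases
  acts <- dae_forward(dae_scale(data, model), W, b, model$config$activation)
  z <- acts[[length(acts)]]
  sweep(sweep(z, 2L, model$ranges, `*`), 2L, model$mins, `+`)
}
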