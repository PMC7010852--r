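# Diffusion component analysis: compress diffusion states into low-rank
# node/context embeddings via a log transform and truncated SVD. The
# KL-divergence objective of the softmax formulation is kept as a
# diagnostic only; it is never optimized directly.

#' Log-transform a diffusion-state matrix
#'
#' Computes `L = log(S + Q) - log(Q)` elementwise, where `Q` is a constant
#' pseudo-count matrix. The pseudo-count guards against taking the logarithm
#' of zero; with the default `1/n` (n = number of rows) an exactly-zero
#' diffusion entry maps to exactly zero in `L`.
#'
#' @param S A `puimc_diffusion` object, or a non-negative matrix of
#'   (possibly fused, hence rectangular) diffusion states.
#' @param pseudo_count Positive constant added inside the logarithm.
#'   Defaults to `1/nrow(S)`.
#' @return A non-negative matrix of the same shape with attribute
#'   `pseudo_count`.
#' @export
log_transform <- function(S, pseudo_count = NULL) {
  S <- diffusion_states(S)
  if (any(S < 0)) stop("`S` must be non-negative", call. = FALSE)
  pseudo_count <- pseudo_count %||% (1 / nrow(S))
  if (!is.numeric(pseudo_count) || length(pseudo_count) != 1L ||
      pseudo_count <= 0) {
    stop("`pseudo_count` must be a single positive number", call. = FALSE)
  }
  L <- log1p(S / pseudo_count)
  attr(L, "pseudo_count") <- pseudo_count
  L
}

#' Node and context embeddings by truncated SVD
#'
#' Takes the rank-`d` truncated singular value decomposition
#' `L ~ U_d %*% diag(sigma_d) %*% t(V_d)` and splits the singular values
#' evenly between the two sides: node features `X = U_d diag(sqrt(sigma_d))`
#' and context features `W = V_d diag(sqrt(sigma_d))`, so that `X %*% t(W)`
#' is the best rank-`d` Frobenius approximation of `L`.
#'
#' Sign indeterminacy of the singular vectors is resolved by forcing the
#' largest-magnitude entry of each left singular vector to be positive, so
#' the embedding is reproducible across platforms.
#'
#' @param L Numeric matrix, typically a [log_transform()]ed diffusion
#'   matrix (n x m; rectangular input from fused networks is fine).
#' @param d Embedding dimension, `1 <= d <= min(n, m)`.
#' @return An object of class `puimc_embedding`: list with `node_features`
#'   (n x d), `context_features` (m x d), `singular_values` (length d,
#'   non-increasing) and `node_ids`.
#' @export
svd_embed <- function(L, d) {
  L <- check_numeric_matrix(L, "L")
  d <- as.integer(d)
  if (length(d) != 1L || is.na(d) || d < 1L || d > min(dim(L))) {
    stop(sprintf("`d` must be an integer in [1, %d]", min(dim(L))),
         call. = FALSE)
  }
  sv <- svd(L, nu = d, nv = d)
  U <- sv$u
  V <- sv$v
  sigma <- sv$d[seq_len(d)]
  for (c in seq_len(d)) {
    jmax <- which.max(abs(U[, c]))
    if (U[jmax, c] < 0) {
      U[, c] <- -U[, c]
      V[, c] <- -V[, c]
    }
  }
  scale <- sqrt(sigma)
  X <- sweep(U, 2L, scale, `*`)
  W <- sweep(V, 2L, scale, `*`)
  rownames(X) <- rownames(L)
  rownames(W) <- colnames(L)
  structure(
    list(node_features = X, context_features = W, singular_values = sigma,
         node_ids = rownames(L)),
    class = "puimc_embedding")
}

#' @export
print.puimc_embedding <- function(x, ...) {
  cat(sprintf("Embedding: %d nodes x %d dims (leading singular value %.4g)\n",
              nrow(x$node_features), ncol(x$node_features),
              x$singular_values[1L]))
  invisible(x)
}

#' KL-divergence diagnostic for an embedding
#'
#' Measures how well the softmax model
#' `shat[i, j] = exp(x_i . w_j) / sum_j' exp(x_i . w_j')` reproduces the
#' diffusion-state rows: returns `mean_i KL(s_i || shat_i)`. This is the
#' objective of the multinomial-logistic formulation of diffusion component
#' analysis; the package optimizes the relaxed SVD objective instead
#' ([svd_embed()]) and exposes this quantity purely as a diagnostic of the
#' relaxation gap.
#'
#' @param S Diffusion states (`puimc_diffusion` or matrix); each row must be
#'   a probability distribution.
#' @param emb A `puimc_embedding` (or list with `node_features` and
#'   `context_features`).
#' @return A single non-negative number; 0 iff the softmax rows equal `S`.
#' @export
kl_objective <- function(S, emb) {
  S <- diffusion_states(S)
  if (any(S < 0) || any(abs(rowSums(S) - 1) > 1e-8)) {
    stop("rows of `S` must be probability distributions", call. = FALSE)
  }
  X <- check_numeric_matrix(emb$node_features, "node_features")
  W <- check_numeric_matrix(emb$context_features, "context_features")
  if (nrow(X) != nrow(S) || nrow(W) != ncol(S) || ncol(X) != ncol(W)) {
    stop("embedding dimensions do not match `S`", call. = FALSE)
  }
  logits <- X %*% t(W)
  mx <- apply(logits, 1L, max)
  lse <- mx + log(rowSums(exp(logits - mx)))
  log_shat <- logits - lse
  terms <- S * (ifelse(S > 0, log(pmax(S, .Machine$double.xmin)), 0) - log_shat)
  terms[S == 0] <- 0
  mean(rowSums(terms))
}
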