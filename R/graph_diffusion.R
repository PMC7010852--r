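# Restart random walks over weighted similarity networks.
#
# Convention (fixed throughout the package): rows are walk sources, columns
# are targets; a distribution is a row vector multiplied on the left of the
# transition matrix.

as_adjacency <- function(adj, name = "adj") {
  adj <- check_numeric_matrix(adj, name)
  if (nrow(adj) != ncol(adj)) {
    stop(sprintf("`%s` must be square", name), call. = FALSE)
  }
  if (any(adj < 0)) {
    stop(sprintf("`%s` has negative weights; edge weights must be >= 0", name),
         call. = FALSE)
  }
  ids <- rownames(adj) %||% sprintf("n%d", seq_len(nrow(adj)))
  if (anyDuplicated(ids)) stop("node identifiers must be unique", call. = FALSE)
  dimnames(adj) <- list(ids, ids)
  adj
}

#' Row-normalize a weighted adjacency matrix into a transition matrix
#'
#' Each entry of the result is the probability of stepping from the row node
#' to the column node: `B[i, j] = A[i, j] / sum_j' A[i, j']`. Rows whose
#' weights sum to zero (isolated nodes) have no well-defined transition
#' distribution; they are replaced according to `zero_row_policy`.
#'
#' @param adj Square numeric matrix of non-negative edge weights. Row/column
#'   names, when present, are used as node identifiers.
#' @param zero_row_policy How to fill rows of isolated nodes: `"uniform"`
#'   (default) assigns `1/n` to every target, keeping the walk well mixed;
#'   `"self_loop"` makes the node absorb its own walk.
#' @return A row-stochastic matrix of the same dimension with node ids as
#'   dimnames.
#' @seealso [rwr_diffusion()]
#' @export
#' @examples
#' A <- matrix(c(0, 2, 1, 0), 2, 2, byrow = TRUE)
#' row_normalize(A)
row_normalize <- function(adj, zero_row_policy = c("uniform", "self_loop")) {
  zero_row_policy <- match.arg(zero_row_policy)
  adj <- as_adjacency(adj)
  n <- nrow(adj)
  rs <- rowSums(adj)
  B <- adj / ifelse(rs > 0, rs, 1)
  zero <- which(rs == 0)
  if (length(zero)) {
    if (zero_row_policy == "uniform") {
      B[zero, ] <- 1 / n
    } else {
      for (i in zero) B[i, i] <- 1
    }
  }
  B
}

check_transition <- function(trans, tol = 1e-8) {
  trans <- check_numeric_matrix(trans, "trans")
  if (nrow(trans) != ncol(trans)) stop("`trans` must be square", call. = FALSE)
  if (any(trans < -tol) || any(trans > 1 + tol)) {
    stop("`trans` entries must lie in [0, 1]", call. = FALSE)
  }
  if (any(abs(rowSums(trans) - 1) > tol)) {
    stop("`trans` rows must each sum to 1 (row-stochastic)", call. = FALSE)
  }
  trans
}

#' Diffusion states by random walk with restart
#'
#' For every source node `i`, iterates
#' `s^{t+1} = (1 - p_r) * s^t %*% B + p_r * delta_i` from `s^0 = delta_i`
#' until the L1 change drops below `tol`. The fixed point `s_i` is the
#' node's diffusion state: its j-th entry is the equilibrium probability
#' that a walk restarted at `i` with probability `p_r` per step is found at
#' `j`. Higher restart probabilities emphasize local network structure.
#'
#' All sources are iterated simultaneously (the matrix recurrence
#' `S <- (1 - p_r) S B + p_r I` starting from the identity).
#'
#' @param trans Row-stochastic transition matrix, e.g. from
#'   [row_normalize()].
#' @param restart_prob Restart probability in (0, 1]. Default 0.05, the
#'   value used for the gene and disease similarity networks.
#' @param tol Convergence threshold on the maximum per-row L1 change.
#' @param max_iter Iteration cap; non-convergence produces a warning and
#'   `converged = FALSE`, not an error.
#' @return An object of class `puimc_diffusion`: a list with `states` (the
#'   n x n row-stochastic diffusion-state matrix, row i = s_i), `node_ids`,
#'   `restart_prob`, `iterations` and `converged`.
#' @export
rwr_diffusion <- function(trans, restart_prob = 0.05, tol = 1e-6,
                          max_iter = 1000L) {
  trans <- check_transition(trans)
  if (!is.numeric(restart_prob) || length(restart_prob) != 1L ||
      restart_prob <= 0 || restart_prob > 1) {
    stop("`restart_prob` must lie in (0, 1]", call. = FALSE)
  }
  if (tol <= 0) stop("`tol` must be positive", call. = FALSE)
  if (max_iter < 1) stop("`max_iter` must be a positive integer", call. = FALSE)
  n <- nrow(trans)
  ids <- rownames(trans) %||% sprintf("n%d", seq_len(n))
  restart <- diag(restart_prob, n)
  S <- diag(n)
  converged <- FALSE
  iters <- 0L
  q <- 1 - restart_prob
  for (it in seq_len(max_iter)) {
    S_new <- q * (S %*% trans) + restart
    delta <- max(rowSums(abs(S_new - S)))
    S <- S_new
    iters <- it
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning(sprintf(
      "random walk did not converge within %d iterations (last L1 change %.3g)",
      max_iter, delta))
  }
  dimnames(S) <- list(ids, ids)
  structure(
    list(states = S, node_ids = ids, restart_prob = restart_prob,
         iterations = iters, converged = converged),
    class = "puimc_diffusion")
}

#' @export
print.puimc_diffusion <- function(x, ...) {
  cat(sprintf(
    "Diffusion states: %d nodes, restart %.3g, %d iterations (%s)\n",
    length(x$node_ids), x$restart_prob, x$iterations,
    if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

# Accept either a puimc_diffusion or a plain matrix of states.
diffusion_states <- function(S) {
  if (inherits(S, "puimc_diffusion")) S$states else check_numeric_matrix(S, "S")
}

#' Fuse diffusion states from multiple networks over a shared node set
#'
#' Column-wise concatenation of the diffusion-state matrices, preserving the
#' (identical) node order, so that a single joint embedding can be taken of
#' all networks at once. Nodes absent from one network should be added to it
#' as isolated nodes before normalization (see `zero_row_policy` in
#' [row_normalize()]).
#'
#' @param states_list List of `puimc_diffusion` objects (or state matrices
#'   with row names) sharing identical `node_ids` in identical order.
#' @return A numeric `n x (m*n)` matrix, the `m` diffusion blocks in list
#'   order; row names are the node ids.
#' @export
fuse_diffusion_states <- function(states_list) {
  if (!is.list(states_list) || length(states_list) == 0L) {
    stop("`states_list` must be a non-empty list", call. = FALSE)
  }
  mats <- lapply(states_list, diffusion_states)
  ids <- rownames(mats[[1L]]) %||% sprintf("n%d", seq_len(nrow(mats[[1L]])))
  for (i in seq_along(mats)) {
    ids_i <- rownames(mats[[i]]) %||% sprintf("n%d", seq_len(nrow(mats[[i]])))
    if (!identical(ids_i, ids)) {
      missing_here <- setdiff(ids, ids_i)
      extra_here <- setdiff(ids_i, ids)
      stop(sprintf(
        paste0("network %d has a different node set/order than network 1",
               " (missing: %s; extra: %s)"),
        i,
        if (length(missing_here)) paste(missing_here, collapse = ", ") else "none",
        if (length(extra_here)) paste(extra_here, collapse = ", ") else "none"),
        call. = FALSE)
    }
  }
  out <- do.call(cbind, mats)
  rownames(out) <- ids
  colnames(out) <- unlist(lapply(seq_along(mats), function(i) {
    paste0("net", i, ".", ids)
  }))
  out
}
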