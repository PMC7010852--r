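# PU-biased inductive matrix completion.
#
# The model scores a gene-disease pair bilinearly, score(i, j) =
# x_i' G H' y_j, with low-rank factors G (f_g x k) and H (f_d x k) learned
# from observed positives (weight 1, target 1) and all remaining cells
# treated as alpha-down-weighted negatives (weight alpha < 1, target 0):
#
#   min_{G,H}  sum_{(i,j) in pos} (1 - x_i'GH'y_j)^2
#            + alpha * sum_{(i,j) not in pos} (x_i'GH'y_j)^2
#            + (lambda/2) (||G||_F^2 + ||H||_F^2)
#
# Fixing one factor makes the other a weighted ridge problem. The full
# unlabeled complement is kept (no negative sampling): its uniform alpha
# weight splits the normal operator into a Kronecker-structured background
# term plus a sparse correction supported on the positives, so a sweep
# costs O(|pos| k + (f_g + f_d) k^2 max(N_g, N_d)).

#' Bilinear association score for one gene-disease pair
#'
#' Returns `x' G H' y`: the inner product of the gene's and disease's
#' latent projections. Higher scores indicate a more likely association.
#'
#' @param gene_feature Numeric vector of length `f_g`.
#' @param disease_feature Numeric vector of length `f_d`.
#' @param factors A `puimc_factors` object (or list with `G`, `H`).
#' @return A single number.
#' @export
score_pair <- function(gene_feature, disease_feature, factors) {
  G <- factors$G
  H <- factors$H
  if (length(gene_feature) != nrow(G) || length(disease_feature) != nrow(H)) {
    stop("feature vector lengths do not match the factor dimensions",
         call. = FALSE)
  }
  drop(crossprod(crossprod(G, gene_feature), crossprod(H, disease_feature)))
}

# sum of squared scores over ALL cells via the k x k trace identity
total_score_sq <- function(E, D) {
  sum(crossprod(E) * crossprod(D))
}

# scores at the positive cells only
scores_at <- function(E, D, pos) {
  rowSums(E[pos[, 1L], , drop = FALSE] * D[pos[, 2L], , drop = FALSE])
}

#' PU-weighted objective value
#'
#' Evaluates the biased matrix-completion objective: squared loss 1 on the
#' observed positives (target 1), squared loss weighted by `alpha` on every
#' other cell (target 0), plus the factored trace-norm surrogate
#' `(lambda/2)(||G||_F^2 + ||H||_F^2)`.
#'
#' @param P Binary association matrix (sparse or dense), genes x diseases.
#' @param gene_features `N_g x f_g` matrix.
#' @param disease_features `N_d x f_d` matrix.
#' @param factors List with factors `G` (`f_g x k`) and `H` (`f_d x k`).
#' @param alpha Weight of the unlabeled cells, in (0, 1].
#' @param lambda Ridge penalty, `>= 0`.
#' @return A single non-negative number.
#' @export
pu_objective <- function(P, gene_features, disease_features, factors,
                         alpha, lambda) {
  assoc <- as_association(P)
  X <- check_numeric_matrix(gene_features)
  Y <- check_numeric_matrix(disease_features)
  if (nrow(X) != nrow(assoc$P) || nrow(Y) != ncol(assoc$P)) {
    stop("feature row counts do not match the association matrix",
         call. = FALSE)
  }
  if (alpha <= 0 || alpha > 1) stop("`alpha` must lie in (0, 1]", call. = FALSE)
  if (lambda < 0) stop("`lambda` must be >= 0", call. = FALSE)
  E <- X %*% factors$G
  D <- Y %*% factors$H
  s_pos <- scores_at(E, D, assoc$positives)
  sum((1 - s_pos)^2) + alpha * (total_score_sq(E, D) - sum(s_pos^2)) +
    (lambda / 2) * (sum(factors$G^2) + sum(factors$H^2))
}

# Solve the weighted ridge subproblem via preconditioned conjugate
# gradient on the normal equations
#   alpha Xs'Xs G Ds'Ds + (1-alpha) Xs' M(G) Ds + (lambda/2) G = Xs' P Ds
# where M(G) is the score matrix restricted to the positive support.
# The alpha-uniform background plus the ridge,
# M0 = alpha (Ds'Ds kron Xs'Xs) + (lambda/2) I, inverts exactly through
# the eigendecompositions of the two small Gram matrices and serves as
# the preconditioner; only the sparse positive correction remains. PCG
# monotonically decreases the subproblem quadratic, so warm-starting at
# the current factor preserves the monotone descent of the outer loop.
solve_imc_subproblem <- function(Xs, Ds, pos, alpha, lambda, G0,
                                 cg_tol = 1e-12, cg_maxit = 500L) {
  XtX <- crossprod(Xs)
  DtD <- crossprod(Ds)
  Psp <- Matrix::sparseMatrix(i = pos[, 1L], j = pos[, 2L], x = 1,
                              dims = c(nrow(Xs), nrow(Ds)))
  b <- as.matrix(Matrix::crossprod(Xs, Psp %*% Ds))
  Aop <- function(G) {
    out <- alpha * (XtX %*% G %*% DtD)
    if (alpha < 1) {
      vals <- scores_at(Xs %*% G, Ds, pos)
      Ssp <- Matrix::sparseMatrix(i = pos[, 1L], j = pos[, 2L], x = vals,
                                  dims = c(nrow(Xs), nrow(Ds)))
      out <- out + (1 - alpha) * as.matrix(Matrix::crossprod(Xs, Ssp %*% Ds))
    }
    out + (lambda / 2) * G
  }
  ex <- eigen(XtX, symmetric = TRUE)
  ed <- eigen(DtD, symmetric = TRUE)
  denom <- alpha * outer(pmax(ex$values, 0), pmax(ed$values, 0)) + lambda / 2
  denom <- pmax(denom, .Machine$double.xmin)
  Minv <- function(R) {
    ex$vectors %*% ((crossprod(ex$vectors, R) %*% ed$vectors) / denom) %*%
      t(ed$vectors)
  }
  G <- G0
  r <- b - Aop(G)
  bnorm <- sqrt(sum(b * b))
  if (bnorm == 0) bnorm <- 1
  z <- Minv(r)
  p <- z
  rz <- sum(r * z)
  for (it in seq_len(cg_maxit)) {
    if (sqrt(sum(r * r)) <= cg_tol * bnorm) break
    Ap <- Aop(p)
    curv <- sum(p * Ap)
    if (curv <= 0) break  # ridge floor keeps this positive in practice
    a <- rz / curv
    G <- G + a * p
    r <- r - a * Ap
    z <- Minv(r)
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
  }
  G
}

#' Fit the PU inductive matrix completion model
#'
#' Alternating minimization: with `H` fixed the objective is a weighted
#' ridge problem in `G` (and vice versa); each subproblem is convex and
#' solved exactly (conjugate gradient on its normal equations, warm-started
#' at the current factor), so the objective is non-increasing at every
#' half-sweep. Stops when the relative objective decrease over a full sweep
#' falls below `rel_tol`, or after `max_sweeps`.
#'
#' @param P Binary gene x disease association matrix (sparse or dense);
#'   nonzero cells are the observed positives, everything else is unlabeled.
#' @param gene_features `N_g x f_g` feature matrix (rows aligned with `P`).
#' @param disease_features `N_d x f_d` feature matrix.
#' @param k Rank of the bilinear model, `k <= min(f_g, f_d)`. Default 200.
#' @param lambda Ridge penalty, default 0.02.
#' @param alpha Weight of unlabeled cells, default 0.0035. Must satisfy
#'   `alpha <= 1`; values below 1 encode the PU prior that known positives
#'   outweigh unknown cells.
#' @param max_sweeps Cap on alternating sweeps, default 50.
#' @param rel_tol Relative objective-decrease stopping threshold, 1e-5.
#' @param seed Seed for the Gaussian factor initialization.
#' @param init_scale Standard deviation of the initial factor entries.
#' @param cg_tol,cg_maxit Inner conjugate-gradient controls.
#' @return Object of class `puimc_factors`: `G`, `H`, `objective_history`
#'   (value at initialization then after every half-sweep), `sweeps`,
#'   `converged`, and the fitting parameters.
#' @export
fit_puimc <- function(P, gene_features, disease_features, k = 200L,
                      lambda = 0.02, alpha = 0.0035, max_sweeps = 50L,
                      rel_tol = 1e-5, seed = 1L, init_scale = 0.01,
                      cg_tol = 1e-12, cg_maxit = 500L) {
  assoc <- as_association(P)
  X <- check_numeric_matrix(gene_features)
  Y <- check_numeric_matrix(disease_features)
  pos <- assoc$positives
  if (nrow(pos) == 0L) stop("no observed positives to train on", call. = FALSE)
  if (nrow(X) != nrow(assoc$P) || nrow(Y) != ncol(assoc$P)) {
    stop("feature row counts do not match the association matrix",
         call. = FALSE)
  }
  k <- as.integer(k)
  if (k < 1L || k > min(ncol(X), ncol(Y))) {
    stop(sprintf("`k` must lie in [1, %d] (min of the feature widths)",
                 min(ncol(X), ncol(Y))), call. = FALSE)
  }
  if (alpha <= 0 || alpha > 1) stop("`alpha` must lie in (0, 1]", call. = FALSE)
  if (lambda < 0) stop("`lambda` must be >= 0", call. = FALSE)

  init <- with_seed(seed, list(
    G = matrix(stats::rnorm(ncol(X) * k, sd = init_scale), ncol(X), k),
    H = matrix(stats::rnorm(ncol(Y) * k, sd = init_scale), ncol(Y), k)))
  G <- init$G
  H <- init$H

  objective <- function(G, H) {
    E <- X %*% G
    D <- Y %*% H
    s_pos <- scores_at(E, D, pos)
    sum((1 - s_pos)^2) + alpha * (total_score_sq(E, D) - sum(s_pos^2)) +
      (lambda / 2) * (sum(G^2) + sum(H^2))
  }

  history <- objective(G, H)
  pos_t <- pos[, 2:1, drop = FALSE]
  converged <- FALSE
  sweeps <- 0L
  for (sweep in seq_len(max_sweeps)) {
    obj_prev <- history[length(history)]
    G <- solve_imc_subproblem(X, Y %*% H, pos, alpha, lambda, G,
                              cg_tol, cg_maxit)
    history <- c(history, objective(G, H))
    H <- solve_imc_subproblem(Y, X %*% G, pos_t, alpha, lambda, H,
                              cg_tol, cg_maxit)
    obj <- objective(G, H)
    history <- c(history, obj)
    sweeps <- sweep
    if (obj_prev > 0 && (obj_prev - obj) / obj_prev < rel_tol) {
      converged <- TRUE
      break
    }
  }
  structure(
    list(G = G, H = H, objective_history = history, sweeps = sweeps,
         converged = converged, k = k, lambda = lambda, alpha = alpha,
         seed = seed,
         gene_ids = rownames(assoc$P), disease_ids = colnames(assoc$P)),
    class = "puimc_factors")
}

#' @export
print.puimc_factors <- function(x, ...) {
  cat(sprintf(
    "PU-IMC factors: rank %d, lambda %.3g, alpha %.4g; %d sweeps (%s), objective %.6g\n",
    x$k, x$lambda, x$alpha, x$sweeps,
    if (x$converged) "converged" else "max sweeps",
    x$objective_history[length(x$objective_history)]))
  invisible(x)
}

# Normalize an exclusion specification (NULL, 2-column index matrix, or
# sparse matrix) into a per-disease list of excluded gene indices.
exclusion_list <- function(exclude, n_genes, n_diseases) {
  out <- vector("list", n_diseases)
  if (is.null(exclude)) return(out)
  if (inherits(exclude, "sparseMatrix")) exclude <- positives_of(exclude)
  exclude <- check_pairs(exclude, n_genes, n_diseases, "exclude")
  split_idx <- split(exclude[, 1L], factor(exclude[, 2L],
                                           levels = seq_len(n_diseases)))
  for (j in seq_len(n_diseases)) out[[j]] <- as.integer(split_idx[[j]])
  out
}

rankings_from_scores <- function(S, exclude = NULL, gene_ids = NULL,
                                 disease_ids = NULL) {
  S <- check_numeric_matrix(S, "S")
  n_genes <- nrow(S)
  n_diseases <- ncol(S)
  excl <- exclusion_list(exclude, n_genes, n_diseases)
  genes <- vector("list", n_diseases)
  scores <- vector("list", n_diseases)
  for (j in seq_len(n_diseases)) {
    cand <- if (length(excl[[j]])) {
      setdiff(seq_len(n_genes), excl[[j]])
    } else {
      seq_len(n_genes)
    }
    s <- S[cand, j]
    o <- order(-s, cand)  # descending score, ties by ascending gene index
    genes[[j]] <- cand[o]
    scores[[j]] <- s[o]
  }
  structure(
    list(genes = genes, scores = scores,
         n_candidates = vapply(genes, length, integer(1L)),
         n_genes = n_genes,
         gene_ids = gene_ids %||% rownames(S) %||%
           sprintf("gene_%d", seq_len(n_genes)),
         disease_ids = disease_ids %||% colnames(S) %||%
           sprintf("disease_%d", seq_len(n_diseases))),
    class = "puimc_rankings")
}

#' Rank candidate genes for every disease
#'
#' Scores every gene-disease cell with the fitted bilinear model and sorts
#' each disease's genes by descending score. Ties are broken by ascending
#' gene index (deterministic). Pairs in `exclude` — typically the training
#' positives of each disease — are removed from that disease's candidate
#' list before ranking.
#'
#' Because the model is inductive, a disease never seen during training
#' still receives a full ranking from its feature vector alone.
#'
#' @param factors A `puimc_factors` fit.
#' @param gene_features,disease_features Feature matrices (rows = entities;
#'   may contain entities unseen during training).
#' @param exclude `NULL`, a two-column (gene, disease) index matrix, or a
#'   sparse matrix whose nonzero cells are excluded per disease.
#' @return Object of class `puimc_rankings`: per-disease ordered gene index
#'   vectors with scores, candidate counts and id vectors.
#' @export
predict_rankings <- function(factors, gene_features, disease_features,
                             exclude = NULL) {
  X <- check_numeric_matrix(gene_features)
  Y <- check_numeric_matrix(disease_features)
  S <- (X %*% factors$G) %*% t(Y %*% factors$H)
  rownames(S) <- rownames(X)
  colnames(S) <- rownames(Y)
  rankings_from_scores(S, exclude)
}

#' @export
print.puimc_rankings <- function(x, ...) {
  cat(sprintf("Rankings for %d diseases over %d genes (candidates: %d-%d)\n",
              length(x$genes), x$n_genes, min(x$n_candidates),
              max(x$n_candidates)))
  invisible(x)
}
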