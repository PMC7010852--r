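# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

check_numeric_matrix <- function(x, name = deparse(substitute(x)),
                                 finite = TRUE) {
  if (inherits(x, "Matrix")) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(sprintf("`%s` must be a numeric matrix", name), call. = FALSE)
  }
  if (finite && !all(is.finite(x))) {
    stop(sprintf("`%s` contains non-finite entries", name), call. = FALSE)
  }
  x
}

# Coerce an association matrix (binary, sparse or dense) to dgCMatrix and
# return it with its positive index set.
as_association <- function(P, name = "P") {
  if (is.matrix(P)) P <- methods::as(P, "CsparseMatrix")
  if (!inherits(P, "sparseMatrix")) {
    stop(sprintf("`%s` must be a (sparse) matrix", name), call. = FALSE)
  }
  if (inherits(P, "nMatrix")) P <- methods::as(P, "dMatrix")  # pattern -> 1s
  P <- methods::as(methods::as(P, "generalMatrix"), "CsparseMatrix")
  tp <- methods::as(P, "TsparseMatrix")
  x <- if (length(tp@x)) tp@x else rep(1, length(tp@i))
  keep <- x != 0
  if (any(x[keep] != 1)) {
    stop(sprintf("`%s` must be binary (entries 0/1)", name), call. = FALSE)
  }
  pos <- cbind(gene = tp@i[keep] + 1L, disease = tp@j[keep] + 1L)
  list(P = P, positives = pos)
}

positives_of <- function(P) as_association(P)$positives

check_pairs <- function(pairs, n_genes, n_diseases, name = "pairs") {
  pairs <- as.matrix(pairs)
  if (ncol(pairs) != 2L) {
    stop(sprintf("`%s` must have two columns (gene, disease)", name),
         call. = FALSE)
  }
  storage.mode(pairs) <- "integer"
  if (nrow(pairs) &&
      (any(pairs[, 1L] < 1L) || any(pairs[, 1L] > n_genes) ||
       any(pairs[, 2L] < 1L) || any(pairs[, 2L] > n_diseases))) {
    stop(sprintf("`%s` contains out-of-range indices", name), call. = FALSE)
  }
  colnames(pairs) <- c("gene", "disease")
  pairs
}
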