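# Plain-text readers/writers for the on-disk formats: edge-list TSV,
# association triplet TSV, MatrixMarket, dense feature TSV, ranking TSV.
# Readers reject malformed input with the offending line number rather
# than silently coercing; all on-disk artifacts use string identifiers.

split_fields <- function(lines) strsplit(trimws(lines), "[ \t]+")

#' Read a weighted edge list
#'
#' Parses 2- or 3-column whitespace/tab-separated lines
#' (`node_a node_b [weight]`); missing weights default to 1. Lines starting
#' with `#` and blank lines are ignored. Self-loops are dropped with a
#' warning; duplicate edges keep the maximum weight (with a warning when
#' the weights disagree). With `undirected = TRUE` (default) the matrix is
#' symmetrized by the elementwise maximum.
#'
#' @param path File path.
#' @param undirected Symmetrize by max (default `TRUE`).
#' @param node_ids Optional identifiers to include even when isolated; the
#'   node universe is their union with the endpoints, sorted.
#' @return Adjacency matrix with node ids as dimnames.
#' @export
read_edge_list <- function(path, undirected = TRUE, node_ids = NULL) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  fields <- split_fields(lines[keep])
  nfield <- lengths(fields)
  bad <- which(nfield < 2L | nfield > 3L)
  if (length(bad)) {
    stop(sprintf("line %d: expected 2 or 3 columns, found %d",
                 idx[bad[1L]], nfield[bad[1L]]), call. = FALSE)
  }
  a <- vapply(fields, `[`, "", 1L)
  b <- vapply(fields, `[`, "", 2L)
  w <- vapply(seq_along(fields), function(i) {
    if (nfield[i] == 3L) {
      wi <- suppressWarnings(as.numeric(fields[[i]][3L]))
      if (is.na(wi)) {
        stop(sprintf("line %d: weight '%s' is not numeric",
                     idx[i], fields[[i]][3L]), call. = FALSE)
      }
      wi
    } else 1
  }, numeric(1L))
  neg <- which(w < 0)
  if (length(neg)) {
    stop(sprintf("line %d: negative edge weight %g", idx[neg[1L]], w[neg[1L]]),
         call. = FALSE)
  }
  loop <- a == b
  if (any(loop)) {
    warning(sprintf("dropped %d self-loop(s)", sum(loop)))
    a <- a[!loop]; b <- b[!loop]; w <- w[!loop]
  }
  ids <- sort(unique(c(a, b, node_ids)))
  if (length(ids) == 0L) stop("edge list contains no edges", call. = FALSE)
  n <- length(ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  ii <- match(a, ids)
  jj <- match(b, ids)
  dup_warned <- FALSE
  for (e in seq_along(ii)) {
    prev <- A[ii[e], jj[e]]
    if (prev > 0 && prev != w[e] && !dup_warned) {
      warning("duplicate edge(s) with differing weights; keeping the maximum")
      dup_warned <- TRUE
    }
    A[ii[e], jj[e]] <- max(prev, w[e])
  }
  if (undirected) A <- pmax(A, t(A))
  A
}

#' Write an adjacency matrix as an edge list
#'
#' Writes tab-separated `node_a node_b weight` rows for the nonzero cells,
#' in deterministic (row, column) order. Symmetric matrices are written as
#' their upper triangle.
#'
#' @param adj Adjacency matrix with node ids as dimnames.
#' @param path Output path.
#' @export
write_edge_list <- function(adj, path) {
  adj <- as_adjacency(adj)
  ids <- rownames(adj)
  sym <- isTRUE(all.equal(adj, t(adj), check.attributes = FALSE))
  sel <- if (sym) which(upper.tri(adj) & adj != 0) else which(adj != 0)
  rc <- arrayInd(sel, dim(adj))
  o <- order(rc[, 1L], rc[, 2L])
  rc <- rc[o, , drop = FALSE]
  writeLines(sprintf("%s\t%s\t%s", ids[rc[, 1L]], ids[rc[, 2L]],
                     format(adj[rc], trim = TRUE, digits = 10)),
             path)
  invisible(path)
}

#' Read a sparse binary association matrix
#'
#' Triplet TSV format: three tab/whitespace-separated columns
#' `gene_id  disease_id  1`; any value other than 1 is rejected (the matrix
#' is binary by construction — unknown cells are simply absent). Duplicated
#' pairs are collapsed with a warning. MatrixMarket coordinate files
#' (`.mtx`) are also accepted; their rows/columns get generated ids.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"tsv"`, or `"matrix_market"`.
#' @return Sparse binary `Matrix` with gene/disease ids as dimnames.
#' @export
read_association_matrix <- function(path,
                                    format = c("auto", "tsv",
                                               "matrix_market")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.mtx$", path)) "matrix_market" else "tsv"
  }
  if (format == "matrix_market") {
    M <- Matrix::readMM(path)
    if (inherits(M, "nMatrix")) M <- methods::as(M, "dMatrix")
    M <- methods::as(M, "CsparseMatrix")
    if (length(M@x) && any(M@x != 1)) {
      stop("association matrix must be binary: found a value other than 1",
           call. = FALSE)
    }
    dimnames(M) <- list(sprintf("gene_%d", seq_len(nrow(M))),
                        sprintf("disease_%d", seq_len(ncol(M))))
    return(M)
  }
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) stop("no positives: association file is empty",
                              call. = FALSE)
  fields <- split_fields(lines[keep])
  bad <- which(lengths(fields) != 3L)
  if (length(bad)) {
    stop(sprintf("line %d: expected 3 columns (gene, disease, 1), found %d",
                 idx[bad[1L]], lengths(fields)[bad[1L]]), call. = FALSE)
  }
  g <- vapply(fields, `[`, "", 1L)
  d <- vapply(fields, `[`, "", 2L)
  v <- vapply(fields, `[`, "", 3L)
  notone <- which(v != "1")
  if (length(notone)) {
    stop(sprintf("line %d: association value must be 1, found '%s'",
                 idx[notone[1L]], v[notone[1L]]), call. = FALSE)
  }
  pair_key <- paste(g, d, sep = "\r")
  if (anyDuplicated(pair_key)) {
    warning(sprintf("collapsed %d duplicated pair(s)",
                    sum(duplicated(pair_key))))
    first <- !duplicated(pair_key)
    g <- g[first]; d <- d[first]
  }
  gene_ids <- sort(unique(g))
  disease_ids <- sort(unique(d))
  Matrix::sparseMatrix(i = match(g, gene_ids), j = match(d, disease_ids),
                       x = 1,
                       dims = c(length(gene_ids), length(disease_ids)),
                       dimnames = list(gene_ids, disease_ids))
}

#' Write an association matrix as triplets or MatrixMarket
#'
#' @param P Sparse binary matrix with dimnames.
#' @param path Output path.
#' @param format `"tsv"` (default; `gene_id disease_id 1` rows in
#'   deterministic order) or `"matrix_market"`.
#' @export
write_association_matrix <- function(P, path,
                                     format = c("tsv", "matrix_market")) {
  format <- match.arg(format)
  assoc <- as_association(P)
  if (format == "matrix_market") {
    Matrix::writeMM(assoc$P, path)
    return(invisible(path))
  }
  pos <- assoc$positives
  o <- order(pos[, 1L], pos[, 2L])
  pos <- pos[o, , drop = FALSE]
  gids <- rownames(assoc$P) %||% sprintf("gene_%d", seq_len(nrow(assoc$P)))
  dids <- colnames(assoc$P) %||% sprintf("disease_%d", seq_len(ncol(assoc$P)))
  writeLines(sprintf("%s\t%s\t1", gids[pos[, 1L]], dids[pos[, 2L]]), path)
  invisible(path)
}

#' Read a dense feature table
#'
#' Tab-separated with a header row; the first column (`id`) holds entity
#' identifiers, remaining columns are numeric features.
#'
#' @param path File path.
#' @return Numeric matrix with ids as row names.
#' @export
read_feature_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  ids <- as.character(df[[1L]])
  M <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(M)) stop("feature columns must be numeric", call. = FALSE)
  rownames(M) <- ids
  M
}

#' Write a dense feature table
#'
#' @param X Numeric matrix with row names.
#' @param path Output path.
#' @export
write_feature_table <- function(X, path) {
  X <- check_numeric_matrix(X)
  df <- data.frame(id = rownames(X) %||% sprintf("e%d", seq_len(nrow(X))),
                   X, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write top-r rankings to TSV
#'
#' Columns `disease_id`, `rank`, `gene_id`, `score` (6 significant digits),
#' ranks `1..min(top_r, candidates)` per disease, byte-deterministic for
#' identical inputs.
#'
#' @param ranked A `puimc_rankings`.
#' @param top_r Number of top genes to write per disease.
#' @param path Output path.
#' @export
write_rankings <- function(ranked, top_r, path) {
  stopifnot(inherits(ranked, "puimc_rankings"))
  top_r <- as.integer(top_r)
  if (top_r < 1L) stop("`top_r` must be >= 1", call. = FALSE)
  rows <- lapply(seq_along(ranked$genes), function(j) {
    m <- min(top_r, ranked$n_candidates[j])
    if (m == 0L) return(NULL)
    data.frame(disease_id = ranked$disease_ids[j], rank = seq_len(m),
               gene_id = ranked$gene_ids[ranked$genes[[j]][seq_len(m)]],
               score = signif(ranked$scores[[j]][seq_len(m)], 6L))
  })
  out <- do.call(rbind, rows)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a rankings TSV written by [write_rankings()]
#'
#' @param path File path.
#' @return Data frame with columns `disease_id`, `rank`, `gene_id`, `score`.
#' @export
read_rankings <- function(path) {
  utils::read.delim(path, colClasses = c("character", "integer",
                                         "character", "numeric"))
}
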