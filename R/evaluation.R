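# Evaluation: recall@r, precision@r, mean percentile ranking, and the
# three hold-out protocols (global three-fold CV over positives, new-gene
# and new-disease single-association hold-outs).

#' Three-fold split of the observed positives
#'
#' Randomly partitions the positive set into three near-equal folds, so
#' that hiding each fold in turn yields the global cross-validation
#' protocol (every positive hidden exactly once).
#'
#' @param P Binary association matrix.
#' @param seed RNG seed; the partition is deterministic given the seed.
#' @return Object of class `puimc_cv_split`: `positives` (2-column index
#'   matrix), `fold` (integer 1-3 per positive), `protocol = "global"`.
#' @export
threefold_split <- function(P, seed) {
  pos <- positives_of(P)
  n <- nrow(pos)
  if (n < 3L) stop("need at least 3 positives for a three-fold split",
                   call. = FALSE)
  fold <- with_seed(seed, {
    f <- rep_len(1:3, n)
    f[sample.int(n)]
  })
  structure(list(positives = pos, fold = fold, protocol = "global"),
            class = "puimc_cv_split")
}

#' Single-association hold-out (new-gene / new-disease protocol)
#'
#' Selects every gene (row) or disease (column) with exactly one observed
#' association; those unique positives form the validation set and are
#' hidden during training. This isolates the inductive setting: entities
#' that are essentially unknown to the association matrix.
#'
#' @param P Binary association matrix.
#' @param axis `"gene"` (rows with row sum 1) or `"disease"` (columns with
#'   column sum 1).
#' @return Object of class `puimc_cv_split` with `hidden` (2-column index
#'   matrix of the held-out positives) and `protocol`
#'   (`"new_gene"`/`"new_disease"`).
#' @export
single_association_holdout <- function(P, axis = c("gene", "disease")) {
  axis <- match.arg(axis)
  assoc <- as_association(P)
  pos <- assoc$positives
  sums <- if (axis == "gene") {
    tabulate(pos[, 1L], nbins = nrow(assoc$P))
  } else {
    tabulate(pos[, 2L], nbins = ncol(assoc$P))
  }
  qualifying <- which(sums == 1L)
  if (length(qualifying) == 0L) {
    stop(sprintf(
      "no new-%s candidates: 0 of %d %ss have exactly one association",
      axis, length(sums), axis), call. = FALSE)
  }
  col <- if (axis == "gene") 1L else 2L
  hidden <- pos[pos[, col] %in% qualifying, , drop = FALSE]
  structure(
    list(hidden = hidden, positives = pos,
         protocol = paste0("new_", axis), axis = axis,
         n_candidates = length(qualifying)),
    class = "puimc_cv_split")
}

# position (1-based rank) and candidate count of each hidden pair within
# its disease's ranking; errors if the pair cannot be looked up
hidden_positions <- function(ranked, hidden) {
  stopifnot(inherits(ranked, "puimc_rankings"))
  hidden <- check_pairs(hidden, ranked$n_genes, length(ranked$genes),
                        "hidden")
  n <- nrow(hidden)
  pos <- integer(n)
  ncand <- integer(n)
  for (idx in seq_len(n)) {
    g <- hidden[idx, 1L]
    d <- hidden[idx, 2L]
    p <- match(g, ranked$genes[[d]])
    if (is.na(p)) {
      stop(sprintf(
        "hidden pair (gene %d, disease %d) is not in the candidate list of its disease (was it excluded?)",
        g, d), call. = FALSE)
    }
    pos[idx] <- p
    ncand[idx] <- ranked$n_candidates[d]
  }
  list(hidden = hidden, position = pos, n_candidates = ncand)
}

#' Recall and precision at a top-r cutoff
#'
#' A hidden positive counts as a true positive when its gene appears within
#' the top `r` of its disease's ranking. False positives are the remaining
#' top-`r` slots of every evaluated disease (a disease with fewer than `r`
#' candidates contributes only its candidate count of slots); false
#' negatives are the hidden positives missed. Only diseases with at least
#' one hidden positive are evaluated.
#'
#' @param ranked A `puimc_rankings`.
#' @param hidden Two-column (gene, disease) index matrix of held-out
#'   positives.
#' @param r Top-list cutoff, `>= 1` (typically `r <= 100`).
#' @return Object of class `puimc_eval`: `recall`, `precision`, counts
#'   `TP`/`FP`/`FN`, `r`, and `per_disease` (data frame of TP and slots per
#'   evaluated disease).
#' @export
recall_precision_at_r <- function(ranked, hidden, r) {
  r <- as.integer(r)
  if (length(r) != 1L || is.na(r) || r < 1L) {
    stop("`r` must be a positive integer", call. = FALSE)
  }
  hp <- hidden_positions(ranked, hidden)
  hit <- hp$position <= r
  diseases <- sort(unique(hp$hidden[, 2L]))
  tp_d <- vapply(diseases, function(d) {
    sum(hit[hp$hidden[, 2L] == d])
  }, integer(1L))
  slots_d <- pmin(r, ranked$n_candidates[diseases])
  TP <- sum(tp_d)
  FN <- nrow(hp$hidden) - TP
  FP <- sum(slots_d - tp_d)
  structure(
    list(recall = TP / (TP + FN), precision = TP / (TP + FP),
         TP = TP, FP = FP, FN = FN, r = r,
         per_disease = data.frame(disease = diseases, TP = tp_d,
                                  slots = slots_d)),
    class = "puimc_eval")
}

#' @export
print.puimc_eval <- function(x, ...) {
  cat(sprintf("recall@%d = %.4f, precision@%d = %.4f (TP %d, FP %d, FN %d)\n",
              x$r, x$recall, x$r, x$precision, x$TP, x$FP, x$FN))
  invisible(x)
}

#' Percentile rank of a position in a ranked list
#'
#' `100 * (position - 1) / (n_candidates - 1)`: the top of the list maps to
#' 0% (most likely association) and the bottom to 100% (least likely),
#' reproducing both defining endpoints exactly. Vectorized.
#'
#' @param position Integer rank(s), `1 <= position <= n_candidates`.
#' @param n_candidates List length(s), `>= 2` (the percentile is undefined
#'   for a single candidate).
#' @return Percentile(s) in `[0, 100]`.
#' @export
percentile_rank <- function(position, n_candidates) {
  if (any(n_candidates < 2L)) {
    stop("`n_candidates` must be >= 2 for a percentile to be defined",
         call. = FALSE)
  }
  if (any(position < 1L) || any(position > n_candidates)) {
    stop("`position` must lie in [1, n_candidates]", call. = FALSE)
  }
  100 * (position - 1) / (n_candidates - 1)
}

#' Mean percentile ranking of hidden positives
#'
#' For each disease with at least one hidden positive, averages the
#' percentile ranks of its hidden genes (R_i); the MPR is the mean of R_i
#' over those diseases. Lower is better: 0% means every hidden association
#' was ranked first, and uniformly random scores give 50% in expectation.
#'
#' @param ranked A `puimc_rankings`.
#' @param hidden Two-column (gene, disease) index matrix; must be
#'   non-empty, and every referenced disease needs `>= 2` candidates.
#' @return A single number in `[0, 100]`, with attribute `per_disease`
#'   (named vector of R_i).
#' @export
mpr <- function(ranked, hidden) {
  if (is.null(hidden) || nrow(as.matrix(hidden)) == 0L) {
    stop("`hidden` is empty; MPR is undefined", call. = FALSE)
  }
  hp <- hidden_positions(ranked, hidden)
  pr <- percentile_rank(hp$position, hp$n_candidates)
  r_i <- tapply(pr, hp$hidden[, 2L], mean)
  out <- mean(r_i)
  attr(out, "per_disease") <- r_i
  out
}
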