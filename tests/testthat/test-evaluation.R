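toy_rankings <- function(score_matrix, exclude = NULL) {
  puimc:::rankings_from_scores(score_matrix, exclude)
}

test_that("three-fold split partitions the positives evenly", {
  P9 <- Matrix::sparseMatrix(i = 1:9, j = rep(1:3, 3), x = 1, dims = c(9, 3))
  s <- threefold_split(P9, seed = 1)
  expect_equal(sort(as.vector(table(s$fold))), c(3L, 3L, 3L))
  P10 <- Matrix::sparseMatrix(i = c(1:9, 1), j = c(rep(1:3, 3), 2), x = 1,
                              dims = c(9, 3))
  s10 <- threefold_split(P10, seed = 1)
  expect_equal(sort(as.vector(table(s10$fold))), c(3L, 3L, 4L))
  expect_identical(threefold_split(P10, seed = 5)$fold,
                   threefold_split(P10, seed = 5)$fold)
  # folds cover every positive exactly once
  expect_equal(nrow(s$positives), 9L)
  expect_true(all(s$fold %in% 1:3))
  P2 <- Matrix::sparseMatrix(i = 1:2, j = 1:2, x = 1, dims = c(3, 3))
  expect_error(threefold_split(P2, seed = 1), "at least 3")
})

test_that("single-association hold-out selects rows/columns with one positive", {
  # gene row sums (1, 2, 0, 1): genes 1 and 4 qualify
  P <- Matrix::sparseMatrix(i = c(1, 2, 2, 4), j = c(1, 1, 2, 3), x = 1,
                            dims = c(4, 3))
  ho <- single_association_holdout(P, axis = "gene")
  expect_equal(ho$hidden[order(ho$hidden[, 1]), ],
               cbind(gene = c(1L, 4L), disease = c(1L, 3L)),
               ignore_attr = TRUE)
  # symmetric toy: disease axis on t(P) picks the same pairs
  ho_t <- single_association_holdout(Matrix::t(P), axis = "disease")
  expect_equal(unname(ho_t$hidden[, c(2, 1)]), unname(ho$hidden))
  # no qualifying rows
  Pall2 <- Matrix::sparseMatrix(i = c(1, 1, 2, 2), j = c(1, 2, 1, 2), x = 1,
                                dims = c(2, 2))
  expect_error(single_association_holdout(Pall2, axis = "gene"),
               "no new-gene candidates")
})

test_that("recall and precision reproduce hand-enumerated cases", {
  # one disease, hidden gene ranked first
  rk <- toy_rankings(matrix(c(0.9, 0.1, 0.2), 3, 1))
  ev <- recall_precision_at_r(rk, cbind(1L, 1L), r = 1)
  expect_equal(ev$recall, 1)
  expect_equal(ev$precision, 1)
  # hidden gene just outside the cutoff
  rk2 <- toy_rankings(matrix(c(3, 2, 1), 3, 1))
  ev2 <- recall_precision_at_r(rk2, cbind(3L, 1L), r = 2)
  expect_equal(ev2$recall, 0)
  expect_equal(ev2$precision, 0)
  # two diseases, hidden ranks {1, 3} and {12}, r = 10:
  # TP = 2, recall 2/3, precision 2/20
  s1 <- seq(20, 1)            # disease 1: gene g has rank g
  rk3 <- toy_rankings(cbind(s1, s1))
  hidden <- rbind(c(1L, 1L), c(3L, 1L), c(12L, 2L))
  ev3 <- recall_precision_at_r(rk3, hidden, r = 10)
  expect_equal(ev3$TP, 2L)
  expect_equal(ev3$recall, 2 / 3)
  expect_equal(ev3$precision, 0.10)
  # recall is non-decreasing in r; precision * slots returns TP exactly
  recalls <- vapply(c(1, 3, 10, 12, 20), function(r) {
    e <- recall_precision_at_r(rk3, hidden, r)
    expect_equal(e$precision * sum(pmin(r, rk3$n_candidates[1:2])), e$TP)
    e$recall
  }, numeric(1))
  expect_true(all(diff(recalls) >= 0))
})

test_that("percentile rank hits both defining endpoints", {
  expect_equal(percentile_rank(1, 10), 0)      # top of the list
  expect_equal(percentile_rank(10, 10), 100)   # bottom of the list
  expect_equal(percentile_rank(2, 3), 50)
  expect_error(percentile_rank(1, 1), ">= 2")
  expect_error(percentile_rank(5, 4), "position")
})

test_that("MPR averages per-disease percentile ranks", {
  # hidden ranks 1-of-5 (PR 0) and 3-of-5 (PR 50): MPR 25
  s <- c(5, 4, 3, 2, 1)
  rk <- toy_rankings(cbind(s, s))
  expect_equal(as.numeric(mpr(rk, rbind(c(1L, 1L), c(3L, 2L)))), 25)
  # perfect model: every hidden gene first
  expect_equal(as.numeric(mpr(rk, rbind(c(1L, 1L), c(1L, 2L)))), 0)
  expect_error(mpr(rk, cbind(integer(0), integer(0))), "empty")
  # hidden pair whose gene was excluded from its disease is rejected
  rk_ex <- toy_rankings(cbind(s, s), exclude = cbind(1L, 1L))
  expect_error(mpr(rk_ex, rbind(c(1L, 1L))), "candidate list")
})

test_that("MPR is invariant to disease order and monotone score maps", {
  S <- puimc:::with_seed(51, matrix(runif(40 * 6), 40, 6))
  hidden <- puimc:::with_seed(52, cbind(sample(40, 6), 1:6))
  m1 <- as.numeric(mpr(toy_rankings(S), hidden))
  # strictly monotone transformation of scores
  expect_equal(as.numeric(mpr(toy_rankings(exp(3 * S)), hidden)), m1)
  # permuting diseases
  perm <- c(3, 1, 2, 6, 5, 4)
  hidden_p <- cbind(hidden[, 1], match(hidden[, 2], perm))
  expect_equal(as.numeric(mpr(toy_rankings(S[, perm]), hidden_p)), m1)
  # reversing every ranking reflects the MPR around 50
  expect_equal(as.numeric(mpr(toy_rankings(-S), hidden)), 100 - m1)
})
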