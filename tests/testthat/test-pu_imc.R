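test_that("bilinear score matches its explicit double sum", {
  k <- 4
  expect_equal(score_pair(c(1, 0, 0, 0), c(1, 0, 0, 0),
                          list(G = diag(4), H = diag(4))), 1)
  expect_equal(score_pair(rnorm(4), rnorm(4),
                          list(G = matrix(0, 4, 2), H = matrix(0, 4, 2))), 0)
  puimc:::with_seed(21, {
    x <- rnorm(4); y <- rnorm(4)
    G <- matrix(rnorm(8), 4, 2); H <- matrix(rnorm(8), 4, 2)
    Z <- G %*% t(H)
    brute <- sum(outer(x, y) * Z)
    expect_equal(score_pair(x, y, list(G = G, H = H)), brute,
                 tolerance = 1e-12)
  })
  expect_error(score_pair(rnorm(3), rnorm(4), list(G = diag(4), H = diag(4))),
               "dimension")
})

test_that("PU objective matches entrywise brute force", {
  inst <- puimc:::with_seed(22, {
    P <- Matrix::sparseMatrix(i = c(1, 2, 5, 6), j = c(1, 3, 2, 4), x = 1,
                              dims = c(6, 4))
    list(P = P, X = matrix(rnorm(6 * 5), 6, 5), Y = matrix(rnorm(4 * 3), 4, 3),
         G = matrix(rnorm(5 * 2), 5, 2), H = matrix(rnorm(3 * 2), 3, 2))
  })
  # zero factors, lambda 0: every positive contributes (1-0)^2
  expect_equal(pu_objective(inst$P, inst$X, inst$Y,
                            list(G = inst$G * 0, H = inst$H * 0),
                            alpha = 0.5, lambda = 0), 4)
  # brute-force double loop over all cells
  brute <- function(alpha, lambda) {
    Pd <- as.matrix(inst$P)
    Z <- inst$G %*% t(inst$H)
    total <- (lambda / 2) * (sum(inst$G^2) + sum(inst$H^2))
    for (i in 1:6) for (j in 1:4) {
      s <- drop(inst$X[i, ] %*% Z %*% inst$Y[j, ])
      w <- if (Pd[i, j] == 1) 1 else alpha
      total <- total + w * (Pd[i, j] - s)^2
    }
    total
  }
  fac <- list(G = inst$G, H = inst$H)
  expect_equal(pu_objective(inst$P, inst$X, inst$Y, fac, 0.0035, 0.02),
               brute(0.0035, 0.02), tolerance = 1e-10)
  # alpha = 1 collapses to the unweighted full-matrix squared error
  expect_equal(pu_objective(inst$P, inst$X, inst$Y, fac, 1, 0),
               brute(1, 0), tolerance = 1e-10)
})

test_that("alternating fit descends monotonically and beats its init", {
  inst <- planted_imc_instance(seed = 1)
  fit <- fit_puimc(inst$P, inst$X, inst$Y, k = 2, lambda = 1e-4,
                   alpha = 0.0035, seed = 3)
  h <- fit$objective_history
  expect_true(all(diff(h) <= 1e-9))
  expect_lt(h[length(h)], 0.1 * h[1])
})

test_that("alpha=1 subproblem equals the closed-form ridge solution", {
  # tiny instance: solve the vectorized normal equations densely
  puimc:::with_seed(23, {
    X <- matrix(rnorm(12 * 4), 12, 4)
    Y <- matrix(rnorm(8 * 3), 8, 3)
    H <- matrix(rnorm(3 * 2), 3, 2)
    P <- Matrix::sparseMatrix(i = c(1, 4, 7), j = c(2, 5, 8), x = 1,
                              dims = c(12, 8))
    pos <- puimc:::positives_of(P)
    lambda <- 0.05
    D <- Y %*% H
    G <- puimc:::solve_imc_subproblem(X, D, pos, alpha = 1, lambda = lambda,
                                      G0 = matrix(0, 4, 2))
    # oracle: A vec(G) = vec(X' P D) with A = (D'D kron X'X) + lambda/2 I
    A <- kronecker(crossprod(D), crossprod(X)) + diag(lambda / 2, 8)
    rhs <- as.vector(crossprod(X, as.matrix(P) %*% D))
    expect_equal(as.vector(G), solve(A, rhs), tolerance = 1e-6)
  })
})

test_that("feature rescaling cancels in the small-ridge limit", {
  inst <- planted_imc_instance(seed = 2)
  f1 <- fit_puimc(inst$P, inst$X, inst$Y, k = 2, lambda = 1e-8,
                  alpha = 0.0035, seed = 5, max_sweeps = 10)
  c <- 4
  f2 <- fit_puimc(inst$P, inst$X * c, inst$Y, k = 2, lambda = 1e-8,
                  alpha = 0.0035, seed = 5, init_scale = 0.01 / c,
                  max_sweeps = 10)
  # same seed draws the same init, rescaled; score matrices must agree
  s1 <- (inst$X %*% f1$G) %*% t(inst$Y %*% f1$H)
  s2 <- ((inst$X * c) %*% f2$G) %*% t(inst$Y %*% f2$H)
  expect_equal(s1, s2, tolerance = 1e-4)
})

test_that("down-weighting unknowns (PU) improves held-out ranking", {
  puimc:::with_seed(24, {
    gf <- make_side_features(150, 20, 5, 0.1, seed = 71)
    df <- make_side_features(60, 15, 5, 0.1, seed = 72)
    pl <- plant_associations(gf, df, 5, 0.05, 0.25, seed = 73)
    run_mpr <- function(alpha) {
      fit <- fit_puimc(pl$assoc, gf, df, k = 5, lambda = 0.02,
                       alpha = alpha, seed = 74)
      mpr(predict_rankings(fit, gf, df, exclude = pl$assoc), pl$hidden)
    }
    m_pu <- run_mpr(0.0035)
    m_off <- run_mpr(1e-6)
    expect_lt(as.numeric(m_pu), as.numeric(m_off))
    expect_lt(as.numeric(m_pu), 45)  # far better than a random ~50%
  })
})

test_that("a disease unseen in training still receives a full ranking", {
  inst <- planted_imc_instance(seed = 3)
  drop_d <- 5L
  keep <- inst$positives[, 2] != drop_d
  P2 <- Matrix::sparseMatrix(i = inst$positives[keep, 1],
                             j = inst$positives[keep, 2], x = 1,
                             dims = dim(inst$P))
  fit <- fit_puimc(P2, inst$X, inst$Y, k = 2, lambda = 0.02,
                   alpha = 0.0035, seed = 6)
  ranked <- predict_rankings(fit, inst$X, inst$Y)
  expect_length(ranked$genes[[drop_d]], nrow(inst$X))
  expect_true(all(is.finite(ranked$scores[[drop_d]])))
})

test_that("rankings sort by score with deterministic tie-breaks", {
  S <- matrix(c(0.9, 0.1, 0.5,
                0.2, 0.2, 0.2), 3, 2)
  rk <- puimc:::rankings_from_scores(S)
  expect_equal(rk$genes[[1]], c(1L, 3L, 2L))  # argmax first
  expect_equal(rk$genes[[2]], c(1L, 2L, 3L))  # all-equal: ascending index
  # excluding the top gene promotes the runner-up
  rk2 <- puimc:::rankings_from_scores(S, exclude = cbind(1L, 1L))
  expect_equal(rk2$genes[[1]], c(3L, 2L))
  expect_equal(rk2$n_candidates, c(2L, 3L))
})

test_that("invalid completion configurations are rejected", {
  inst <- planted_imc_instance(seed = 4)
  expect_error(fit_puimc(inst$P, inst$X, inst$Y, k = 50), "feature widths")
  expect_error(fit_puimc(inst$P, inst$X, inst$Y, k = 2, alpha = 0),
               "alpha")
  empty <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = dim(inst$P))
  expect_error(fit_puimc(empty, inst$X, inst$Y, k = 2), "no observed positives")
})
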