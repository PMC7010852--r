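test_that("log transform maps zero diffusion mass to zero", {
  expect_equal(unname(log_transform(matrix(0, 2, 2), 0.5)),
               matrix(0, 2, 2), ignore_attr = TRUE)
  expect_equal(log_transform(matrix(1), 1)[1, 1], log(2))
  expect_equal(unname(log_transform(diag(2), 0.5)),
               matrix(c(log(3), 0, 0, log(3)), 2, 2), ignore_attr = TRUE)
  expect_error(log_transform(matrix(c(-0.1, 1, 0, 1), 2, 2), 0.5),
               "non-negative")
  expect_error(log_transform(matrix(1, 2, 2), 0), "positive")
})

test_that("svd embedding is the best rank-d approximation", {
  L <- puimc:::with_seed(31, matrix(rnorm(400), 20, 20))
  sv_full <- svd(L)$d
  errs <- vapply(c(1, 2, 5, 10), function(d) {
    e <- svd_embed(L, d)
    err2 <- sum((e$node_features %*% t(e$context_features) - L)^2)
    # Eckart-Young: squared error equals the discarded squared spectrum
    expect_equal(err2, sum(sv_full[-seq_len(d)]^2), tolerance = 1e-6)
    err2
  }, numeric(1))
  expect_true(all(diff(errs) <= 0))  # non-increasing in d
  # full rank reconstructs exactly
  ef <- svd_embed(L, 20)
  expect_lt(sqrt(sum((ef$node_features %*% t(ef$context_features) - L)^2)),
            1e-8)
  # rank-1 input at d = 1
  L1 <- outer(1:5, c(2, -1, 3))
  e1 <- svd_embed(L1, 1)
  expect_lt(max(abs(e1$node_features %*% t(e1$context_features) - L1)), 1e-8)
  expect_error(svd_embed(L, 21), "\\[1, 20\\]")
})

test_that("no random factor pair beats the svd embedding", {
  L <- puimc:::with_seed(32, matrix(rnorm(400), 20, 20))
  d <- 4
  e <- svd_embed(L, d)
  best <- sum((e$node_features %*% t(e$context_features) - L)^2)
  errs <- puimc:::with_seed(33, vapply(1:200, function(i) {
    sum((matrix(rnorm(20 * d), 20) %*% t(matrix(rnorm(20 * d), 20)) - L)^2)
  }, numeric(1)))
  expect_true(all(errs >= best))
})

test_that("svd embedding is deterministic and ordered", {
  L <- puimc:::with_seed(34, matrix(rnorm(200), 20, 10))
  e1 <- svd_embed(L, 5)
  e2 <- svd_embed(L, 5)
  expect_identical(e1$node_features, e2$node_features)
  expect_true(all(diff(e1$singular_values) <= 0))
  expect_true(all(e1$singular_values >= 0))
})

test_that("KL diagnostic agrees with brute-force divergence", {
  # 4-node instance: compare against a double-loop evaluation
  S <- puimc:::with_seed(35, {
    M <- matrix(runif(16), 4, 4)
    M / rowSums(M)
  })
  emb <- puimc:::with_seed(36, list(node_features = matrix(rnorm(8), 4, 2),
                                    context_features = matrix(rnorm(8), 4, 2)))
  brute <- {
    logits <- emb$node_features %*% t(emb$context_features)
    total <- 0
    for (i in 1:4) {
      shat <- exp(logits[i, ]) / sum(exp(logits[i, ]))
      for (j in 1:4) total <- total + S[i, j] * (log(S[i, j]) - log(shat[j]))
    }
    total / 4
  }
  expect_equal(kl_objective(S, emb), brute, tolerance = 1e-10)
  expect_gte(kl_objective(S, emb), 0)
})

test_that("KL diagnostic is zero iff the softmax model reproduces S", {
  # build S from the embedding's own softmax: divergence must vanish
  emb <- puimc:::with_seed(37, list(node_features = matrix(rnorm(12), 6, 2),
                                    context_features = matrix(rnorm(12), 6, 2)))
  logits <- emb$node_features %*% t(emb$context_features)
  S <- exp(logits) / rowSums(exp(logits))
  expect_lt(kl_objective(S, emb), 1e-12)
  # zero embedding => uniform model; uniform S => zero divergence
  zero_emb <- list(node_features = matrix(0, 4, 2),
                   context_features = matrix(0, 4, 2))
  expect_equal(kl_objective(matrix(0.25, 4, 4), zero_emb), 0)
  # a different S gives strictly positive divergence
  S2 <- matrix(1 / 6, 6, 6)
  expect_gt(kl_objective(S2, emb), 0)
  expect_error(kl_objective(matrix(1, 2, 2), zero_emb), "probability")
})

test_that("rescaling node and context features symmetrically changes nothing", {
  S <- puimc:::with_seed(38, {
    M <- matrix(runif(25), 5, 5)
    M / rowSums(M)
  })
  emb <- puimc:::with_seed(39, list(node_features = matrix(rnorm(15), 5, 3),
                                    context_features = matrix(rnorm(15), 5, 3)))
  for (c in c(0.1, 2, 10)) {
    scaled <- list(node_features = emb$node_features * c,
                   context_features = emb$context_features / c)
    expect_equal(kl_objective(S, scaled), kl_objective(S, emb),
                 tolerance = 1e-10)
  }
})
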