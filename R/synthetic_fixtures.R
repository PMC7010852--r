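# Synthetic fixture generators: modular similarity networks, correlated
# noisy feature tables, and sparse bipartite positives planted from a
# low-rank bilinear model. Everything is deterministic under a fixed seed.
#
# The fixtures deliberately plant associations from the same model family
# the completion step fits (a favorable case): they test the
# implementation end to end, not the biological claim that real
# gene-disease data has this structure.

#' Fixture configuration
#'
#' Defaults define the standard desk-scale recovery experiment: 300 genes,
#' 120 diseases, two gene networks, rank-10 planted truth, 5% positive
#' density with 20% of positives withheld as hidden ground truth.
#' `feature_noise_sd` is relative to the unit-scale latent signal
#' (default 0.1, i.e. 10% noise).
#'
#' @param n_genes,n_diseases Entity counts.
#' @param n_networks Number of gene similarity networks to generate.
#' @param n_modules Community count for the planted-partition networks.
#' @param f_g,f_d Feature-table widths for genes and diseases.
#' @param k_true Rank of the planted bilinear model.
#' @param positive_density Fraction of cells planted as positives.
#' @param feature_noise_sd Gaussian noise sd added to the feature tables.
#' @param hidden_fraction Fraction of planted positives withheld from
#'   training as ground truth.
#' @param p_in,p_out Within/between-module edge probabilities.
#' @param seed Master seed; stage seeds are derived from it.
#' @return List of class `fixture_config`.
#' @export
fixture_config <- function(n_genes = 300L, n_diseases = 120L,
                           n_networks = 2L, n_modules = 6L,
                           f_g = 40L, f_d = 30L, k_true = 10L,
                           positive_density = 0.05,
                           feature_noise_sd = 0.1,
                           hidden_fraction = 0.2,
                           p_in = 0.15, p_out = 0.02, seed = 7L) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_diseases = as.integer(n_diseases),
              n_networks = as.integer(n_networks),
              n_modules = as.integer(n_modules),
              f_g = as.integer(f_g), f_d = as.integer(f_d),
              k_true = as.integer(k_true),
              positive_density = positive_density,
              feature_noise_sd = feature_noise_sd,
              hidden_fraction = hidden_fraction,
              p_in = p_in, p_out = p_out, seed = as.integer(seed))
  if (cfg$k_true > min(cfg$f_g, cfg$f_d)) {
    stop("`k_true` must be <= min(f_g, f_d)", call. = FALSE)
  }
  if (cfg$positive_density <= 0 || cfg$positive_density >= 1) {
    stop("`positive_density` must lie in (0, 1)", call. = FALSE)
  }
  if (cfg$positive_density * cfg$n_genes * cfg$n_diseases < 10) {
    stop("fixture too sparse: fewer than 10 planted positives", call. = FALSE)
  }
  structure(cfg, class = "fixture_config")
}

#' Planted-partition similarity network
#'
#' Symmetric unweighted graph with `n_modules` communities: node pairs in
#' the same module are connected with probability `p_in`, pairs in
#' different modules with `p_out < p_in`. No self-loops.
#'
#' @param n Number of nodes.
#' @param n_modules Number of communities (balanced blocks unless
#'   `membership` is supplied).
#' @param p_in,p_out Edge probabilities, `0 <= p_out < p_in <= 1`.
#' @param seed RNG seed.
#' @param membership Optional integer vector of community labels.
#' @param node_ids Optional node identifiers (default `n001`, ...).
#' @return Adjacency matrix with node ids as dimnames.
#' @export
make_network <- function(n, n_modules, p_in, p_out, seed,
                         membership = NULL, node_ids = NULL) {
  n <- as.integer(n)
  if (!(p_out >= 0 && p_out < p_in && p_in <= 1)) {
    stop("require 0 <= p_out < p_in <= 1", call. = FALSE)
  }
  membership <- membership %||% sort(rep_len(seq_len(n_modules), n))
  if (length(membership) != n) {
    stop("`membership` must have one label per node", call. = FALSE)
  }
  node_ids <- node_ids %||% sprintf("n%03d", seq_len(n))
  with_seed(seed, {
    same <- outer(membership, membership, `==`)
    prob <- ifelse(same, p_in, p_out)
    A <- matrix(0, n, n)
    ut <- upper.tri(A)
    A[ut] <- as.numeric(stats::runif(sum(ut)) < prob[ut])
    A <- A + t(A)
    dimnames(A) <- list(node_ids, node_ids)
    A
  })
}

#' Correlated noisy feature table with planted low-rank structure
#'
#' Rows are latent `n x k_true` Gaussian factors times a random
#' `k_true x f` loading matrix (scaled so signal entries have roughly unit
#' variance), plus i.i.d. Gaussian noise. The latent factors are attached
#' as attribute `"latent"` so associations can be planted from the same
#' latent space.
#'
#' @param n Number of entities (rows).
#' @param f Number of features (columns), `>= k_true`.
#' @param k_true Latent rank.
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed RNG seed.
#' @param ids Optional row identifiers.
#' @return `n x f` matrix with attribute `latent` (`n x k_true`).
#' @export
make_side_features <- function(n, f, k_true, noise_sd, seed, ids = NULL) {
  if (k_true > f) stop("`k_true` must be <= f", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  with_seed(seed, {
    latent <- matrix(stats::rnorm(n * k_true), n, k_true)
    loadings <- matrix(stats::rnorm(k_true * f), k_true, f) / sqrt(k_true)
    M <- latent %*% loadings
    if (noise_sd > 0) {
      M <- M + matrix(stats::rnorm(n * f, sd = noise_sd), n, f)
    }
    rownames(M) <- ids %||% sprintf("e%03d", seq_len(n))
    attr(M, "latent") <- latent
    M
  })
}

#' Plant sparse bipartite positives from a low-rank bilinear model
#'
#' Draws a random `k_true x k_true` core, scores every gene-disease cell
#' through the latent factors of the two feature tables (falling back to
#' random rank-`k_true` projections of the features themselves when no
#' latent attribute is present), and declares the top
#' `round(density * N_g * N_d)` cells positives. A `hidden_fraction` of the
#' positives is withheld as ground truth; the remaining cells are unlabeled
#' — the positive-unlabeled condition the completion step assumes.
#'
#' @param gene_features,disease_features Feature matrices, ideally from
#'   [make_side_features()] (their `latent` attributes drive the planting).
#' @param k_true Rank of the planted bilinear core.
#' @param positive_density Fraction of cells made positive.
#' @param hidden_fraction Fraction of positives withheld as hidden truth.
#' @param seed RNG seed.
#' @return List of class `puimc_planted`: `assoc` (sparse training matrix),
#'   `hidden` (2-column index matrix of withheld positives), `all_positives`,
#'   and `true_scores` (the planted score matrix).
#' @export
plant_associations <- function(gene_features, disease_features, k_true,
                               positive_density, hidden_fraction, seed) {
  Xg <- check_numeric_matrix(gene_features)
  Xd <- check_numeric_matrix(disease_features)
  if (hidden_fraction < 0 || hidden_fraction >= 1) {
    stop("`hidden_fraction` must lie in [0, 1)", call. = FALSE)
  }
  n_g <- nrow(Xg)
  n_d <- nrow(Xd)
  q <- round(positive_density * n_g * n_d)
  if (q < 1) stop("density too low: no positives to plant", call. = FALSE)
  with_seed(seed, {
    Ug <- attr(gene_features, "latent") %||%
      (Xg %*% matrix(stats::rnorm(ncol(Xg) * k_true), ncol(Xg)) / sqrt(ncol(Xg)))
    Ud <- attr(disease_features, "latent") %||%
      (Xd %*% matrix(stats::rnorm(ncol(Xd) * k_true), ncol(Xd)) / sqrt(ncol(Xd)))
    core <- matrix(stats::rnorm(ncol(Ug) * ncol(Ud)), ncol(Ug)) / sqrt(k_true)
    scores <- Ug %*% core %*% t(Ud)
    if (max(scores) - min(scores) < .Machine$double.eps * 100) {
      stop("degenerate planted scores (all cells equal)", call. = FALSE)
    }
    top <- order(scores, decreasing = TRUE)[seq_len(q)]
    pos <- arrayInd(top, dim(scores))
    colnames(pos) <- c("gene", "disease")
    n_hidden <- round(hidden_fraction * q)
    hid_idx <- if (n_hidden > 0) sample.int(q, n_hidden) else integer(0)
    hidden <- pos[hid_idx, , drop = FALSE]
    train <- pos[setdiff(seq_len(q), hid_idx), , drop = FALSE]
    if (nrow(train) == 0L) stop("all positives hidden; nothing to train on",
                                call. = FALSE)
    P <- Matrix::sparseMatrix(i = train[, 1L], j = train[, 2L], x = 1,
                              dims = c(n_g, n_d),
                              dimnames = list(rownames(Xg), rownames(Xd)))
    structure(
      list(assoc = P, hidden = hidden, all_positives = pos,
           true_scores = scores, core = core),
      class = "puimc_planted")
  })
}

#' End-to-end parameter-recovery experiment on a synthetic fixture
#'
#' Runs the full pipeline on one generated instance: plants features and
#' associations; builds planted-partition networks whose module labels come
#' from k-means on the latent factors (so network topology carries signal
#' about the planted truth); extracts diffusion-state embeddings (restart
#' random walk, log transform, truncated SVD) and denoising-autoencoder
#' codes; concatenates and standardizes the two feature blocks per side;
#' fits the PU completion model; and evaluates the hidden positives with
#' training positives excluded from each disease's candidate list.
#'
#' A random-ranking baseline (uniform scores on the same candidate sets and
#' hidden split) is evaluated alongside; it should sit at ~50% MPR.
#'
#' @param cfg A [fixture_config()].
#' @param k Completion rank (default 20, the desk-scale analogue of the
#'   full-scale rank-200 setting).
#' @param lambda,alpha,restart_prob Model parameters (defaults 0.02,
#'   0.0035 and 0.05).
#' @param r Top-list cutoff for recall/precision (default 100).
#' @param gene_embed_dim,disease_embed_dim Network embedding dimensions.
#' @param dae_code_dim Autoencoder code width per side.
#' @param dae_epochs Autoencoder training epochs.
#' @param shuffle_disease_features If `TRUE`, permute the rows of the
#'   disease feature matrix before fitting — a negative control that breaks
#'   the feature/association link and should push MPR toward 50%.
#' @param return_details If `TRUE`, attach the fitted factors, rankings and
#'   fixture to the report.
#' @return List of class `puimc_recovery`: `mpr`, `recall`, `precision`,
#'   `random_mpr`, `n_hidden`, plus `details` when requested.
#' @export
parameter_recovery_experiment <- function(cfg = fixture_config(),
                                          k = 20L, lambda = 0.02,
                                          alpha = 0.0035,
                                          restart_prob = 0.05, r = 100L,
                                          gene_embed_dim = 30L,
                                          disease_embed_dim = 20L,
                                          dae_code_dim = 10L,
                                          dae_epochs = 60L,
                                          shuffle_disease_features = FALSE,
                                          return_details = FALSE) {
  stopifnot(inherits(cfg, "fixture_config"))
  gf <- make_side_features(cfg$n_genes, cfg$f_g, cfg$k_true,
                           cfg$feature_noise_sd, seed = cfg$seed + 11L,
                           ids = sprintf("g%04d", seq_len(cfg$n_genes)))
  df <- make_side_features(cfg$n_diseases, cfg$f_d, cfg$k_true,
                           cfg$feature_noise_sd, seed = cfg$seed + 12L,
                           ids = sprintf("d%04d", seq_len(cfg$n_diseases)))
  planted <- plant_associations(gf, df, cfg$k_true, cfg$positive_density,
                                cfg$hidden_fraction, seed = cfg$seed + 13L)

  memb_g <- with_seed(cfg$seed + 14L,
                      stats::kmeans(attr(gf, "latent"), centers = cfg$n_modules,
                                    nstart = 5L)$cluster)
  memb_d <- with_seed(cfg$seed + 15L,
                      stats::kmeans(attr(df, "latent"), centers = cfg$n_modules,
                                    nstart = 5L)$cluster)
  gene_nets <- lapply(seq_len(cfg$n_networks), function(i) {
    make_network(cfg$n_genes, cfg$n_modules, cfg$p_in, cfg$p_out,
                 seed = cfg$seed + 20L + i, membership = memb_g,
                 node_ids = rownames(gf))
  })
  disease_net <- make_network(cfg$n_diseases, cfg$n_modules, cfg$p_in,
                              cfg$p_out, seed = cfg$seed + 30L,
                              membership = memb_d, node_ids = rownames(df))

  diff_g <- lapply(gene_nets, function(A) {
    rwr_diffusion(row_normalize(A), restart_prob = restart_prob)
  })
  emb_g <- svd_embed(log_transform(fuse_diffusion_states(diff_g)),
                     gene_embed_dim)
  emb_d <- svd_embed(log_transform(
    rwr_diffusion(row_normalize(disease_net), restart_prob = restart_prob)),
    disease_embed_dim)

  dae_g <- train_dae(gf, dae_config(
    layer_sizes = c(24L, dae_code_dim), epochs = dae_epochs,
    batch_size = 50L, learning_rate = 3e-3, seed = cfg$seed + 31L))
  dae_d <- train_dae(df, dae_config(
    layer_sizes = c(20L, dae_code_dim), epochs = dae_epochs,
    batch_size = 50L, learning_rate = 3e-3, seed = cfg$seed + 32L))

  standardize <- function(M) {
    sds <- apply(M, 2L, stats::sd)
    sds[sds < 1e-12] <- 1
    sweep(sweep(M, 2L, colMeans(M), `-`), 2L, sds, `/`)
  }
  X <- standardize(cbind(emb_g$node_features, encode(gf, dae_g)))
  Y <- standardize(cbind(emb_d$node_features, encode(df, dae_d)))
  rownames(X) <- rownames(gf)
  rownames(Y) <- rownames(df)
  if (shuffle_disease_features) {
    Y <- Y[with_seed(cfg$seed + 41L, sample.int(nrow(Y))), , drop = FALSE]
    rownames(Y) <- rownames(df)
  }

  fit <- fit_puimc(planted$assoc, X, Y, k = k, lambda = lambda,
                   alpha = alpha, seed = cfg$seed + 51L)
  ranked <- predict_rankings(fit, X, Y, exclude = planted$assoc)
  m <- mpr(ranked, planted$hidden)
  rp <- recall_precision_at_r(ranked, planted$hidden, r)

  rand_scores <- with_seed(cfg$seed + 61L,
                           matrix(stats::runif(cfg$n_genes * cfg$n_diseases),
                                  cfg$n_genes, cfg$n_diseases))
  rand_ranked <- rankings_from_scores(rand_scores, exclude = planted$assoc,
                                      gene_ids = rownames(X),
                                      disease_ids = rownames(Y))
  random_mpr <- mpr(rand_ranked, planted$hidden)

  out <- list(mpr = as.numeric(m), recall = rp$recall,
              precision = rp$precision, random_mpr = as.numeric(random_mpr),
              r = rp$r, n_hidden = nrow(planted$hidden),
              n_train_positives = nrow(planted$all_positives) -
                nrow(planted$hidden),
              seed = cfg$seed)
  if (return_details) {
    out$details <- list(fit = fit, ranked = ranked, planted = planted,
                        gene_features = X, disease_features = Y)
  }
  structure(out, class = "puimc_recovery")
}

#' @export
print.puimc_recovery <- function(x, ...) {
  cat(sprintf(
    paste0("Recovery experiment (seed %d): MPR %.2f%% (random baseline",
           " %.2f%%), recall@%d %.3f, precision@%d %.4f [%d hidden]\n"),
    x$seed, x$mpr, x$random_mpr, x$r, x$recall, x$r, x$precision,
    x$n_hidden))
  invisible(x)
}
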