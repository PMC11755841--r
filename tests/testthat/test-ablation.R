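test_that("PCA feature embeddings are complete and variance-ordered", {
  d <- tiny_dataset(seed = 51, n_features = 5, n_items = 30, n_users = 25)
  emb <- selt_embeddings(d$S, d$P, d$A, "PCAf", d = 5)
  U <- emb$feature_embeddings
  expect_equal(dim(U), c(5L, 5L))
  # full-rank coordinates match the PCA scores up to component sign, and
  # reconstruct the centred matrix through the component basis
  M <- jeli:::impute0(cbind(d$S, d$P))
  Mc <- M - rowMeans(M)                    # centred over features
  pc <- stats::prcomp(M, center = TRUE)
  flip <- sign(vapply(seq_len(5), function(k)
    pc$x[which.max(abs(pc$x[, k])), k], numeric(1)))
  expect_equal(unname(U), unname(sweep(pc$x, 2, flip, "*")),
               tolerance = 1e-10)
  recon <- pc$x %*% t(pc$rotation) +
    matrix(colMeans(M), nrow(M), ncol(M), byrow = TRUE)
  expect_equal(recon, M, tolerance = 1e-8, ignore_attr = TRUE)
  # explained variance non-increasing
  expect_true(all(diff(emb$sdev) <= 1e-12))
  # sign canonicalisation: deterministic across repeated runs
  emb2 <- selt_embeddings(d$S, d$P, d$A, "PCAf", d = 5)
  expect_identical(emb$feature_embeddings, emb2$feature_embeddings)
  expect_error(selt_embeddings(d$S, d$P, d$A, "PCAf", d = 40), "rank")
})

test_that("entity embeddings derive from the PCA projection", {
  d <- tiny_dataset(seed = 52, n_features = 5, n_items = 20, n_users = 20)
  f <- selt_embeddings(d$S, d$P, d$A, "PCAf", d = 2)
  iu <- selt_embeddings(d$S, d$P, d$A, "PCAiu", d = 2)
  expect_equal(iu$item_embeddings,
               t(jeli:::impute0(d$S)) %*% f$feature_embeddings)
  expect_equal(dim(iu$user_embeddings), c(20L, 2L))
})

test_that("free MuRE embedding training returns finite per-entity vectors", {
  inp <- toy_kg_inputs()
  emb <- selt_embeddings(inp$S, inp$P, inp$A, "KGE", d = 2, seed = 1,
                         epochs = 10)
  expect_equal(dim(emb$all_embeddings), c(4L, 2L))  # 2 items, 1 user, 1 feat
  expect_true(all(is.finite(emb$all_embeddings)))
  emb2 <- selt_embeddings(inp$S, inp$P, inp$A, "KGE", d = 2, seed = 1,
                          epochs = 10)
  expect_identical(emb$all_embeddings, emb2$all_embeddings)
})

test_that("the frozen-embedding classifier head separates a separable toy", {
  # labels generated linearly from the embedding space
  set.seed(3)
  n_i <- 40; n_u <- 30
  Ei <- matrix(rnorm(n_i * 2), n_i, 2)
  Eu <- matrix(rnorm(n_u * 2), n_u, 2)
  marg <- outer(Ei[, 1] + Ei[, 2], Eu[, 1] + Eu[, 2], "+")
  A <- matrix(0L, n_i, n_u)
  A[marg > 0.5] <- 1L; A[marg < -0.5] <- -1L
  emb <- list(variant = "KGE", item_embeddings = Ei, user_embeddings = Eu)
  # complete separation: glm's separation warnings are expected here
  cl <- suppressWarnings(train_fixed_embedding_classifier(emb, A))
  sc <- cl$scores()
  acc <- mean(sign(sc[A != 0]) == A[A != 0])
  expect_gte(acc, 0.95)
  # zero embeddings collapse to the intercept: constant predictions
  emb0 <- list(variant = "KGE", item_embeddings = 0 * Ei,
               user_embeddings = 0 * Eu)
  cl0 <- train_fixed_embedding_classifier(emb0, A)
  expect_equal(max(cl0$scores()) - min(cl0$scores()), 0, tolerance = 1e-9)
  # single-class training set is rejected
  expect_error(train_fixed_embedding_classifier(emb, abs(A)),
               "single-class")
})

test_that("the ablation suite runs every arm and is reproducible", {
  res <- run_ablation_suite(variants = c("FM2", "CrossFM2", "SELT-PCAf",
                                         "SELT-PCAiu", "SELT-KGE", "JELI"),
                            sparsity_levels = 0.5, n_datasets = 1,
                            n_seeds = 1, n_items = 40, n_users = 30,
                            n_features = 6, base_seed = 5, epochs = 15)
  expect_equal(nrow(res$results), 6L)
  expect_true(all(is.finite(res$results$auc)))
  expect_true(all(is.finite(res$results$ns_auc)))
  expect_true(all(is.finite(res$results$ndcg)))
  expect_true(all(res$results$auc >= 0 & res$results$auc <= 1))
  res2 <- run_ablation_suite(variants = c("FM2", "SELT-PCAf"),
                             sparsity_levels = 0.5, n_datasets = 1,
                             n_seeds = 1, n_items = 40, n_users = 30,
                             n_features = 6, base_seed = 5, epochs = 15)
  expect_equal(res2$results$auc[1],
               res$results$auc[res$results$variant == "FM2"])
})

test_that("FM baselines recover a factorization-machine signal", {
  d <- tiny_dataset(seed = 53, n_items = 50, n_users = 40)
  sp <- jeli:::split_cells(d$A, 0.2, seed = 1)
  for (cross in c(FALSE, TRUE)) {
    m <- jeli:::train_fm_baseline(sp$A_train, d$S, d$P, dim = 2,
                                  cross = cross, epochs = 150, seed = 2)
    sc <- jeli:::predict_fm_baseline(m, d$S, d$P)
    expect_gte(auc(sp$labels, sc[sp$cells]), 0.85)
  }
  # the all-pairs scorer agrees with the per-pair definitions
  m <- jeli:::train_fm_baseline(sp$A_train, d$S, d$P, dim = 2,
                                cross = FALSE, epochs = 5, seed = 2)
  sc <- jeli:::predict_fm_baseline(m, d$S, d$P)
  x15 <- c(jeli:::impute0(d$S)[, 1], jeli:::impute0(d$P)[, 5])
  expect_equal(sc[1, 5], fm_score(m$theta, x15), tolerance = 1e-10)
  mc <- jeli:::train_fm_baseline(sp$A_train, d$S, d$P, dim = 2,
                                 cross = TRUE, epochs = 5, seed = 2)
  scc <- jeli:::predict_fm_baseline(mc, d$S, d$P)
  expect_equal(scc[1, 5], crossfm_score(mc$theta, d$S[, 1], d$P[, 5]),
               tolerance = 1e-10)
})
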