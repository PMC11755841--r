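# Ablation arms: plain and cross-only factorization machines trained by
# logistic loss, and SELT variants (Separate Embedding Learning and
# Training) where embeddings are computed first — by PCA or by free MuRE
# knowledge-graph embedding — and then frozen while a small classifier head
# is fitted.

# Uniform 80/20-style split of the known (nonzero) cells of A.
split_cells <- function(A, test_fraction = 0.2, seed = 0L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, 606L))
  nz <- which(A != 0)
  n_test <- floor(test_fraction * length(nz))
  test_idx <- if (n_test > 0L) sample(nz, n_test) else integer(0)
  A_train <- A
  A_train[test_idx] <- 0L
  list(A_train = A_train, cells = test_idx, labels = A[test_idx])
}

# ---- factorization-machine baselines ---------------------------------------

# Logistic-loss training of a second-order FM (or cross-only FM) on the
# labelled cells of A_train. Full-batch Adam; deterministic given seed.
train_fm_baseline <- function(A_train, S, P, dim = 2L, cross = FALSE,
                              epochs = 200L, learning_rate = 0.05,
                              init_sd = 0.1, seed = 0L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, 707L))
  Xi_all <- t(impute0(S)); Xu_all <- t(impute0(P))
  F_ <- ncol(Xi_all)
  cells <- which(A_train != 0, arr.ind = TRUE)
  if (nrow(cells) == 0L) stop("no labelled training cells", call. = FALSE)
  y <- A_train[A_train != 0]
  Xi <- Xi_all[cells[, 1L], , drop = FALSE]
  Xu <- Xu_all[cells[, 2L], , drop = FALSE]
  X <- cbind(Xi, Xu)
  omega0 <- 0
  omega1 <- numeric(2L * F_)
  V <- matrix(stats::rnorm(2L * F_ * dim, sd = init_sd), 2L * F_, dim)
  st <- adam_state(list(omega0 = omega0, omega1 = omega1, V = V))
  for (ep in seq_len(epochs)) {
    if (cross) {
      Vt <- V[seq_len(F_), , drop = FALSE]
      Vb <- V[F_ + seq_len(F_), , drop = FALSE]
      zi <- Xi %*% Vt; zu <- Xu %*% Vb
      score <- omega0 + as.numeric(X %*% omega1) + rowSums(zi * zu)
    } else {
      z <- X %*% V
      score <- omega0 + as.numeric(X %*% omega1) +
        0.5 * (rowSums(z^2) - as.numeric((X^2) %*% rowSums(V^2)))
    }
    g <- -y * sigmoid(-y * score)            # d logistic loss / d score
    grad <- list(omega0 = sum(g), omega1 = as.numeric(crossprod(X, g)))
    if (cross) {
      grad$V <- rbind(crossprod(Xi * g, zu), crossprod(Xu * g, zi))
    } else {
      grad$V <- crossprod(X * g, z) -
        as.numeric(crossprod(X^2, g)) * V
    }
    upd <- adam_step(st, grad, learning_rate)
    st <- upd$state
    omega0 <- omega0 - upd$delta$omega0
    omega1 <- omega1 - upd$delta$omega1
    V <- V - upd$delta$V
  }
  theta <- list(omega0 = omega0, omega1 = omega1, V = V)
  list(theta = theta, cross = cross, F_ = F_)
}

# All-pairs score matrix of a trained FM/CrossFM baseline.
predict_fm_baseline <- function(model, S, P) {
  Xi <- t(impute0(S)); Xu <- t(impute0(P))
  F_ <- model$F_
  th <- model$theta
  Vt <- th$V[seq_len(F_), , drop = FALSE]
  Vb <- th$V[F_ + seq_len(F_), , drop = FALSE]
  li <- as.numeric(Xi %*% th$omega1[seq_len(F_)])
  lu <- as.numeric(Xu %*% th$omega1[F_ + seq_len(F_)])
  zi <- Xi %*% Vt; zu <- Xu %*% Vb
  cross <- tcrossprod(zi, zu)
  base <- th$omega0 + outer(li, lu, "+") + cross
  if (model$cross) return(base)
  wi <- 0.5 * (rowSums(zi^2) - as.numeric((Xi^2) %*% rowSums(Vt^2)))
  wu <- 0.5 * (rowSums(zu^2) - as.numeric((Xu^2) %*% rowSums(Vb^2)))
  base + outer(wi, wu, "+")
}

# ---- SELT embeddings --------------------------------------------------------

#' Separately learned embeddings for the SELT ablations
#'
#' `PCAf` runs a PCA on the F x (n_i + n_u) concatenation of the item and
#' user feature tables (features as observations) and returns each
#' feature's d leading principal-component coordinates. `PCAiu` projects
#' item and user feature vectors through those same feature coordinates to
#' obtain entity embeddings. `KGE` trains free (unstructured) MuRE
#' embeddings on the nine-relation knowledge graph with an empty prior and
#' returns the item and user embeddings. PCA component signs are
#' canonicalised (largest-magnitude coordinate positive).
#'
#' @param S,P Item and user feature tables (F x n_i, F x n_u).
#' @param A Association matrix (used by the KGE variant's graph).
#' @param variant `"PCAf"`, `"PCAiu"` or `"KGE"`.
#' @param d Embedding dimension.
#' @param seed Integer seed (KGE variant).
#' @param tau Similarity threshold of the graph (KGE variant).
#' @param epochs,learning_rate,margin MuRE training settings (KGE variant).
#' @return List with `variant` and, depending on it, `feature_embeddings`
#'   (F x d) and/or `item_embeddings` / `user_embeddings`.
#' @export
selt_embeddings <- function(S, P, A, variant = c("PCAf", "PCAiu", "KGE"),
                            d = 2L, seed = 0L, tau = 0.5, epochs = 100L,
                            learning_rate = 0.05, margin = 1) {
  variant <- match.arg(variant)
  d <- stopifnot_count(d, "d")
  if (variant %in% c("PCAf", "PCAiu")) {
    M <- cbind(impute0(S), impute0(P))
    pc <- stats::prcomp(M, center = TRUE, scale. = FALSE)
    if (d > ncol(pc$x))
      stop("'d' exceeds the rank of the concatenated feature matrix",
           call. = FALSE)
    U <- pc$x[, seq_len(d), drop = FALSE]
    for (k in seq_len(d))                    # canonical sign per component
      if (U[which.max(abs(U[, k])), k] < 0) U[, k] <- -U[, k]
    rownames(U) <- rownames(S)
    if (variant == "PCAf")
      return(list(variant = variant, feature_embeddings = U,
                  sdev = pc$sdev[seq_len(d)]))
    return(list(variant = variant,
                item_embeddings = t(impute0(S)) %*% U,
                user_embeddings = t(impute0(P)) %*% U))
  }
  kg <- build_knowledge_graph(A, S, P, prior = NULL, tau = tau)
  emb <- train_mure_free(kg, d = d, seed = seed, epochs = epochs,
                         learning_rate = learning_rate, margin = margin)
  n_i <- ncol(S); n_u <- ncol(P)
  list(variant = variant,
       item_embeddings = emb$E[seq_len(n_i), , drop = FALSE],
       user_embeddings = emb$E[n_i + seq_len(n_u), , drop = FALSE],
       all_embeddings = emb$E)
}

# Free MuRE knowledge-graph embedding training (no structure function): one
# free d-vector per entity, MuRE scoring for all relations including +/-,
# margin ranking loss with head corruption, full-batch Adam.
train_mure_free <- function(kg, d = 2L, epochs = 100L, learning_rate = 0.05,
                            margin = 1, init_sd = 0.1, seed = 0L, ...) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, 808L))
  idx <- kg_index(kg)
  n_ent <- idx$n_ent
  E <- matrix(stats::rnorm(n_ent * d, sd = init_sd), n_ent, d)
  Rarr <- array(rep(diag(d), idx$n_rel), c(d, d, idx$n_rel))
  Erel <- matrix(stats::rnorm(idx$n_rel * d, sd = init_sd), idx$n_rel, d)
  bias <- numeric(n_ent)
  st <- adam_state(list(E = E, Rarr = Rarr, Erel = Erel, bias = bias))
  score_rel <- function(hh, rid, tt) {
    Rr <- matrix(Rarr[, , rid], d, d)
    U <- E[hh, , drop = FALSE] %*% t(Rr) - E[tt, , drop = FALSE] -
      matrix(Erel[rid, ], length(hh), d, byrow = TRUE)
    list(s = -rowSums(U^2) + bias[hh] + bias[tt], U = U)
  }
  for (ep in seq_len(epochs)) {
    cr <- corrupt_heads(idx$h, idx$r, idx$t, idx$part_id, idx$members,
                        idx$t_keys, n_ent, idx$n_rel)
    keep <- which(cr$valid)
    grad <- list(E = 0 * E, Rarr = 0 * Rarr, Erel = 0 * Erel,
                 bias = 0 * bias)
    for (rid in unique(idx$r)) {
      rows <- intersect(which(idx$r == rid), keep)
      if (length(rows) == 0L) next
      tr <- score_rel(idx$h[rows], rid, idx$t[rows])
      co <- score_rel(cr$hbar[rows], rid, idx$t[rows])
      g <- sigmoid(margin - tr$s + co$s)
      Rr <- matrix(Rarr[, , rid], d, d)
      for (side in 1:2) {
        U <- if (side == 1L) tr$U else co$U
        hh <- if (side == 1L) idx$h[rows] else cr$hbar[rows]
        w <- if (side == 1L) -g else g
        Uw <- U * w
        grad$Rarr[, , rid] <- grad$Rarr[, , rid] -
          2 * crossprod(Uw, E[hh, , drop = FALSE])
        grad$Erel[rid, ] <- grad$Erel[rid, ] + 2 * colSums(Uw)
        dE <- rowsum(rbind(-2 * (Uw %*% Rr), 2 * Uw),
                     c(hh, idx$t[rows]))
        ri <- as.integer(rownames(dE))
        grad$E[ri, ] <- grad$E[ri, , drop = FALSE] + dE
        bg <- rowsum(c(w, w), c(hh, idx$t[rows]))
        bi <- as.integer(rownames(bg))
        grad$bias[bi] <- grad$bias[bi] + as.numeric(bg)
      }
    }
    upd <- adam_step(st, grad, learning_rate)
    st <- upd$state
    E <- E - upd$delta$E
    Rarr <- Rarr - upd$delta$Rarr
    Erel <- Erel - upd$delta$Erel
    bias <- bias - upd$delta$bias
  }
  rownames(E) <- kg$entities
  list(E = E, Rarr = Rarr, Erel = Erel, bias = bias)
}

# ---- frozen-embedding classifier head --------------------------------------

#' Train the classifier head of a SELT variant on frozen embeddings
#'
#' With feature embeddings available (`PCAf`), the frozen matrix plays the
#' role of the structure matrix W of an order-2 RHOFM and the intercept,
#' linear weight and interaction weight are fitted by logistic regression
#' on the derived covariates (`e_i + e_u` and the pairwise kernel term).
#' With entity embeddings only (`PCAiu`, `KGE`), the interaction term has
#' no feature-level support and the head reduces to logistic regression on
#' `e_i + e_u`.
#'
#' @param embeddings A [selt_embeddings()] result.
#' @param A_train Association matrix whose nonzero cells are the training
#'   labels.
#' @param S,P Feature tables (needed to derive entity embeddings for the
#'   `PCAf` variant).
#' @return Classifier object with a `$scores(S, P)` function returning the
#'   all-pairs score matrix.
#' @export
train_fixed_embedding_classifier <- function(embeddings, A_train,
                                             S = NULL, P = NULL) {
  y <- A_train[A_train != 0]
  if (length(unique(y)) < 2L)
    stop("training cells are single-class; cannot fit the classifier head",
         call. = FALSE)
  cells <- which(A_train != 0, arr.ind = TRUE)
  y01 <- (y + 1) / 2
  if (embeddings$variant == "PCAf") {
    W <- embeddings$feature_embeddings
    Xi <- t(impute0(S)); Xu <- t(impute0(P))
    Ei <- Xi %*% W; Eu <- Xu %*% W
    wsq <- rowSums(W^2)
    ci <- as.numeric((Xi^2) %*% wsq); cu <- as.numeric((Xu^2) %*% wsq)
    z <- Ei[cells[, 1L], , drop = FALSE] + Eu[cells[, 2L], , drop = FALSE]
    pair <- 0.5 * (rowSums(z^2) - ci[cells[, 1L]] - cu[cells[, 2L]])
    df <- data.frame(z, pair = pair)
    fitg <- stats::glm(y01 ~ ., data = df, family = stats::binomial())
    beta <- stats::coef(fitg)
    beta[is.na(beta)] <- 0
    d <- ncol(W)
    scores <- function(S, P) {
      Xi <- t(impute0(S)); Xu <- t(impute0(P))
      Ei <- Xi %*% W; Eu <- Xu %*% W
      ci <- as.numeric((Xi^2) %*% wsq); cu <- as.numeric((Xu^2) %*% wsq)
      bz <- beta[1L + seq_len(d)]
      pairm <- 0.5 * (outer(rowSums(Ei^2) - ci, rowSums(Eu^2) - cu, "+") +
                        2 * tcrossprod(Ei, Eu))
      beta[[1L]] + outer(as.numeric(Ei %*% bz), as.numeric(Eu %*% bz), "+") +
        beta[[d + 2L]] * pairm
    }
    return(structure(list(variant = "PCAf", beta = beta, W = W,
                          scores = scores), class = "jeli_selt"))
  }
  Ei <- embeddings$item_embeddings
  Eu <- embeddings$user_embeddings
  z <- Ei[cells[, 1L], , drop = FALSE] + Eu[cells[, 2L], , drop = FALSE]
  df <- data.frame(z)
  fitg <- stats::glm(y01 ~ ., data = df, family = stats::binomial())
  beta <- stats::coef(fitg)
  beta[is.na(beta)] <- 0
  d <- ncol(Ei)
  scores <- function(S = NULL, P = NULL) {
    bz <- beta[1L + seq_len(d)]
    beta[[1L]] + outer(as.numeric(Ei %*% bz), as.numeric(Eu %*% bz), "+")
  }
  structure(list(variant = embeddings$variant, beta = beta, scores = scores),
            class = "jeli_selt")
}

# ---- experiment harnesses ---------------------------------------------------

#' Synthetic-data benchmark of the jointly trained model
#'
#' Generates `n_datasets` synthetic datasets of the requested kind and, for
#' each, fits the model on `n_seeds` random train/test splits and collects
#' held-out AUC, NS-AUC, NDCG and the Spearman correlation between fitted
#' and true feature importance.
#'
#' @param kind `"first_order"` or `"second_order"` generating model.
#' @param n_datasets,n_seeds Numbers of datasets and of splits per dataset.
#' @param sparsity Sparsity number of the generated association matrices.
#' @param n_features,dim,n_items,n_users Generator geometry.
#' @param base_seed Master seed; every dataset and split seed derives from
#'   it.
#' @param ... Passed to [jeli()] (e.g. `epochs`, `learning_rate`).
#' @param verbose Print one line per run.
#' @return Data frame with one row per (dataset, seed) run.
#' @export
run_synthetic_benchmark <- function(kind = "first_order", n_datasets = 10L,
                                    n_seeds = 10L, sparsity = 0.5,
                                    n_features = 10L, dim = 2L,
                                    n_items = 173L, n_users = 173L,
                                    base_seed = 0L, verbose = FALSE, ...) {
  rows <- vector("list", n_datasets * n_seeds)
  k <- 0L
  for (j in seq_len(n_datasets)) {
    ds <- simulate_dataset(n_features = n_features, dim = dim,
                           n_items = n_items, n_users = n_users,
                           kind = kind, sparsity = sparsity,
                           seed = derive_seed(base_seed, 11L, j))
    for (s in seq_len(n_seeds)) {
      fit <- jeli(ds$A, ds$S, ds$P, dim = dim,
                  seed = derive_seed(base_seed, 13L, j, s), ...)
      m <- holdout_metrics(fit, s_true = ds$s_star)
      k <- k + 1L
      rows[[k]] <- data.frame(kind = kind, sparsity = sparsity,
                              dataset = j, seed = s, auc = m$auc,
                              ns_auc = m$ns_auc, ndcg = m$ndcg,
                              rho = m$spearman_rho)
      if (verbose)
        message(sprintf("%s d%02d s%02d: auc %.3f ns %.3f rho %+.3f",
                        kind, j, s, m$auc, m$ns_auc, m$spearman_rho))
    }
  }
  do.call(rbind, rows)
}

#' Run the within-family ablation suite
#'
#' For every variant x sparsity x dataset x seed combination, trains the
#' variant on an 80/20 split of the known cells (the split is shared across
#' variants) and evaluates held-out AUC, NS-AUC and NDCG. Failures of a
#' single run are recorded and the suite continues.
#'
#' @param variants Subset of `c("FM2", "CrossFM2", "SELT-PCAf",
#'   "SELT-PCAiu", "SELT-KGE", "JELI")`.
#' @param sparsity_levels Sparsity numbers of the generated datasets.
#' @param n_datasets,n_seeds Datasets per sparsity and splits per dataset.
#' @param dim Embedding dimension shared by all arms.
#' @param n_features,n_items,n_users Generator geometry.
#' @param base_seed Master seed.
#' @param out Optional path: the per-run table is written there as TSV.
#' @param ... Passed to [jeli()] and the internal trainers (e.g. `epochs`).
#' @return List with `results` (per-run data frame, `NA` metrics on failed
#'   runs) and `summary` (mean and sd per variant x sparsity).
#' @export
run_ablation_suite <- function(variants = c("FM2", "CrossFM2", "SELT-PCAf",
                                            "SELT-PCAiu", "SELT-KGE",
                                            "JELI"),
                               sparsity_levels = c(0.5, 0.65, 0.8),
                               n_datasets = 2L, n_seeds = 5L, dim = 2L,
                               n_features = 10L, n_items = 173L,
                               n_users = 173L, base_seed = 0L, out = NULL,
                               ...) {
  variants <- match.arg(variants, several.ok = TRUE)
  rows <- list()
  for (sp in sparsity_levels) {
    for (j in seq_len(n_datasets)) {
      ds <- simulate_dataset(n_features = n_features, dim = dim,
                             n_items = n_items, n_users = n_users,
                             kind = "first_order", sparsity = sp,
                             seed = derive_seed(base_seed, 17L, round(100 * sp), j))
      for (s in seq_len(n_seeds)) {
        run_seed <- derive_seed(base_seed, 19L, round(100 * sp), j, s)
        sc <- split_cells(ds$A, 0.2, seed = run_seed)
        A_eval <- matrix(NA_real_, nrow(ds$A), ncol(ds$A))
        A_eval[ds$A == 0] <- 0
        A_eval[sc$cells] <- sc$labels
        for (v in variants) {
          res <- tryCatch({
            scores <- ablation_arm_scores(v, sc$A_train, ds, dim, run_seed,
                                          ...)
            # AUC on held-out labelled cells; ranking metrics over every
            # cell not seen in training (held-out labels + unknown zeros),
            # so memorisation earns no credit
            c(auc = auc(sc$labels, scores[sc$cells]),
              ns_auc = ns_auc(A_eval, scores),
              ndcg = ndcg_at_ni(A_eval, scores))
          }, error = function(e) {
            warning(sprintf("run failed (%s, sparsity %g, dataset %d, seed %d): %s",
                            v, sp, j, s, conditionMessage(e)))
            c(auc = NA_real_, ns_auc = NA_real_, ndcg = NA_real_)
          })
          rows[[length(rows) + 1L]] <-
            data.frame(variant = v, sparsity = sp, dataset = j, seed = s,
                       auc = res[["auc"]], ns_auc = res[["ns_auc"]],
                       ndcg = res[["ndcg"]])
        }
      }
    }
  }
  results <- do.call(rbind, rows)
  agg <- stats::aggregate(results[, c("auc", "ns_auc", "ndcg")],
                          by = results[, c("variant", "sparsity")],
                          FUN = function(x) c(mean = mean(x, na.rm = TRUE),
                                              sd = stats::sd(x, na.rm = TRUE)))
  if (!is.null(out))
    utils::write.table(results, out, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  list(results = results, summary = agg)
}

# Score matrix of one ablation arm, trained on A_train.
ablation_arm_scores <- function(variant, A_train, ds, dim, seed, ...) {
  switch(variant,
    "JELI" = {
      fit <- jeli(A_train, ds$S, ds$P, dim = dim, test_fraction = 0,
                  seed = seed, ...)
      predict(fit, type = "link")
    },
    "FM2" = predict_fm_baseline(
      train_fm_baseline(A_train, ds$S, ds$P, dim = dim, cross = FALSE,
                        seed = seed), ds$S, ds$P),
    "CrossFM2" = predict_fm_baseline(
      train_fm_baseline(A_train, ds$S, ds$P, dim = dim, cross = TRUE,
                        seed = seed), ds$S, ds$P),
    "SELT-PCAf" = {
      emb <- selt_embeddings(ds$S, ds$P, A_train, "PCAf", d = dim)
      cl <- train_fixed_embedding_classifier(emb, A_train, ds$S, ds$P)
      cl$scores(ds$S, ds$P)
    },
    "SELT-PCAiu" = {
      emb <- selt_embeddings(ds$S, ds$P, A_train, "PCAiu", d = dim)
      cl <- train_fixed_embedding_classifier(emb, A_train)
      cl$scores()
    },
    "SELT-KGE" = {
      emb <- selt_embeddings(ds$S, ds$P, A_train, "KGE", d = dim,
                             seed = seed)
      cl <- train_fixed_embedding_classifier(emb, A_train)
      cl$scores()
    },
    stop("unknown variant: ", variant))
}
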