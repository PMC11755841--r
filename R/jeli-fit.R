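# Joint training of the RHOFM classifier and MuRE knowledge-graph
# embeddings. All nine relations are scored through one parameter set: the
# + / - relations by the (signed) RHOFM, every other relation by MuRE on
# the structure embeddings s_W(x). Minimising a soft margin ranking loss
# with negative sampling over the whole graph therefore trains W (and the
# relation/bias parameters) on association prediction and graph completion
# at once.

#' Multi-relational Euclidean (MuRE) triplet score
#'
#' `-||R_r e_h - (e_t + e_r)||^2 + b_h + b_t`.
#'
#' @param e_h,e_t Head and tail embeddings (length d).
#' @param e_r Relation embedding (length d).
#' @param R_r d x d relation matrix.
#' @param b_h,b_t Head and tail scalar biases.
#' @return Scalar score.
#' @export
mure_score <- function(e_h, e_r, e_t, R_r, b_h = 0, b_t = 0) {
  d <- length(e_h)
  if (length(e_t) != d || length(e_r) != d || any(dim(R_r) != d))
    stop("embedding dimensions are inconsistent", call. = FALSE)
  u <- as.numeric(R_r %*% e_h) - (e_t + e_r)
  -sum(u^2) + b_h + b_t
}

#' Soft margin ranking loss
#'
#' `sum log(1 + exp(margin - score(true) + score(corrupted)))` over paired
#' positive/corrupted scores: non-negative, and decreasing as true triplets
#' outscore their corruptions. `strict_paper = TRUE` flips the orientation
#' of the score difference inside the exponential (the printed form, which
#' instead rewards low-scoring true triplets).
#'
#' @param pos_scores,neg_scores Equal-length numeric vectors, pairwise
#'   matched.
#' @param margin Non-negative margin (default 1).
#' @param strict_paper Use the flipped orientation.
#' @return Scalar loss; 0 for empty input.
#' @export
margin_ranking_loss <- function(pos_scores, neg_scores, margin = 1,
                                strict_paper = FALSE) {
  if (length(pos_scores) != length(neg_scores))
    stop("positive and corrupted scores must be paired", call. = FALSE)
  if (length(pos_scores) == 0L) return(0)
  z <- if (strict_paper) margin + pos_scores - neg_scores
       else margin - pos_scores + neg_scores
  sum(softplus(z))
}

# Numerically stable log(1 + exp(z)).
softplus <- function(z) {
  out <- z
  lo <- z < 30
  out[lo] <- log1p(exp(z[lo]))
  out
}

# ---- internal index structures ---------------------------------------------

# Integer encoding of a triplet for O(1)-ish membership tests.
triplet_keys <- function(h, r, t, n_ent, n_rel) {
  ((h - 1) * n_rel + (r - 1)) * n_ent + t
}

# Head corruptions drawn uniformly within the head's entity partition,
# rejecting corruptions that are themselves graph triplets. Returns the
# corrupted head indices and a validity flag (FALSE = partition exhausted
# after `rounds` rejection rounds; such pairs are skipped).
corrupt_heads <- function(h, r, t, part_id, members, t_keys, n_ent, n_rel,
                          rounds = 10L) {
  n <- length(h)
  hbar <- integer(n)
  for (pid in unique(part_id[h])) {
    rows <- which(part_id[h] == pid)
    pool <- members[[pid]]
    hbar[rows] <- pool[sample.int(length(pool), length(rows), replace = TRUE)]
  }
  bad <- triplet_keys(hbar, r, t, n_ent, n_rel) %in% t_keys
  round <- 0L
  while (any(bad) && round < rounds) {
    rows <- which(bad)
    for (pid in unique(part_id[h[rows]])) {
      sel <- rows[part_id[h[rows]] == pid]
      pool <- members[[pid]]
      hbar[sel] <- pool[sample.int(length(pool), length(sel), replace = TRUE)]
    }
    bad <- triplet_keys(hbar, r, t, n_ent, n_rel) %in% t_keys
    round <- round + 1L
  }
  list(hbar = hbar, valid = !bad)
}

#' Sample corrupted (negative) triplets for a knowledge graph
#'
#' For each triplet, draws `k` head corruptions uniformly from the head's
#' entity partition (item/user/feature/prior), rejecting corruptions that
#' are themselves present in the graph. Triplets whose partition offers no
#' valid corruption are skipped (recorded in the `"skipped"` attribute).
#'
#' @param kg A [build_knowledge_graph()] object.
#' @param k Corruptions per triplet (>= 0).
#' @param seed Integer seed.
#' @return Data frame of corrupted triplets (head, relation, tail), with a
#'   `"positive"` column indexing the source triplet.
#' @export
sample_negatives <- function(kg, k = 1L, seed = 0L) {
  stopifnot(inherits(kg, "jeli_kg"))
  if (k < 0) stop("'k' must be non-negative", call. = FALSE)
  if (k == 0L || nrow(kg$triplets) == 0L) {
    out <- data.frame(head = character(), relation = character(),
                      tail = character(), positive = integer(),
                      stringsAsFactors = FALSE)
    attr(out, "skipped") <- 0L
    return(out)
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, 404L))
  idx <- kg_index(kg)
  pos <- rep(seq_along(idx$h), each = k)
  cr <- corrupt_heads(idx$h[pos], idx$r[pos], idx$t[pos], idx$part_id,
                      idx$members, idx$t_keys, idx$n_ent, idx$n_rel)
  keep <- cr$valid
  out <- data.frame(head = kg$entities[cr$hbar[keep]],
                    relation = kg$triplets$relation[pos[keep]],
                    tail = kg$entities[idx$t[pos[keep]]],
                    positive = pos[keep], stringsAsFactors = FALSE)
  attr(out, "skipped") <- sum(!keep)
  out
}

# Integer-index view of a knowledge graph.
kg_index <- function(kg) {
  ent <- kg$entities
  n_ent <- length(ent)
  rel <- kg$relations
  h <- match(kg$triplets$head, ent)
  t <- match(kg$triplets$tail, ent)
  r <- match(kg$triplets$relation, rel)
  part <- factor(kg$partition[ent], levels = c("item", "user", "feature",
                                               "prior"))
  part_id <- as.integer(part)
  members <- lapply(1:4, function(p) which(part_id == p))
  list(h = h, r = r, t = t, part_id = part_id, members = members,
       t_keys = triplet_keys(h, r, t, n_ent, length(rel)),
       n_ent = n_ent, n_rel = length(rel))
}

# ---- the fitting function ---------------------------------------------------

#' Fit a JELI model: jointly trained RHOFM + knowledge-graph embeddings
#'
#' Builds the nine-relation similarity knowledge graph from the training
#' part of `A` together with `S`, `P` and optional `prior` edges, then
#' minimises the soft margin ranking loss with per-epoch negative sampling
#' over all graph triplets by adaptive-moment (Adam) gradient descent. The
#' `+`/`-` relations are scored by the RHOFM (order 2), all others by MuRE
#' on the structure embeddings, so the structure matrix W is shared by
#' classification and graph completion.
#'
#' @param A Item x user association matrix over `{-1, 0, 1}` (0 = unknown).
#' @param S,P Item (F x n_i) and user (F x n_u) feature tables; `NA`
#'   entries are imputed to zero at scoring time.
#' @param prior Optional prior edge data frame (see
#'   [build_knowledge_graph()]).
#' @param dim Embedding dimension d.
#' @param order RHOFM order m; the trainer supports m = 2 (all experiments
#'   in the ablation and synthetic protocols use m = 2).
#' @param ridge Ridge coefficient of the exact-form embedding estimator
#'   (kept in the returned parameter set; the factored training form does
#'   not use it).
#' @param tau Similarity threshold for the knowledge graph.
#' @param margin Ranking-loss margin (default 1).
#' @param negatives Head corruptions per positive triplet per epoch.
#' @param epochs Training epochs (one full-batch Adam step per epoch unless
#'   `batch_size` is set).
#' @param learning_rate Adam step size.
#' @param batch_size Minibatch size; `NULL` (default) = full batch.
#' @param test_fraction Fraction of nonzero cells of `A` held out before
#'   building the graph (default 0.2); the held-out cells and labels are
#'   stored in the fit for validation. Set 0 to train on all known cells.
#' @param interpretable Keep `omega1 = 1_d` and `omega2m = 1` fixed
#'   (default), preserving the intrinsic feature-importance read-out; if
#'   `FALSE` they are trained freely.
#' @param strict_paper_loss Use the flipped ranking-loss orientation (see
#'   [margin_ranking_loss()]).
#' @param init_sd Standard deviation of the Gaussian initialisation of W
#'   and the relation embeddings.
#' @param seed Integer seed; fitting is deterministic given it.
#' @param verbose Print the loss every 10 epochs.
#' @return An object of class `"jeli"`; see [predict.jeli()],
#'   [feature_importance()], [holdout_metrics()], [coef.jeli()].
#' @examples
#' d <- simulate_dataset(n_features = 6, n_items = 40, n_users = 30,
#'                       seed = 7)
#' fit <- jeli(d$A, d$S, d$P, epochs = 30, seed = 1)
#' fit
#' @export
jeli <- function(A, S, P, prior = NULL, dim = 2L, order = 2L, ridge = 0,
                 tau = 0.5, margin = 1, negatives = 1L, epochs = 100L,
                 learning_rate = 0.05, batch_size = NULL,
                 test_fraction = 0.2, interpretable = TRUE,
                 strict_paper_loss = FALSE, init_sd = 0.1, seed = 0L,
                 verbose = FALSE) {
  order <- stopifnot_count(order, "order")
  if (order != 2L)
    stop("the joint trainer supports order m = 2; use rhofm_score() for ",
         "higher-order scoring", call. = FALSE)
  dim <- stopifnot_count(dim, "dim")
  if (!all(A %in% c(-1, 0, 1)))
    stop("A must take values in {-1, 0, 1}", call. = FALSE)
  if (sum(A != 0) == 0L)
    stop("A has no known (nonzero) cells to train on", call. = FALSE)

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, 505L))

  # train/test split of the known cells
  nz <- which(A != 0)
  holdout <- NULL
  A_train <- A
  if (test_fraction > 0) {
    n_test <- floor(test_fraction * length(nz))
    if (n_test > 0L && n_test < length(nz)) {
      test_idx <- sample(nz, n_test)
      holdout <- list(cells = test_idx, labels = A[test_idx])
      A_train[test_idx] <- 0L
    }
  }
  if (sum(A_train != 0) == 0L)
    stop("no nonzero training cells remain after the split", call. = FALSE)

  kg <- build_knowledge_graph(A_train, S, P, prior = prior, tau = tau)
  idx <- kg_index(kg)
  n_ent <- idx$n_ent
  F_ <- nrow(S)

  # entity design matrix: item/user columns of S/P (zero-imputed), feature
  # indicators, zero rows for prior-only entities
  Xent <- matrix(0, n_ent, F_)
  n_i <- ncol(S); n_u <- ncol(P)
  Xent[seq_len(n_i), ] <- t(impute0(S))
  Xent[n_i + seq_len(n_u), ] <- t(impute0(P))
  Xent[cbind(n_i + n_u + seq_len(F_), seq_len(F_))] <- 1
  Xent2 <- Xent^2

  mure_rels <- setdiff(sort(unique(idx$r)), c(2L, 3L))

  # parameters
  W <- matrix(stats::rnorm(F_ * dim, sd = init_sd), F_, dim,
              dimnames = list(rownames(S), NULL))
  omega0 <- 0
  omega1 <- rep(1, dim)
  omega2 <- 1
  Rarr <- array(rep(diag(dim), idx$n_rel), c(dim, dim, idx$n_rel))
  Erel <- matrix(stats::rnorm(idx$n_rel * dim, sd = init_sd), idx$n_rel, dim)
  bias <- numeric(n_ent)

  adam <- adam_state(list(W = W, omega0 = omega0, omega1 = omega1,
                          omega2 = omega2, Rarr = Rarr, Erel = Erel,
                          bias = bias))
  n_tri <- length(idx$h)
  loss_trace <- numeric(epochs)
  skipped_total <- 0L

  score_grad <- function(hh, rr, tt, E, weights = NULL) {
    # scores of triplets (and, when weights are given, the gradient of
    # sum(weights * score) accumulated into the enclosing grad_* variables)
    sc <- numeric(length(hh))
    is_pm <- rr %in% c(2L, 3L)
    if (any(is_pm)) {
      rows <- which(is_pm)
      sgn <- ifelse(rr[rows] == 2L, 1, -1)
      smat <- Xent[hh[rows], , drop = FALSE] + Xent[tt[rows], , drop = FALSE]
      qmat <- Xent2[hh[rows], , drop = FALSE] + Xent2[tt[rows], , drop = FALSE]
      z <- smat %*% W
      wsq <- rowSums(W^2)
      pair <- 0.5 * (rowSums(z^2) - as.numeric(qmat %*% wsq))
      raw <- omega0 + as.numeric(z %*% omega1) + omega2 * pair
      sc[rows] <- sgn * raw
      if (!is.null(weights)) {
        wr <- weights[rows] * sgn             # d(loss)/d(raw score)
        M <- matrix(omega1, length(rows), ncol(W), byrow = TRUE) + omega2 * z
        gW <- crossprod(smat * wr, M) - omega2 * (as.numeric(crossprod(qmat, wr)) * W)
        grad$W <<- grad$W + gW
        grad$omega0 <<- grad$omega0 + sum(wr)
        if (!interpretable) {
          grad$omega1 <<- grad$omega1 + as.numeric(crossprod(z, wr))
          grad$omega2 <<- grad$omega2 + sum(wr * pair)
        }
      }
    }
    if (any(!is_pm)) {
      dE_idx <- integer(0); dE_val <- NULL
      for (rid in unique(rr[!is_pm])) {
        rows <- which(rr == rid)
        eh <- E[hh[rows], , drop = FALSE]
        et <- E[tt[rows], , drop = FALSE]
        Rr <- matrix(Rarr[, , rid], ncol(E), ncol(E))
        U <- eh %*% t(Rr) - et -
          matrix(Erel[rid, ], length(rows), ncol(E), byrow = TRUE)
        sc[rows] <- -rowSums(U^2) + bias[hh[rows]] + bias[tt[rows]]
        if (!is.null(weights)) {
          wr <- weights[rows]
          Uw <- U * wr
          grad$Rarr[, , rid] <<- grad$Rarr[, , rid] - 2 * crossprod(Uw, eh)
          grad$Erel[rid, ] <<- grad$Erel[rid, ] + 2 * colSums(Uw)
          dEh <- -2 * (Uw %*% Rr)
          dEt <- 2 * Uw
          dE_idx <- c(dE_idx, hh[rows], tt[rows])
          dE_val <- rbind(dE_val, dEh, dEt)
          bg <- rowsum(c(wr, wr), c(hh[rows], tt[rows]))
          grad$bias[as.integer(rownames(bg))] <<-
            grad$bias[as.integer(rownames(bg))] + as.numeric(bg)
        }
      }
      if (!is.null(weights) && length(dE_idx) > 0L) {
        agg <- rowsum(dE_val, dE_idx)
        dE_N <- matrix(0, n_ent, ncol(E))
        dE_N[as.integer(rownames(agg)), ] <- agg
        grad$W <<- grad$W + crossprod(Xent, dE_N)
      }
    }
    sc
  }

  pair_pos <- rep(seq_len(n_tri), each = max(1L, negatives))
  if (negatives == 0L)
    stop("'negatives' must be at least 1 for ranking training", call. = FALSE)

  for (ep in seq_len(epochs)) {
    cr <- corrupt_heads(idx$h[pair_pos], idx$r[pair_pos], idx$t[pair_pos],
                        idx$part_id, idx$members, idx$t_keys, n_ent,
                        idx$n_rel)
    skipped_total <- skipped_total + sum(!cr$valid)
    batches <- if (is.null(batch_size)) list(seq_along(pair_pos))
               else split(sample(seq_along(pair_pos)),
                          ceiling(seq_along(pair_pos) /
                                  max(1L, as.integer(batch_size))))
    ep_loss <- 0
    for (bt in batches) {
      bt <- bt[cr$valid[bt]]
      if (length(bt) == 0L) next
      pp <- pair_pos[bt]
      E <- Xent %*% W
      grad <- list(W = 0 * W, omega0 = 0, omega1 = 0 * omega1, omega2 = 0,
                   Rarr = 0 * Rarr, Erel = 0 * Erel, bias = 0 * bias)
      st <- score_grad(idx$h[pp], idx$r[pp], idx$t[pp], E)
      sc <- score_grad(cr$hbar[bt], idx$r[pp], idx$t[pp], E)
      z <- if (strict_paper_loss) margin + st - sc else margin - st + sc
      ep_loss <- ep_loss + sum(softplus(z))
      g <- sigmoid(z)
      w_true <- if (strict_paper_loss) g else -g
      w_corr <- -w_true
      score_grad(c(idx$h[pp], cr$hbar[bt]), c(idx$r[pp], idx$r[pp]),
                 c(idx$t[pp], idx$t[pp]), E, weights = c(w_true, w_corr))
      upd <- adam_step(adam, grad, learning_rate)
      adam <- upd$state
      W <- W - upd$delta$W
      omega0 <- omega0 - upd$delta$omega0
      if (!interpretable) {
        omega1 <- omega1 - upd$delta$omega1
        omega2 <- omega2 - upd$delta$omega2
      }
      Rarr <- Rarr - upd$delta$Rarr
      Erel <- Erel - upd$delta$Erel
      bias <- bias - upd$delta$bias
    }
    loss_trace[ep] <- ep_loss
    if (verbose && (ep %% 10L == 0L || ep == 1L))
      message(sprintf("epoch %d: loss %.2f", ep, ep_loss))
  }

  params <- rhofm_params(W, omega0 = omega0, omega1 = omega1,
                         omega2m = omega2, order = 2L, ridge = ridge,
                         structure = "linear")
  structure(list(
    rhofm = params,
    relations = list(labels = kg$relations, R = Rarr, e = Erel,
                     mure = kg$relations[mure_rels]),
    biases = stats::setNames(bias, kg$entities),
    kg = kg, Xent = Xent,
    holdout = holdout, A = A, A_train = A_train, S = S, P = P,
    loss = loss_trace, skipped_negatives = skipped_total,
    config = list(dim = dim, order = 2L, ridge = ridge, tau = tau,
                  margin = margin, negatives = negatives, epochs = epochs,
                  learning_rate = learning_rate, batch_size = batch_size,
                  test_fraction = test_fraction,
                  interpretable = interpretable,
                  strict_paper_loss = strict_paper_loss,
                  init_sd = init_sd, seed = seed)),
    class = "jeli")
}

# ---- Adam optimiser ---------------------------------------------------------

adam_state <- function(params, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  list(m = lapply(params, function(p) 0 * p),
       v = lapply(params, function(p) 0 * p),
       t = 0L, beta1 = beta1, beta2 = beta2, eps = eps)
}

adam_step <- function(state, grad, lr) {
  state$t <- state$t + 1L
  delta <- list()
  for (nm in names(grad)) {
    state$m[[nm]] <- state$beta1 * state$m[[nm]] + (1 - state$beta1) * grad[[nm]]
    state$v[[nm]] <- state$beta2 * state$v[[nm]] +
      (1 - state$beta2) * grad[[nm]]^2
    mhat <- state$m[[nm]] / (1 - state$beta1^state$t)
    vhat <- state$v[[nm]] / (1 - state$beta2^state$t)
    delta[[nm]] <- lr * mhat / (sqrt(vhat) + state$eps)
  }
  list(state = state, delta = delta)
}

# ---- scoring of fitted models ----------------------------------------------

#' Edge score of a fitted JELI model
#'
#' Dispatches on the relation: `+` triplets score `RHOFM(x^h, x^t)`, `-`
#' triplets the exact negation, and every other relation scores by MuRE on
#' the structure embeddings with the fitted relation matrix, relation
#' embedding, and entity biases.
#'
#' @param fit A fitted [jeli()] model.
#' @param h,t Entity names (as in `fit$kg$entities`).
#' @param r Relation label (one of the nine-relation vocabulary).
#' @return Scalar score.
#' @export
edge_score <- function(fit, h, r, t) {
  stopifnot(inherits(fit, "jeli"))
  hi <- match(h, fit$kg$entities); ti <- match(t, fit$kg$entities)
  if (is.na(hi) || is.na(ti)) stop("unknown entity", call. = FALSE)
  rid <- match(r, fit$relations$labels)
  if (is.na(rid)) stop("unknown relation label: ", r, call. = FALSE)
  xh <- fit$Xent[hi, ]; xt <- fit$Xent[ti, ]
  if (r == "+") return(rhofm_score(fit$rhofm, xh, xt))
  if (r == "-") return(-rhofm_score(fit$rhofm, xh, xt))
  eh <- structure_apply(fit$rhofm$structure, fit$rhofm$W, xh)
  et <- structure_apply(fit$rhofm$structure, fit$rhofm$W, xt)
  d <- length(eh)
  mure_score(eh, fit$relations$e[rid, ], et,
             matrix(fit$relations$R[, , rid], d, d),
             fit$biases[[hi]], fit$biases[[ti]])
}

#' Predict association scores for every item-user pair
#'
#' Scores `sigmoid(RHOFM(x^i, x^u))` for all column pairs of the supplied
#' (or training) feature tables; unseen entities are handled by the
#' structure function with zero-imputed features.
#'
#' @param object A fitted [jeli()] model.
#' @param S,P Optional item and user feature tables (default: the training
#'   tables). Must share the feature axis the model was trained on.
#' @param type `"response"` (probabilities, default), `"link"` (raw RHOFM
#'   scores) or `"label"` (`+1` where the probability strictly exceeds
#'   0.5, else `-1`).
#' @param ... Unused.
#' @return `n_i x n_u` numeric (or integer, for `"label"`) matrix.
#' @export
predict.jeli <- function(object, S = NULL, P = NULL,
                         type = c("response", "link", "label"), ...) {
  type <- match.arg(type)
  if (is.null(S)) S <- object$S
  if (is.null(P)) P <- object$P
  F_ <- nrow(object$rhofm$W)
  if (nrow(S) != F_ || nrow(P) != F_)
    stop("feature axis does not match the trained model", call. = FALSE)
  p <- object$rhofm
  raw <- rhofm_score_matrix(p$omega0, p$omega1, p$omega2m[1L], p$W,
                            t(impute0(S)), t(impute0(P)))
  dimnames(raw) <- list(colnames(S), colnames(P))
  switch(type,
         link = raw,
         response = sigmoid(raw),
         label = matrix(ifelse(sigmoid(raw) > 0.5, 1L, -1L), nrow(raw),
                        dimnames = dimnames(raw)))
}

#' Validation metrics of a fitted model
#'
#' AUC is evaluated on the known (nonzero) cells held out by [jeli()]'s
#' `test_fraction` split — zeros are unknown, not negatives. NS-AUC and
#' NDCG rank, per user, every cell *not seen in training* (the held-out
#' labelled cells together with the unknown zeros), the standard
#' recommender evaluation population: ordering unseen pairs is the actual
#' task, and cells memorised from training earn no credit. Spearman's rho
#' between the fitted intrinsic importance scores and `s_true` is added
#' when supplied.
#'
#' @param fit A fitted [jeli()] model with a held-out split.
#' @param s_true Optional length-F ground-truth importance vector.
#' @return A `"jeli_metrics"` object.
#' @export
holdout_metrics <- function(fit, s_true = NULL) {
  stopifnot(inherits(fit, "jeli"))
  if (is.null(fit$holdout))
    stop("model was fitted without a held-out split", call. = FALSE)
  scores <- predict(fit, type = "link")
  rho <- if (is.null(s_true)) NA_real_
         else spearman_rho(s_true, feature_importance(fit$rhofm))
  A_eval <- matrix(NA_real_, nrow(fit$A), ncol(fit$A))
  A_eval[fit$A == 0] <- 0                       # unknown cells stay ranked
  A_eval[fit$holdout$cells] <- fit$holdout$labels
  structure(list(auc = auc(fit$holdout$labels, scores[fit$holdout$cells]),
                 ns_auc = ns_auc(A_eval, scores),
                 ndcg = ndcg_at_ni(A_eval, scores),
                 spearman_rho = rho,
                 n_evaluated_pairs = length(fit$holdout$cells)),
            class = "jeli_metrics")
}

# ---- standard S3 methods ----------------------------------------------------

#' @export
print.jeli <- function(x, ...) {
  cfg <- x$config
  cat("JELI: jointly trained RHOFM + knowledge-graph embeddings\n")
  cat(sprintf("  %d items x %d users, %d features; d = %d, m = %d\n",
              ncol(x$S), ncol(x$P), nrow(x$S), cfg$dim, cfg$order))
  cat(sprintf("  graph: %d triplets over %d entities (tau = %g)\n",
              nrow(x$kg$triplets), length(x$kg$entities), cfg$tau))
  cat(sprintf("  %d epochs, final ranking loss %.2f\n",
              cfg$epochs, utils::tail(x$loss, 1)))
  if (!is.null(x$holdout))
    cat(sprintf("  held-out cells: %d (test fraction %g)\n",
                length(x$holdout$cells), cfg$test_fraction))
  invisible(x)
}

#' @export
summary.jeli <- function(object, s_true = NULL, ...) {
  print(object)
  imp <- feature_importance(object$rhofm)
  cat("\nIntrinsic feature importance (top 5 by |score|):\n")
  top <- utils::head(imp[order(-abs(imp))], 5L)
  for (i in seq_along(top))
    cat(sprintf("  %-8s %+.3f\n", names(top)[i], top[i]))
  if (!is.null(object$holdout)) {
    cat("\n")
    print(holdout_metrics(object, s_true = s_true))
  }
  invisible(object)
}

#' @export
coef.jeli <- function(object, ...) {
  p <- object$rhofm
  list(omega0 = p$omega0, omega1 = p$omega1, omega2m = p$omega2m, W = p$W,
       relation_matrices = object$relations$R,
       relation_embeddings = object$relations$e,
       entity_biases = object$biases)
}

#' @export
fitted.jeli <- function(object, ...) predict(object, type = "response")

#' Plot a fitted JELI model
#'
#' `type = "importance"` draws the intrinsic feature-importance bar plot;
#' `type = "loss"` the per-epoch training loss.
#'
#' @param x A fitted [jeli()] model.
#' @param type What to draw.
#' @param ... Passed to the underlying base-graphics call.
#' @export
plot.jeli <- function(x, type = c("importance", "loss"), ...) {
  type <- match.arg(type)
  if (type == "importance") {
    imp <- feature_importance(x$rhofm)
    graphics::barplot(imp, las = 2, ylab = "intrinsic importance",
                      main = "Fitted feature importance", ...)
  } else {
    graphics::plot(seq_along(x$loss), x$loss, type = "l",
                   xlab = "epoch", ylab = "margin ranking loss",
                   main = "Training loss", ...)
  }
  invisible(x)
}
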