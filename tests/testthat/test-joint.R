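test_that("MuRE scoring matches hand evaluation", {
  # exact-match case: R = I, e_t = e_h - e_r, zero biases
  eh <- c(1, 2); er <- c(0.5, -1)
  expect_equal(mure_score(eh, er, eh - er, diag(2)), 0)
  # hand case: -|| (2,2) - (1,1) ||^2 + 1 = -1
  expect_equal(mure_score(c(1, 2), c(1, 0), c(0, 1), diag(c(2, 1)),
                          0.5, 0.5), -1)
  # affine in the biases
  base <- mure_score(c(1, 2), c(1, 0), c(0, 1), diag(c(2, 1)), 0, 0)
  expect_equal(mure_score(c(1, 2), c(1, 0), c(0, 1), diag(c(2, 1)), 3, 3),
               base + 6)
  expect_error(mure_score(c(1, 2), c(1, 0, 0), c(0, 1), diag(2)),
               "dimension")
})

test_that("margin ranking loss matches its closed forms", {
  expect_equal(margin_ranking_loss(0.7, 0.7, margin = 1), log(1 + exp(1)))
  expect_equal(margin_ranking_loss(1.4, 0.4, margin = 1), log(2))
  expect_lt(margin_ranking_loss(100, 0, margin = 1), 1e-10)
  expect_equal(margin_ranking_loss(numeric(0), numeric(0)), 0)
  # all-zero parameters: n pairs x log(1 + e^margin)
  n <- 37
  expect_equal(margin_ranking_loss(numeric(n), numeric(n), margin = 1),
               n * log(1 + exp(1)))
  # decreasing in the score gap
  gaps <- seq(-2, 2, by = 0.5)
  losses <- vapply(gaps, function(g) margin_ranking_loss(g, 0), numeric(1))
  expect_true(all(diff(losses) < 0))
  # the printed orientation flips the monotonicity
  losses_p <- vapply(gaps, function(g)
    margin_ranking_loss(g, 0, strict_paper = TRUE), numeric(1))
  expect_true(all(diff(losses_p) > 0))
  expect_error(margin_ranking_loss(1:3, 1:2), "paired")
})

test_that("negative sampling corrupts within partitions, uniformly, off-graph", {
  # 10 items, 1 user, one + triplet; valid corruptions are the other 9 items
  A <- matrix(0L, 10, 1); A[1, 1] <- 1L
  S <- matrix(0, 2, 10); P <- matrix(0, 2, 1)
  kg <- build_knowledge_graph(A, S, P)
  neg0 <- sample_negatives(kg, k = 0)
  expect_equal(nrow(neg0), 0L)
  neg <- sample_negatives(kg, k = 9999, seed = 5)
  expect_true(all(neg$relation == "+"))
  expect_true(all(neg$head != "i1"))       # the true triplet is off limits
  expect_true(all(neg$head %in% paste0("i", 2:10)))
  counts <- table(neg$head)
  expval <- 9999 / 9
  sdev <- sqrt(9999 * (1 / 9) * (8 / 9))
  expect_true(all(abs(counts - expval) < 3 * sdev))
  expect_identical(sample_negatives(kg, k = 5, seed = 1),
                   sample_negatives(kg, k = 5, seed = 1))

  # corruptions of a toy graph never reproduce graph triplets
  d <- tiny_dataset(seed = 41, n_items = 12, n_users = 9)
  kg2 <- build_knowledge_graph(d$A, d$S, d$P)
  neg2 <- sample_negatives(kg2, k = 2, seed = 3)
  in_graph <- paste(neg2$head, neg2$relation, neg2$tail) %in%
    paste(kg2$triplets$head, kg2$triplets$relation, kg2$triplets$tail)
  expect_false(any(in_graph))
})

test_that("fitting is deterministic and its loss decreases", {
  d <- tiny_dataset(seed = 42, n_features = 10, n_items = 50, n_users = 50,
                    dim = 2)
  fit1 <- jeli(d$A, d$S, d$P, epochs = 40, seed = 9)
  fit2 <- jeli(d$A, d$S, d$P, epochs = 40, seed = 9)
  expect_identical(fit1$rhofm$W, fit2$rhofm$W)
  expect_identical(fit1$biases, fit2$biases)
  expect_identical(fit1$loss, fit2$loss)
  expect_identical(predict(fit1), predict(fit2))
  # loss trend is non-increasing over the last 80% of epochs, up to the
  # resampling noise of the fresh negatives drawn each epoch
  tail_loss <- fit1$loss[-seq_len(8)]
  expect_true(all(diff(tail_loss) <= 0.05 * tail_loss[-length(tail_loss)]))
  expect_lt(mean(utils::tail(tail_loss, 8)), mean(utils::head(tail_loss, 8)))
  expect_lt(tail_loss[length(tail_loss)], fit1$loss[1])
  # linearly separable first-order toy: held-out AUC >= 0.9
  m <- holdout_metrics(fit1, s_true = d$s_star)
  expect_gte(m$auc, 0.9)
})

test_that("the fitted edge score honours the relation dispatch", {
  d <- tiny_dataset(seed = 43, n_items = 15, n_users = 12)
  fit <- jeli(d$A, d$S, d$P, epochs = 15, seed = 2)
  # +/- antisymmetry on every checked pair
  for (i in c("i1", "i7")) for (u in c("u2", "u11")) {
    expect_equal(edge_score(fit, i, "-", u), -edge_score(fit, i, "+", u),
                 tolerance = 1e-12)
  }
  # the + edge score is the RHOFM score used for prediction
  expect_equal(edge_score(fit, "i3", "+", "u4"),
               predict(fit, type = "link")["i3", "u4"], tolerance = 1e-10)
  expect_error(edge_score(fit, "i1", "likes", "u1"), "relation")
  expect_error(edge_score(fit, "i99", "+", "u1"), "entity")
})

test_that("similarity edge scores depend on W only through the embeddings", {
  # two items supported on features 1:2; their sim edge must ignore W rows 3+
  S <- matrix(0, 4, 3)
  S[1:2, 1] <- c(1, 1); S[1:2, 2] <- c(1, 0.9); S[3:4, 3] <- c(1, -1)
  colnames(S) <- paste0("i", 1:3); rownames(S) <- paste0("f", 1:4)
  P <- matrix(rnorm(8), 4, 2, dimnames = list(rownames(S), c("u1", "u2")))
  A <- matrix(c(1L, -1L, 0L, 0L, 1L, -1L), 3, 2)
  fit <- jeli(A, S, P, epochs = 5, seed = 1, test_fraction = 0)
  base <- edge_score(fit, "i1", "item-sim", "i2")
  fit2 <- fit
  fit2$rhofm$W[4, ] <- fit2$rhofm$W[4, ] + 100   # outside the support
  expect_equal(edge_score(fit2, "i1", "item-sim", "i2"), base,
               tolerance = 1e-10)
  fit3 <- fit
  fit3$rhofm$W[1, ] <- fit3$rhofm$W[1, ] + 1     # inside the support
  expect_false(isTRUE(all.equal(edge_score(fit3, "i1", "item-sim", "i2"),
                                base)))
})

test_that("prediction handles unseen entities and degenerate models", {
  d <- tiny_dataset(seed = 44, n_items = 20, n_users = 15)
  fit <- jeli(d$A, d$S, d$P, epochs = 10, seed = 3)
  pr <- predict(fit)
  expect_equal(dim(pr), c(20L, 15L))
  expect_true(all(pr > 0 & pr < 1))
  # labels are +1 exactly where the probability strictly exceeds 1/2
  lab <- predict(fit, type = "label")
  expect_identical(lab == 1L, pr > 0.5)
  # duplicating an item column duplicates its score row
  S2 <- cbind(d$S, dup = d$S[, 5])
  pr2 <- predict(fit, S = S2, P = d$P)
  expect_equal(unname(pr2[21, ]), unname(pr[5, ]))
  # a zeroed structure matrix predicts sigmoid(omega0) everywhere
  fit0 <- fit
  fit0$rhofm$W[] <- 0
  expect_true(all(abs(predict(fit0, type = "link") -
                        fit0$rhofm$omega0) < 1e-12))
  expect_error(predict(fit, S = d$S[-1, , drop = FALSE], P = d$P),
               "feature axis")
})

test_that("strict-paper loss orientation trains towards the opposite ranking", {
  d <- tiny_dataset(seed = 45, n_items = 30, n_users = 25)
  fit_std <- jeli(d$A, d$S, d$P, epochs = 30, seed = 4)
  fit_flip <- jeli(d$A, d$S, d$P, epochs = 30, seed = 4,
                   strict_paper_loss = TRUE)
  m_std <- holdout_metrics(fit_std)
  m_flip <- holdout_metrics(fit_flip)
  expect_gt(m_std$auc, m_flip$auc)
})
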