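test_that("structure function embeds entities, indicators, and partial vectors", {
  W <- matrix(c(1, 2), 2, 1)
  expect_equal(structure_apply("linear", W, c(1, 1)), 3)
  # indicator vector of feature f returns row W[f, ]
  W2 <- matrix(rnorm(8), 4, 2)
  for (f in 1:4) {
    e <- numeric(4); e[f] <- 1
    expect_equal(structure_apply("linear", W2, e), unname(W2[f, ]))
  }
  # missing entry behaves as zero padding
  x <- c(1.5, NA, -0.5, 2)
  x0 <- c(1.5, 0, -0.5, 2)
  expect_equal(structure_apply("linear", W2, x),
               structure_apply("linear", W2, x0))
  expect_error(structure_apply("linear", W2, c(1, 2)), "length")
})

test_that("ridge embedding estimator matches closed forms", {
  # identity design recovers W exactly
  p <- rhofm_params(matrix(c(1, 2), 2, 1))
  expect_equal(ridge_embedding_estimator(c(1, 0), c(0, 1), p),
               matrix(c(1, 2), 2, 1), tolerance = 1e-12)
  # heavy ridge shrinks towards zero
  p_big <- rhofm_params(matrix(c(1, 2), 2, 1), ridge = 1e8)
  expect_lt(max(abs(ridge_embedding_estimator(c(1, 0), c(0, 1), p_big))),
            1e-6)
  # random 2x5 design vs an independent normal-equations solve
  set.seed(42)
  W <- matrix(rnorm(10), 5, 2)
  xi <- rnorm(5); xu <- rnorm(5)
  p2 <- rhofm_params(W, ridge = 0.1)
  X <- rbind(xi, xu)
  oracle <- solve(crossprod(X) + 0.1 * diag(5)) %*% crossprod(X, X %*% W)
  expect_equal(ridge_embedding_estimator(xi, xu, p2), unname(oracle),
               tolerance = 1e-10)
})

test_that("ANOVA kernel DP agrees with combinatorial enumeration", {
  V <- rbind(c(1, 0), c(0, 1), c(1, 1))
  expect_equal(anova_kernel(V, c(1, 1, 1), 2), 2)        # 0 + 1 + 1
  # a single nonzero input leaves no surviving pair
  expect_equal(anova_kernel(matrix(rnorm(8), 4), c(0, 3, 0, 0), 2), 0)
  expect_equal(anova_kernel(matrix(1, 2, 1), c(1, 1), 3), 0)  # t > q
  expect_error(anova_kernel(V, c(1, 1, 1), 1), "at least 2")

  # brute-force oracle over all tuples, q <= 6, t <= 4, d <= 3
  enum_oracle <- function(V, xw, t) {
    tot <- 0
    for (j in seq_len(ncol(utils::combn(nrow(V), t)))) {
      idx <- utils::combn(nrow(V), t)[, j]
      tot <- tot + sum(apply(V[idx, , drop = FALSE], 2, prod)) * prod(xw[idx])
    }
    tot
  }
  set.seed(1)
  for (q in 2:6) for (t in 2:min(4, q)) for (d in 1:3) {
    V <- matrix(rnorm(q * d), q, d)
    xw <- rnorm(q)
    expect_equal(anova_kernel(V, xw, t), enum_oracle(V, xw, t),
                 tolerance = 1e-12)
  }
})

test_that("RHOFM scoring matches hand evaluation in both modes", {
  # W = 0: only the intercept survives
  p0 <- rhofm_params(matrix(0, 3, 2), omega0 = 1.25)
  x <- rnorm(3); y <- rnorm(3)
  expect_equal(rhofm_score(p0, x, y, "factored"), 1.25)
  expect_equal(rhofm_score(p0, x, y, "exact"), 1.25)

  # F=2, d=1, m=2, W=(1,1)': linear 2, pairwise 1, total 3; W_tilde = W here
  p <- rhofm_params(matrix(c(1, 1), 2, 1))
  expect_equal(rhofm_score(p, c(1, 0), c(0, 1), "factored"), 3)
  expect_equal(rhofm_score(p, c(1, 0), c(0, 1), "exact"), 3)

  # symmetry under item/user swap, both modes
  set.seed(7)
  for (r in 1:5) {
    W <- matrix(rnorm(8), 4, 2)
    pr <- rhofm_params(W, omega0 = rnorm(1))
    xi <- rnorm(4); xu <- rnorm(4)
    for (md in c("factored", "exact"))
      expect_equal(rhofm_score(pr, xi, xu, md), rhofm_score(pr, xu, xi, md),
                   tolerance = 1e-10)
  }
})

test_that("exact and factored forms coincide where the theory says so", {
  set.seed(11)
  xi <- rnorm(5); xu <- rnorm(5)
  # linear term only (interaction weights zero): modes agree at lambda = 0
  W <- matrix(rnorm(10), 5, 2)
  p_lin <- rhofm_params(W, omega1 = c(2, -1), omega2m = 0)
  expect_equal(rhofm_score(p_lin, xi, xu, "exact"),
               rhofm_score(p_lin, xi, xu, "factored"), tolerance = 1e-10)
  # full agreement when W's columns lie in span{x^i, x^u}
  W_span <- cbind(0.3 * xi - 1.2 * xu, 0.7 * xi + 0.1 * xu)
  p_span <- rhofm_params(W_span)
  expect_equal(rhofm_score(p_span, xi, xu, "exact"),
               rhofm_score(p_span, xi, xu, "factored"), tolerance = 1e-10)
})

test_that("vectorised all-pairs scorer matches the per-pair evaluation", {
  set.seed(3)
  d <- tiny_dataset(seed = 3, n_items = 7, n_users = 5)
  W <- matrix(rnorm(12), 6, 2)
  p <- rhofm_params(W, omega0 = 0.4)
  M <- jeli:::rhofm_score_matrix(0.4, rep(1, 2), 1, W,
                                 t(jeli:::impute0(d$S)),
                                 t(jeli:::impute0(d$P)))
  for (i in c(1, 4, 7)) for (u in c(2, 5)) {
    expect_equal(M[i, u], rhofm_score(p, d$S[, i], d$P[, u]),
                 tolerance = 1e-10)
  }
})

test_that("feature importance follows the row-sum rule", {
  W <- matrix(c(1, 0, 2, -1), 2, 2)       # rows (1,2), (0,-1)
  p <- rhofm_params(W)
  expect_equal(unname(feature_importance(p)), c(3, -1))
  expect_equal(unname(feature_importance(p, x = c(2, 1))), c(6, -1))
  expect_equal(unname(feature_importance(p, x = c(0, 0))), c(0, 0))
  p_free <- rhofm_params(W, omega1 = c(2, 1))
  expect_warning(feature_importance(p_free), "interpretable")
})

test_that("parameter count matches the family formula", {
  for (F_ in c(2, 10)) for (d in c(1, 3)) for (m in c(2, 4)) {
    p <- rhofm_params(matrix(0, F_, d), order = m)
    expect_identical(n_parameters(p), as.integer(1 + m + (F_ + 1) * d))
  }
})

test_that("label prediction thresholds the sigmoid strictly", {
  p3 <- rhofm_params(matrix(c(1, 1), 2, 1), omega0 = 1)  # score 3 on (1,0),(0,1)
  out <- predict_label(p3, c(1, 0), c(0, 1))
  expect_identical(out$label, 1L)
  expect_equal(out$probability, 1 / (1 + exp(-4)), tolerance = 1e-12)
  # raw score 0 -> -1 (strict inequality)
  p0 <- rhofm_params(matrix(0, 2, 1), omega0 = 0)
  expect_identical(predict_label(p0, c(1, 0), c(0, 1))$label, -1L)
  pm <- rhofm_params(matrix(0, 2, 1), omega0 = -1)
  out2 <- predict_label(pm, c(1, 0), c(0, 1))
  expect_identical(out2$label, -1L)
  expect_equal(out2$probability, 1 / (1 + exp(1)), tolerance = 1e-12)
})

test_that("FM, CrossFM and brute-force HOFM agree with their definitions", {
  th <- list(omega0 = 1, omega1 = c(1, 1), V = rbind(c(1, 0), c(0, 1)))
  expect_equal(fm_score(th, c(1, 1)), 3)       # 1 + 2 + 0
  th0 <- list(omega0 = 0.5, omega1 = c(2, -1), V = matrix(0, 2, 2))
  expect_equal(fm_score(th0, c(1, 3)), 0.5 + 2 - 3)

  # FM equals order-2 brute force on random instances
  set.seed(5)
  for (r in 1:5) {
    q <- 6
    th2 <- list(omega0 = rnorm(1), omega1 = rnorm(q),
                V = matrix(rnorm(q * 3), q, 3))
    x <- rnorm(q)
    expect_equal(fm_score(th2, x),
                 hofm_bruteforce(list(omega0 = th2$omega0,
                                      omega1 = th2$omega1,
                                      interactions = th2$V), x, m = 2),
                 tolerance = 1e-12)
  }

  # CrossFM hand case: F=1, omega0=0, omega1=(1,1), V=(1),(2), x=(2),(3)
  thc <- list(omega0 = 0, omega1 = c(1, 1), V = matrix(c(1, 2), 2, 1))
  expect_equal(crossfm_score(thc, 2, 3), 5 + 1 * 2 * 2 * 3)
  expect_equal(crossfm_score(thc, 2, 0), 2)    # no cross pairs
  # decomposition: cross term = FM pair term minus within-item/user terms
  set.seed(6)
  F_ <- 3
  thr <- list(omega0 = rnorm(1), omega1 = rnorm(2 * F_),
              V = matrix(rnorm(2 * F_ * 2), 2 * F_, 2))
  xi <- rnorm(F_); xu <- rnorm(F_)
  within <- fm_score(list(omega0 = 0, omega1 = numeric(F_),
                          V = thr$V[1:F_, , drop = FALSE]), xi) +
            fm_score(list(omega0 = 0, omega1 = numeric(F_),
                          V = thr$V[F_ + 1:F_, , drop = FALSE]), xu)
  expect_equal(crossfm_score(thr, xi, xu),
               fm_score(thr, c(xi, xu)) - within, tolerance = 1e-12)

  # m = 3 brute force equals the ANOVA-kernel evaluation
  set.seed(8)
  q <- 4
  V <- matrix(rnorm(q * 2), q, 2)
  x <- rnorm(q)
  bf <- hofm_bruteforce(list(omega0 = 0, omega1 = numeric(q),
                             interactions = V), x, m = 3)
  expect_equal(bf, anova_kernel(V, x, 2) + anova_kernel(V, x, 3),
               tolerance = 1e-12)
  expect_equal(hofm_bruteforce(list(omega0 = 2.5, omega1 = numeric(q),
                                    interactions = V), numeric(q), m = 3),
               2.5)
  expect_error(hofm_bruteforce(list(omega0 = 0, omega1 = numeric(40),
                                    interactions = matrix(0, 40, 2)),
                               numeric(40), m = 6), "too large")
})
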