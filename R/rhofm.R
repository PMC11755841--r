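# Redundant structured higher-order factorization machines (RHOFM) and the
# plain FM / CrossFM / HOFM reference models.
#
# An RHOFM of order m and dimension d scores an (item, user) pair from the
# concatenation of their length-F feature vectors. Unlike a plain HOFM, all
# embeddings (item, user, and per-feature) derive from one shared structure
# function s_W: R^F -> R^d with parameter W (F x d); in the linear case
# s_W(x) = x W, and the embedding of feature f is simply row W_{f,}.

#' Construct an RHOFM parameter set
#'
#' @param W F x d structure matrix; feature f's embedding is `s_W` applied
#'   to its indicator vector (row `W[f, ]` for the linear structure).
#' @param omega0 Intercept.
#' @param omega1 Length-d weights of the linear (first-order) term; default
#'   `1_d` (interpretable mode).
#' @param omega2m Length-(m-1) weights of the interaction orders t = 2..m;
#'   default `1_{m-1}` (interpretable mode).
#' @param order Interaction order m >= 2.
#' @param ridge Ridge coefficient lambda >= 0 of the embedding estimator
#'   used by the exact scoring form.
#' @param structure `"linear"` or a function `f(x, W)` mapping a
#'   zero-imputed length-F vector to a length-d embedding.
#' @return An object of class `"rhofm_params"`.
#' @details In interpretable mode (`omega1`, `omega2m` all equal to one)
#'   the model admits intrinsic feature-importance scores; see
#'   [feature_importance()]. Counting the intercept, the d linear weights,
#'   the m - 1 interaction-order weights, the ridge coefficient and the
#'   F x d structure matrix, the family has `1 + m + (F + 1) d` scalar
#'   parameters — compare 1 + 2F + 2Fd(m - 1) for an unstructured HOFM on
#'   the concatenated input.
#' @export
rhofm_params <- function(W, omega0 = 0, omega1 = NULL, omega2m = NULL,
                         order = 2L, ridge = 0, structure = "linear") {
  stopifnot(is.matrix(W), is.numeric(W))
  order <- stopifnot_count(order, "order")
  if (order < 2L) stop("'order' (m) must be at least 2", call. = FALSE)
  if (ridge < 0) stop("'ridge' must be non-negative", call. = FALSE)
  d <- ncol(W)
  if (is.null(omega1)) omega1 <- rep(1, d)
  if (is.null(omega2m)) omega2m <- rep(1, order - 1L)
  if (length(omega1) != d)
    stop("'omega1' must have length d = ncol(W)", call. = FALSE)
  if (length(omega2m) != order - 1L)
    stop("'omega2m' must have length m - 1", call. = FALSE)
  if (!(identical(structure, "linear") || is.function(structure)))
    stop("'structure' must be \"linear\" or a function(x, W)", call. = FALSE)
  structure(list(omega0 = omega0, omega1 = as.numeric(omega1),
                 omega2m = as.numeric(omega2m), W = W,
                 order = order, dim = d, ridge = ridge,
                 structure = structure),
            class = "rhofm_params")
}

#' @export
print.rhofm_params <- function(x, ...) {
  cat(sprintf("RHOFM parameters: F = %d, d = %d, m = %d, lambda = %g\n",
              nrow(x$W), x$dim, x$order, x$ridge))
  cat(sprintf("  structure: %s; interpretable mode: %s\n",
              if (identical(x$structure, "linear")) "linear" else "custom",
              if (is_interpretable(x)) "yes" else "no"))
  cat(sprintf("  scalar parameters: %d\n", n_parameters(x)))
  invisible(x)
}

is_interpretable <- function(params) {
  all(params$omega1 == 1) && all(params$omega2m == 1)
}

#' Number of scalar parameters of an RHOFM family
#'
#' `1 + m + (F + 1) d`: intercept, d linear weights, m - 1 interaction
#' weights, ridge coefficient, and the F x d structure matrix.
#'
#' @param params An [rhofm_params()] object.
#' @return Integer count.
#' @export
n_parameters <- function(params) {
  stopifnot(inherits(params, "rhofm_params"))
  F_ <- nrow(params$W)
  as.integer(1L + params$order + (F_ + 1L) * params$dim)
}

#' Apply the structure function to a feature vector
#'
#' Returns `s_W(x)`, the d-dimensional embedding of an entity with feature
#' vector `x`; missing entries are imputed to zero first, so unseen
#' entities with partial features embed without retraining.
#'
#' @param structure `"linear"` or a function `f(x, W)`.
#' @param W F x d structure matrix.
#' @param x Length-F feature vector, `NA` allowed.
#' @return Length-d numeric embedding.
#' @export
structure_apply <- function(structure, W, x) {
  if (length(x) != nrow(W))
    stop("feature vector length does not match nrow(W)", call. = FALSE)
  x <- impute0(as.numeric(x))
  if (identical(structure, "linear")) as.numeric(x %*% W)
  else as.numeric(structure(x, W))
}

# Embeddings of the F feature-indicator vectors, stacked as an F x d matrix.
# For the linear structure this is W itself.
feature_embeddings <- function(structure, W) {
  if (identical(structure, "linear")) return(W)
  t(vapply(seq_len(nrow(W)), function(f) {
    e <- numeric(nrow(W)); e[f] <- 1
    structure_apply(structure, W, e)
  }, numeric(ncol(W))))
}

#' Ridge least-squares embedding estimator
#'
#' Solves `s_W(X) = X V` for V in the ridge-regularised least-squares
#' sense, where X is the 2 x F design matrix with rows `x^i`, `x^u`:
#' `W_tilde = (X'X + lambda I_F)^+ X' Y` with `Y = rbind(s_W(x^i),
#' s_W(x^u))`. The Moore-Penrose pseudo-inverse makes `lambda = 0` legal
#' despite the rank-2 design. With the linear structure and `lambda = 0`,
#' `X W_tilde = X W` exactly (projection identity).
#'
#' @param xi,xu Length-F item and user feature vectors, `NA` allowed.
#' @param params An [rhofm_params()] object (supplies W, ridge, structure).
#' @return F x d matrix `W_tilde`.
#' @export
ridge_embedding_estimator <- function(xi, xu, params) {
  stopifnot(inherits(params, "rhofm_params"))
  X <- rbind(impute0(as.numeric(xi)), impute0(as.numeric(xu)))
  if (ncol(X) != nrow(params$W))
    stop("feature vector length does not match nrow(W)", call. = FALSE)
  Y <- rbind(structure_apply(params$structure, params$W, xi),
             structure_apply(params$structure, params$W, xu))
  G <- crossprod(X) + params$ridge * diag(ncol(X))
  MASS::ginv(G) %*% crossprod(X, Y)
}

#' Degree-t ANOVA kernel over weighted latent rows
#'
#' Computes `sum_{f1 < ... < ft} <V_{f1}, ..., V_{ft}> xw_{f1} ... xw_{ft}`,
#' i.e. per latent dimension the degree-t elementary symmetric polynomial of
#' `{xw_f * V_{f,k}}_f`, evaluated by the O(q t) dynamic-programming
#' recursion and summed over dimensions.
#'
#' @param V q x d matrix of latent rows.
#' @param xw Length-q input weights.
#' @param t Interaction degree, `2 <= t`; `t > q` returns 0 (empty sum).
#' @return Scalar kernel value.
#' @export
anova_kernel <- function(V, xw, t) {
  if (!is.matrix(V)) V <- matrix(V, ncol = 1L)
  q <- nrow(V)
  if (length(xw) != q) stop("length(xw) must equal nrow(V)", call. = FALSE)
  t <- stopifnot_count(t, "t")
  if (t < 2L) stop("'t' must be at least 2", call. = FALSE)
  if (t > q) return(0)
  a <- V * xw                                 # rows scaled by inputs
  dp <- matrix(0, t + 1L, ncol(V))
  dp[1L, ] <- 1
  for (f in seq_len(q)) {
    for (j in seq.int(min(f, t), 1L)) {
      dp[j + 1L, ] <- dp[j + 1L, ] + dp[j, ] * a[f, ]
    }
  }
  sum(dp[t + 1L, ])
}

#' RHOFM score of an (item, user) pair
#'
#' @param params An [rhofm_params()] object.
#' @param xi,xu Length-F item and user feature vectors, `NA` imputed to 0.
#' @param mode `"factored"` (default) evaluates the reordered form — linear
#'   term on the structure embeddings `s_W(x^i) + s_W(x^u)` plus ANOVA
#'   kernels over input-weighted feature embeddings — in O(F d m).
#'   `"exact"` evaluates the defining form on the concatenated 2F input
#'   with the stacked ridge estimate `rbind(W_tilde, W_tilde)` from
#'   [ridge_embedding_estimator()]. The two agree exactly on the linear
#'   term when `ridge = 0` (projection identity) and whenever W's rows lie
#'   in the span of `{x^i, x^u}`.
#' @return Scalar raw score (pass through [sigmoid()] for a probability).
#' @export
rhofm_score <- function(params, xi, xu, mode = c("factored", "exact")) {
  stopifnot(inherits(params, "rhofm_params"))
  mode <- match.arg(mode)
  xi <- impute0(as.numeric(xi)); xu <- impute0(as.numeric(xu))
  F_ <- nrow(params$W)
  if (length(xi) != F_ || length(xu) != F_)
    stop("feature vectors must have length nrow(W)", call. = FALSE)
  xprime <- c(xi, xu)
  if (mode == "exact") {
    Wt <- ridge_embedding_estimator(xi, xu, params)
    Vstack <- rbind(Wt, Wt)
    lin <- sum(params$omega1 * as.numeric(xprime %*% Vstack))
  } else {
    ei <- structure_apply(params$structure, params$W, xi)
    eu <- structure_apply(params$structure, params$W, xu)
    lin <- sum(params$omega1 * (ei + eu))
    Phi <- feature_embeddings(params$structure, params$W)
    Vstack <- rbind(Phi, Phi)
  }
  inter <- 0
  for (t in seq.int(2L, params$order)) {
    inter <- inter + params$omega2m[t - 1L] * anova_kernel(Vstack, xprime, t)
  }
  params$omega0 + lin + inter
}

# Vectorised all-pairs factored RHOFM evaluation for m = 2 and the linear
# structure. Xi: n_i x F, Xu: n_u x F (already zero-imputed). w2 is the
# scalar weight of the pairwise term. Uses the identity
#   sum_{f<f'} v_f v_f' = ((sum_f v_f)^2 - sum_f v_f^2) / 2
# per latent dimension, with v_f = x'_f W_{f%%F, k}.
rhofm_score_matrix <- function(omega0, w1, w2, W, Xi, Xu) {
  Ei <- Xi %*% W
  Eu <- Xu %*% W
  li <- as.numeric(Ei %*% w1)
  lu <- as.numeric(Eu %*% w1)
  wsq <- rowSums(W^2)
  ci <- as.numeric((Xi^2) %*% wsq)        # sum_f,k x_f^2 W_fk^2
  cu <- as.numeric((Xu^2) %*% wsq)
  ni2 <- rowSums(Ei^2)
  nu2 <- rowSums(Eu^2)
  pair <- 0.5 * (outer(ni2 - ci, nu2 - cu, "+") + 2 * tcrossprod(Ei, Eu))
  omega0 + outer(li, lu, "+") + w2 * pair
}

#' Intrinsic feature importance and per-entity attribution
#'
#' In interpretable mode (constant `omega1`, `omega2m`) the intrinsic,
#' entity-independent importance of feature f is the row sum
#' `sum_k W[f, k]`; the attribution of a specific entity with feature
#' vector `x` scales it to `x_f * sum_k W[f, k]`.
#'
#' @param params An [rhofm_params()] object, or a fitted [jeli()] model.
#' @param x Optional length-F feature vector; when supplied the attribution
#'   is returned instead of the intrinsic scores.
#' @return Length-F named numeric vector.
#' @export
feature_importance <- function(params, x = NULL) {
  if (inherits(params, "jeli")) params <- params$rhofm
  stopifnot(inherits(params, "rhofm_params"))
  if (!is_interpretable(params))
    warning("omega1/omega2m are not constant: intrinsic importance scores ",
            "assume interpretable mode")
  s <- rowSums(params$W)
  if (!is.null(x)) {
    if (length(x) != length(s))
      stop("feature vector length does not match nrow(W)", call. = FALSE)
    s <- impute0(as.numeric(x)) * s
  }
  names(s) <- rownames(params$W)
  s
}

#' Predict an association label from an RHOFM
#'
#' Labels `+1` iff `sigmoid(score) > 0.5` (strict), i.e. iff the raw score
#' is positive; ties at exactly 0 go to `-1`.
#'
#' @inheritParams rhofm_score
#' @return List with `label` (-1 or +1), `probability` (`sigmoid(score)`)
#'   and the raw `score`.
#' @export
predict_label <- function(params, xi, xu) {
  sc <- rhofm_score(params, xi, xu)
  p <- sigmoid(sc)
  list(label = if (p > 0.5) 1L else -1L, probability = p, score = sc)
}

#' Second-order factorization machine score
#'
#' `FM(x) = omega0 + omega1'x + sum_{f<f'} <V_f, V_f'> x_f x_f'`, evaluated
#' with the degree-2 kernel identity in O(q d).
#'
#' @param theta List with `omega0` (scalar), `omega1` (length q) and `V`
#'   (q x d latent matrix).
#' @param x Length-q input vector (item and user features concatenated).
#' @return Scalar score.
#' @export
fm_score <- function(theta, x) {
  x <- impute0(as.numeric(x))
  V <- theta$V
  if (length(x) != length(theta$omega1) || length(x) != nrow(V))
    stop("input length must match omega1 and nrow(V)", call. = FALSE)
  z <- as.numeric(x %*% V)
  pair <- 0.5 * sum(z^2 - as.numeric((x^2) %*% (V^2)))
  theta$omega0 + sum(theta$omega1 * x) + pair
}

#' Cross-only second-order factorization machine score
#'
#' Like [fm_score()] on the concatenated input, but the pairwise term keeps
#' only item-feature x user-feature pairs:
#' `sum_{f <= F, f' > F} <V_f, V_f'> x^i_f x^u_{f'-F}`.
#'
#' @param theta List with `omega0`, `omega1` (length 2F), `V` (2F x d).
#' @param xi,xu Length-F item and user feature vectors.
#' @return Scalar score.
#' @export
crossfm_score <- function(theta, xi, xu) {
  xi <- impute0(as.numeric(xi)); xu <- impute0(as.numeric(xu))
  F_ <- length(xi)
  if (length(xu) != F_) stop("xi and xu must have equal length", call. = FALSE)
  if (length(theta$omega1) != 2L * F_ || nrow(theta$V) != 2L * F_)
    stop("theta must be sized for the concatenated 2F input", call. = FALSE)
  Vt <- theta$V[seq_len(F_), , drop = FALSE]
  Vb <- theta$V[F_ + seq_len(F_), , drop = FALSE]
  cross <- sum(as.numeric(xi %*% Vt) * as.numeric(xu %*% Vb))
  theta$omega0 + sum(theta$omega1 * c(xi, xu)) + cross
}

#' Brute-force higher-order factorization machine score (test oracle)
#'
#' Exact enumeration of the defining sum over all strictly increasing index
#' tuples for t = 2..m. Exponential in m; intended as an independent oracle
#' on small instances.
#'
#' @param theta List with `omega0`, `omega1` (length q) and `interactions`,
#'   a list of q x d_t latent matrices for t = 2..m (a single matrix is
#'   recycled across orders).
#' @param x Length-q input vector.
#' @param m Order (>= 2).
#' @param max_terms Enumeration guard; instances with more index tuples are
#'   rejected.
#' @return Scalar score.
#' @export
hofm_bruteforce <- function(theta, x, m = 2L, max_terms = 2e5) {
  x <- impute0(as.numeric(x))
  q <- length(x)
  m <- stopifnot_count(m, "m")
  if (m < 2L) stop("'m' must be at least 2", call. = FALSE)
  Vs <- theta$interactions
  if (is.matrix(Vs)) Vs <- rep(list(Vs), m - 1L)
  if (length(Vs) == 1L && m > 2L) Vs <- rep(Vs, m - 1L)
  total_terms <- sum(vapply(2:m, function(t) choose(q, t), numeric(1)))
  if (total_terms > max_terms)
    stop("instance too large for brute-force enumeration", call. = FALSE)
  out <- theta$omega0 + sum(theta$omega1 * x)
  for (t in 2:m) {
    if (t > q) next
    V <- Vs[[t - 1L]]
    combos <- utils::combn(q, t)
    for (j in seq_len(ncol(combos))) {
      idx <- combos[, j]
      out <- out + sum(apply(V[idx, , drop = FALSE], 2L, prod)) * prod(x[idx])
    }
  }
  out
}
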