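# Synthetic recommendation data with known ground-truth feature importance.
#
# The generator draws item/user feature vectors from a standard Gaussian,
# hides ~10% of entries through a not-missing-at-random Gaussian self-masking
# mechanism, scores every item-user pair with a first- or second-order
# logistic generating model g0 built on a ground-truth embedding matrix
# W*, and thresholds the scores into {-1, 0, +1} labels so that a requested
# fraction of cells (the "sparsity number") stays unknown.

#' Draw a feature table of i.i.d. standard-normal values
#'
#' @param n_features Number of features (rows).
#' @param n_entities Number of entities (columns).
#' @param seed Integer seed; the same seed reproduces the same table.
#' @return A `n_features x n_entities` numeric matrix with `f1..fF` row names.
#' @export
gen_features <- function(n_features, n_entities, seed = 0L) {
  stopifnot_count(n_features, "n_features")
  stopifnot_count(n_entities, "n_entities")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, 101L))
  matrix(stats::rnorm(n_features * n_entities), nrow = n_features,
         dimnames = list(paste0("f", seq_len(n_features)), NULL))
}

#' Draw a ground-truth embedding matrix W* and its importance vector
#'
#' W* has i.i.d. standard-normal entries; the intrinsic importance score of
#' feature f is the row sum `s*_f = sum_k W*_{f,k}`.
#'
#' @param n_features Number of features F.
#' @param dim Embedding dimension d.
#' @param seed Integer seed.
#' @return List with `W_star` (F x d matrix) and `s_star` (length-F vector).
#' @export
gen_true_W <- function(n_features, dim, seed = 0L) {
  stopifnot_count(n_features, "n_features")
  stopifnot_count(dim, "dim")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, 202L))
  W <- matrix(stats::rnorm(n_features * dim), nrow = n_features,
              dimnames = list(paste0("f", seq_len(n_features)),
                              paste0("k", seq_len(dim))))
  list(W_star = W, s_star = rowSums(W))
}

#' Gaussian self-masking of a feature table
#'
#' Each entry of row f is hidden (set to `NA`) independently with
#' probability `K_f * exp(-(x - mu_f)^2 / (2 sigma_f^2))`, where `mu_f`,
#' `sigma_f` are the row's empirical mean and standard deviation: values
#' close to the feature's typical value are the most likely to be missing
#' (not missing at random). The amplitude `K_f` is calibrated per row so the
#' expected missing fraction equals `rate`; since the expectation is linear
#' in `K_f` the calibration is a closed form (probabilities are capped at 1
#' with a warning if the requested rate is unreachable). A constant row
#' falls back to uniform Bernoulli(rate) masking.
#'
#' @param x Numeric feature matrix (features x entities).
#' @param rate Target missing fraction in `[0, 1)`.
#' @param seed Integer seed.
#' @return `x` with masked entries replaced by `NA`; observed values
#'   unchanged.
#' @export
apply_self_masking <- function(x, rate = 0.1, seed = 0L) {
  stopifnot(is.matrix(x), is.numeric(x))
  if (!is.numeric(rate) || length(rate) != 1L || rate < 0 || rate >= 1)
    stop("'rate' must lie in [0, 1)", call. = FALSE)
  if (rate == 0) return(x)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, 303L))
  prob <- matrix(rate, nrow(x), ncol(x))
  mu <- rowMeans(x)
  sdv <- apply(x, 1L, stats::sd)
  for (f in seq_len(nrow(x))) {
    if (!is.finite(sdv[f]) || sdv[f] <= 0) next  # constant row: uniform rate
    bump <- exp(-(x[f, ] - mu[f])^2 / (2 * sdv[f]^2))
    k <- rate / mean(bump)
    p <- k * bump
    if (any(p > 1)) {
      warning("self-masking rate unreachable for a row; probabilities capped")
      p <- pmin(p, 1)
    }
    prob[f, ] <- p
  }
  mask <- matrix(stats::runif(length(x)) < prob, nrow(x))
  x[mask] <- NA_real_
  x
}

#' Ground-truth association scores from the generating model g0
#'
#' First-order: `g0(x^i, x^u) = sigmoid((x^i + x^u) %*% W* %*% 1_d)`, which
#' equals the RHOFM with parameters `(0, 1_d, 0_{m-1}, W*)`. Second-order:
#' `g0 = sigmoid(RHOFM_{(1, 1_d, 1_{m-1}, W*)}(x^i, x^u))` with order m = 2.
#' Both use the linear structure function and no ridge penalty; missing
#' feature values are imputed to zero before scoring.
#'
#' @param S Item feature table (F x n_i), `NA` allowed.
#' @param P User feature table (F x n_u), `NA` allowed.
#' @param W_star F x d embedding matrix.
#' @param kind `"first_order"` or `"second_order"`.
#' @return `n_i x n_u` matrix of scores in (0, 1).
#' @export
gen_scores <- function(S, P, W_star, kind = c("first_order", "second_order")) {
  kind <- match.arg(kind)
  if (nrow(S) != nrow(P) || nrow(S) != nrow(W_star))
    stop("S, P and W_star must share the feature axis", call. = FALSE)
  Xi <- t(impute0(S))                      # n_i x F
  Xu <- t(impute0(P))                      # n_u x F
  if (kind == "first_order") {
    raw <- rhofm_score_matrix(0, w1 = rep(1, ncol(W_star)), w2 = 0,
                              W = W_star, Xi = Xi, Xu = Xu)
  } else {
    raw <- rhofm_score_matrix(1, w1 = rep(1, ncol(W_star)), w2 = 1,
                              W = W_star, Xi = Xi, Xu = Xu)
  }
  sigmoid(raw)
}

#' Threshold scores into a sparse {-1, 0, +1} association matrix
#'
#' The top `(1 - sparsity)/2` fraction of cells by score become `+1`, the
#' bottom `(1 - sparsity)/2` become `-1`, and the middle fraction
#' (`sparsity`, the "sparsity number") stays 0 (unknown). Counts are exact
#' up to integer rounding of one cell.
#'
#' @param scores Numeric matrix of pair scores.
#' @param sparsity Fraction of unknown cells; values below 0.5 are allowed
#'   but warned about.
#' @return Integer matrix over `{-1, 0, 1}` with the shape of `scores`.
#' @export
sparsify_labels <- function(scores, sparsity = 0.5) {
  if (!is.matrix(scores) || length(scores) == 0L)
    stop("'scores' must be a non-empty matrix", call. = FALSE)
  if (sparsity < 0 || sparsity >= 1)
    stop("'sparsity' must lie in [0, 1)", call. = FALSE)
  if (sparsity < 0.5)
    warning("sparsity below 0.5 departs from the intended regime")
  n <- length(scores)
  n_zero <- round(sparsity * n)
  n_pos <- ceiling((n - n_zero) / 2)
  n_neg <- n - n_zero - n_pos
  ord <- order(scores, decreasing = TRUE)     # stable tie-break
  lab <- integer(n)
  if (n_pos > 0) lab[ord[seq_len(n_pos)]] <- 1L
  if (n_neg > 0) lab[ord[seq.int(n - n_neg + 1L, n)]] <- -1L
  matrix(lab, nrow(scores), ncol(scores), dimnames = dimnames(scores))
}

#' Generate a complete synthetic recommendation dataset
#'
#' Bundles the whole generating protocol: standard-Gaussian item and user
#' features, ground-truth `W*` with importance vector `s*`, Gaussian
#' self-masking of the feature tables, pair scoring by the first- or
#' second-order logistic model, and sparsity-controlled labelling.
#'
#' @param n_features Number of shared features F (default 10).
#' @param dim Ground-truth embedding dimension d (default 2).
#' @param n_items,n_users Numbers of items and users (default 173 each).
#' @param kind `"first_order"` or `"second_order"` generating model.
#' @param sparsity Target fraction of unknown cells (default 0.5).
#' @param mask_rate Expected fraction of missing feature values
#'   (default 0.1).
#' @param seed Integer seed; everything is reproducible from it.
#' @return An object of class `"jeli_synth"`: a list with masked feature
#'   tables `S` (F x n_i) and `P` (F x n_u), association matrix `A`
#'   (n_i x n_u over -1/0/+1), `W_star`, `s_star`, `scores` (the latent g0
#'   scores), and the generation settings.
#' @examples
#' d <- simulate_dataset(n_features = 4, n_items = 20, n_users = 15, seed = 1)
#' table(d$A)
#' @export
simulate_dataset <- function(n_features = 10L, dim = 2L,
                             n_items = 173L, n_users = 173L,
                             kind = c("first_order", "second_order"),
                             sparsity = 0.5, mask_rate = 0.1, seed = 0L) {
  kind <- match.arg(kind)
  S <- gen_features(n_features, n_items, seed = derive_seed(seed, 1L))
  P <- gen_features(n_features, n_users, seed = derive_seed(seed, 2L))
  tw <- gen_true_W(n_features, dim, seed = derive_seed(seed, 3L))
  colnames(S) <- paste0("i", seq_len(n_items))
  colnames(P) <- paste0("u", seq_len(n_users))
  # g0 scores come from the complete feature values; the learner only ever
  # sees the masked tables below
  scores <- gen_scores(S, P, tw$W_star, kind)
  dimnames(scores) <- list(colnames(S), colnames(P))
  A <- sparsify_labels(scores, sparsity)
  S <- apply_self_masking(S, mask_rate, seed = derive_seed(seed, 4L))
  P <- apply_self_masking(P, mask_rate, seed = derive_seed(seed, 5L))
  structure(list(S = S, P = P, A = A, W_star = tw$W_star,
                 s_star = tw$s_star, scores = scores, kind = kind,
                 sparsity = sparsity, mask_rate = mask_rate, seed = seed,
                 n_features = as.integer(n_features), dim = as.integer(dim),
                 n_items = as.integer(n_items), n_users = as.integer(n_users)),
            class = "jeli_synth")
}

#' @export
print.jeli_synth <- function(x, ...) {
  cat(sprintf("Synthetic %s recommendation dataset\n",
              sub("_", "-", x$kind)))
  cat(sprintf("  %d items x %d users, %d shared features (d = %d)\n",
              x$n_items, x$n_users, x$n_features, x$dim))
  cat(sprintf("  sparsity number: %.3f (requested %.3f)\n",
              mean(x$A == 0), x$sparsity))
  cat(sprintf("  missing feature values: %.1f%% (items), %.1f%% (users)\n",
              100 * mean(is.na(x$S)), 100 * mean(is.na(x$P))))
  invisible(x)
}

# Save/restore the global RNG state so generator calls do not perturb the
# caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
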