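# Ranking metrics: Spearman's rho on feature-importance scores, ROC AUC,
# user-averaged NS-AUC, and user-averaged NDCG at the item count.

#' Spearman rank correlation between true and predicted importance scores
#'
#' `1 - 6 sum(Delta_f^2) / (F (F^2 - 1))` where `Delta_f` is the rank gap
#' (decreasing order, average ranks for ties) between the two scores of
#' feature f.
#'
#' @param s_true,s_pred Numeric vectors of equal length F >= 2.
#' @return Scalar in `[-1, 1]`, or `NA` with a warning when either vector
#'   is constant (ranks undefined).
#' @export
spearman_rho <- function(s_true, s_pred) {
  if (length(s_true) != length(s_pred) || length(s_true) < 2L)
    stop("inputs must be two vectors of equal length >= 2", call. = FALSE)
  if (stats::sd(s_true) == 0 || stats::sd(s_pred) == 0) {
    warning("constant score vector: Spearman's rho is undefined")
    return(NA_real_)
  }
  F_ <- length(s_true)
  rt <- rank(-s_true, ties.method = "average")
  rp <- rank(-s_pred, ties.method = "average")
  1 - 6 * sum((rt - rp)^2) / (F_ * (F_^2 - 1))
}

#' ROC area under the curve
#'
#' Probability that a uniformly drawn positive cell outscores a uniformly
#' drawn negative one, ties counting one half (the rank/Mann-Whitney
#' formulation of the ROC area).
#'
#' @param labels Vector over `{-1, +1}` (held-out association labels).
#' @param scores Matching numeric prediction scores.
#' @return Scalar in `[0, 1]`, or `NA` with a warning on single-class
#'   input.
#' @export
auc <- function(labels, scores) {
  keep <- !is.na(labels)
  labels <- labels[keep]; scores <- scores[keep]
  if (length(labels) != length(scores))
    stop("labels and scores must have equal length", call. = FALSE)
  npos <- sum(labels == 1); nneg <- sum(labels == -1)
  if (npos == 0 || nneg == 0) {
    warning("AUC undefined: need at least one positive and one negative")
    return(NA_real_)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' User-averaged NS-AUC
#'
#' For each user u, the fraction of item pairs (i, i') with a strictly
#' larger true label (`A[i, u] > A[i', u]`) whose predicted scores are also
#' strictly ordered (`scores[i, u] > scores[i', u]`; ties earn no credit),
#' averaged over users with at least one such pair. Cells with `NA` in `A`
#' are excluded, which restricts the evaluation to, e.g., held-out cells.
#'
#' @param A Item x user label matrix over `{-1, 0, 1}` (`NA` = excluded).
#' @param scores Matching numeric score matrix.
#' @return Scalar in `[0, 1]`, or `NA` with a warning when no user has an
#'   ordered pair.
#' @export
ns_auc <- function(A, scores) {
  stopifnot(is.matrix(A), all(dim(A) == dim(scores)))
  per_user <- rep(NA_real_, ncol(A))
  for (u in seq_len(ncol(A))) {
    a <- A[, u]; s <- scores[, u]
    keep <- !is.na(a)
    a <- a[keep]; s <- s[keep]
    lv <- sort(unique(a))
    if (length(lv) < 2L) next
    tot <- 0; good <- 0
    for (hi in seq_along(lv)[-1L]) for (lo in seq_len(hi - 1L)) {
      sx <- s[a == lv[hi]]; sy <- sort(s[a == lv[lo]])
      tot <- tot + length(sx) * length(sy)
      # strict count: elements of sy strictly below each sx
      good <- good + sum(findInterval(sx, sy, left.open = TRUE))
    }
    per_user[u] <- good / tot
  }
  if (all(is.na(per_user))) {
    warning("NS-AUC undefined: no user has a strictly ordered item pair")
    return(NA_real_)
  }
  mean(per_user, na.rm = TRUE)
}

#' User-averaged NDCG at the item count
#'
#' Per user, items are sorted by decreasing predicted score; the discounted
#' cumulative gain over the first `N+_u = min(n_i, #positives)` positions
#' uses the raw association values as gains (so a mis-ranked `-1` item
#' contributes negatively), normalised by the all-ones ideal. Users without
#' a positive item are excluded; `NA` cells in `A` are excluded.
#'
#' @inheritParams ns_auc
#' @return Scalar `<= 1` (can be negative), or `NA` with a warning when no
#'   user has a positive item.
#' @export
ndcg_at_ni <- function(A, scores) {
  stopifnot(is.matrix(A), all(dim(A) == dim(scores)))
  per_user <- rep(NA_real_, ncol(A))
  for (u in seq_len(ncol(A))) {
    a <- A[, u]; s <- scores[, u]
    keep <- !is.na(a)
    a <- a[keep]; s <- s[keep]
    npos <- sum(a == 1)
    if (npos == 0L) next
    ntop <- min(length(a), npos)
    ord <- order(s, decreasing = TRUE)
    disc <- 1 / log2(seq_len(ntop) + 1)
    per_user[u] <- sum(a[ord[seq_len(ntop)]] * disc) / sum(disc)
  }
  if (all(is.na(per_user))) {
    warning("NDCG undefined: no user has a positive item")
    return(NA_real_)
  }
  mean(per_user, na.rm = TRUE)
}

#' Bundle the four validation metrics
#'
#' @param A_eval Item x user label matrix with `NA` on cells excluded from
#'   evaluation (e.g. training cells).
#' @param scores Predicted score matrix.
#' @param s_true,s_pred Optional true and fitted feature-importance vectors
#'   for the Spearman component.
#' @return List of class `"jeli_metrics"` with `auc`, `ns_auc`, `ndcg`,
#'   `spearman_rho` and `n_evaluated_pairs`.
#' @export
metrics_report <- function(A_eval, scores, s_true = NULL, s_pred = NULL) {
  lab <- A_eval[!is.na(A_eval) & A_eval != 0]
  sc <- scores[!is.na(A_eval) & A_eval != 0]
  rho <- if (!is.null(s_true) && !is.null(s_pred))
    spearman_rho(s_true, s_pred) else NA_real_
  structure(list(auc = auc(lab, sc),
                 ns_auc = ns_auc(A_eval, scores),
                 ndcg = ndcg_at_ni(A_eval, scores),
                 spearman_rho = rho,
                 n_evaluated_pairs = sum(!is.na(A_eval))),
            class = "jeli_metrics")
}

#' @export
print.jeli_metrics <- function(x, ...) {
  cat("Validation metrics\n")
  cat(sprintf("  AUC:          %s\n", format(x$auc, digits = 4)))
  cat(sprintf("  NS-AUC:       %s\n", format(x$ns_auc, digits = 4)))
  cat(sprintf("  NDCG@n_i:     %s\n", format(x$ndcg, digits = 4)))
  cat(sprintf("  Spearman rho: %s\n", format(x$spearman_rho, digits = 4)))
  cat(sprintf("  evaluated cells: %d\n", x$n_evaluated_pairs))
  invisible(x)
}
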