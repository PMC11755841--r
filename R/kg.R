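# Nine-relation similarity-based knowledge graph built from the association
# matrix A and the item/user feature tables S and P, optionally augmented
# with prior edges. Relations: known associations (+ / -), item-item and
# user-user similarity above a threshold tau, signed item-feature and
# user-feature links from the signs of S and P, and "prior" edges.

KG_RELATIONS <- c("prior", "+", "-", "user-sim", "item-sim",
                  "item-feat-pos", "item-feat-neg",
                  "user-feat-pos", "user-feat-neg")

#' Cosine similarity between two feature vectors
#'
#' Missing entries are imputed to zero; an all-zero vector has similarity
#' exactly 0 with anything.
#'
#' @param u,v Numeric vectors of equal length.
#' @return Scalar in `[-1, 1]`.
#' @export
cosine_similarity <- function(u, v) {
  if (length(u) != length(v))
    stop("vectors must have equal length", call. = FALSE)
  u <- impute0(as.numeric(u)); v <- impute0(as.numeric(v))
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) return(0)
  sum(u * v) / (nu * nv)
}

# Pairwise cosine similarity between the columns of a (zero-imputed)
# feature table; all-zero columns get similarity 0.
cosine_matrix <- function(X) {
  X <- impute0(X)
  nrm <- sqrt(colSums(X^2))
  nrm[nrm == 0] <- Inf
  Xn <- sweep(X, 2L, nrm, "/")
  crossprod(Xn)
}

#' Build the similarity-based knowledge graph
#'
#' Assembles the triplet set from: prior edges (relation `"prior"`); `+`
#' and `-` triplets for the known cells of `A`; `user-sim` / `item-sim`
#' triplets for entity pairs whose cosine similarity strictly exceeds
#' `tau` (self-pairs excluded, one canonical direction stored); and signed
#' `item-feat-pos`/`-neg`, `user-feat-pos`/`-neg` triplets from the signs
#' of `S` and `P` (missing entries produce no edge).
#'
#' @param A Item x user association matrix over `{-1, 0, 1}`.
#' @param S Item feature table (F x n_i), `NA` allowed.
#' @param P User feature table (F x n_u), `NA` allowed.
#' @param prior Optional data frame of prior edges with columns `head` and
#'   `tail` (a third `relation` column is ignored: prior edges are labelled
#'   `"prior"`). Endpoints not among the items/users/features are
#'   registered as new prior-only entities, with a message.
#' @param tau Similarity threshold in `[0, 1]`.
#' @param similarity Similarity function for entity pairs; the default is
#'   cosine on zero-imputed vectors. Any function of two vectors into
#'   `[-1, 1]` may be plugged in.
#' @return An object of class `"jeli_kg"`: list with `triplets` (data frame
#'   head/relation/tail), `entities`, `partition` (named vector over
#'   item/user/feature/prior), and `tau`.
#' @export
build_knowledge_graph <- function(A, S, P, prior = NULL, tau = 0.5,
                                  similarity = NULL) {
  if (!is.numeric(tau) || length(tau) != 1L || tau < 0 || tau > 1)
    stop("'tau' must lie in [0, 1]", call. = FALSE)
  if (nrow(S) != nrow(P))
    stop("S and P must share the feature axis", call. = FALSE)
  if (nrow(A) != ncol(S) || ncol(A) != ncol(P))
    stop("A must be items x users matching ncol(S) and ncol(P)",
         call. = FALSE)
  if (!all(A %in% c(-1, 0, 1)))
    stop("A must take values in {-1, 0, 1}", call. = FALSE)

  items <- colnames(S); if (is.null(items)) items <- paste0("i", seq_len(ncol(S)))
  users <- colnames(P); if (is.null(users)) users <- paste0("u", seq_len(ncol(P)))
  feats <- rownames(S); if (is.null(feats)) feats <- paste0("f", seq_len(nrow(S)))

  tri <- function(h, r, t) {
    if (length(h) == 0L) return(NULL)
    data.frame(head = h, relation = r, tail = t, stringsAsFactors = FALSE)
  }
  parts <- list()

  # known associations
  pos <- which(A == 1, arr.ind = TRUE)
  neg <- which(A == -1, arr.ind = TRUE)
  parts$pos <- tri(items[pos[, 1L]], "+", users[pos[, 2L]])
  parts$neg <- tri(items[neg[, 1L]], "-", users[neg[, 2L]])

  # similarity edges (strict threshold, canonical direction j < k)
  sim_pairs <- function(X, names, rel) {
    if (is.null(similarity)) {
      cs <- cosine_matrix(X)
    } else {
      n <- ncol(X)
      cs <- matrix(0, n, n)
      X0 <- impute0(X)
      for (j in seq_len(n)) for (k in seq_len(n))
        cs[j, k] <- similarity(X0[, j], X0[, k])
    }
    cs[lower.tri(cs, diag = TRUE)] <- -Inf    # self-pairs and duplicates out
    hit <- which(cs > tau, arr.ind = TRUE)
    tri(names[hit[, 1L]], rel, names[hit[, 2L]])
  }
  parts$isim <- sim_pairs(S, items, "item-sim")
  parts$usim <- sim_pairs(P, users, "user-sim")

  # signed entity-feature edges; NA entries yield no edge
  feat_edges <- function(X, names, relpos, relneg) {
    up <- which(X > 0, arr.ind = TRUE)       # NA drops out of comparisons
    dn <- which(X < 0, arr.ind = TRUE)
    rbind(tri(names[up[, 2L]], relpos, feats[up[, 1L]]),
          tri(names[dn[, 2L]], relneg, feats[dn[, 1L]]))
  }
  parts$ifeat <- feat_edges(S, items, "item-feat-pos", "item-feat-neg")
  parts$ufeat <- feat_edges(P, users, "user-feat-pos", "user-feat-neg")

  entities <- c(items, users, feats)
  partition <- stats::setNames(
    rep(c("item", "user", "feature"),
        c(length(items), length(users), length(feats))), entities)

  if (!is.null(prior) && nrow(prior) > 0L) {
    stopifnot(all(c("head", "tail") %in% names(prior)))
    new_ent <- setdiff(unique(c(prior$head, prior$tail)), entities)
    if (length(new_ent) > 0L) {
      message(length(new_ent), " prior-only entities registered")
      entities <- c(entities, new_ent)
      partition <- c(partition,
                     stats::setNames(rep("prior", length(new_ent)), new_ent))
    }
    parts$prior <- tri(as.character(prior$head), "prior",
                       as.character(prior$tail))
  }

  triplets <- do.call(rbind, Filter(Negate(is.null), parts))
  if (is.null(triplets))
    triplets <- data.frame(head = character(), relation = character(),
                           tail = character(), stringsAsFactors = FALSE)
  triplets <- unique(triplets)
  rownames(triplets) <- NULL
  structure(list(triplets = triplets, entities = entities,
                 partition = partition, relations = KG_RELATIONS, tau = tau),
            class = "jeli_kg")
}

#' @export
print.jeli_kg <- function(x, ...) {
  cat(sprintf("Knowledge graph: %d entities, %d triplets (tau = %g)\n",
              length(x$entities), nrow(x$triplets), x$tau))
  tab <- table(factor(x$triplets$relation, levels = x$relations))
  for (r in names(tab)) if (tab[[r]] > 0)
    cat(sprintf("  %-14s %d\n", r, tab[[r]]))
  invisible(x)
}

#' Write / read a knowledge graph as a triplet file
#'
#' The graph is stored as a 3-column tab-separated file (head, relation,
#' tail) plus a JSON sidecar (`<path>.meta.json`) holding the entity
#' partition and the similarity threshold. `read_kg()` also accepts a bare
#' 2- or 3-column triplet file as a prior graph (missing relation column
#' defaults to `"prior"`).
#'
#' @param kg A `"jeli_kg"` object.
#' @param path Path of the triplet file.
#' @return `read_kg()` returns a `"jeli_kg"` object; `write_kg()` returns
#'   `path` invisibly.
#' @export
write_kg <- function(kg, path) {
  stopifnot(inherits(kg, "jeli_kg"))
  utils::write.table(kg$triplets, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  meta <- list(entities = kg$entities,
               partition = as.list(kg$partition), tau = kg$tau)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_kg
#' @export
read_kg <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (ncol(df) == 2L) {
    names(df) <- c("head", "tail")
    df$relation <- "prior"
    df <- df[, c("head", "relation", "tail")]
  }
  stopifnot(all(c("head", "relation", "tail") %in% names(df)))
  meta_path <- paste0(path, ".meta.json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    partition <- unlist(meta$partition)
    structure(list(triplets = df[, c("head", "relation", "tail")],
                   entities = meta$entities, partition = partition,
                   relations = KG_RELATIONS, tau = meta$tau),
              class = "jeli_kg")
  } else {
    ents <- unique(c(df$head, df$tail))
    structure(list(triplets = df[, c("head", "relation", "tail")],
                   entities = ents,
                   partition = stats::setNames(rep("prior", length(ents)),
                                               ents),
                   relations = KG_RELATIONS, tau = NA_real_),
              class = "jeli_kg")
  }
}
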