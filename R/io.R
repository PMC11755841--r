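# Plain-text serialisation: dataset bundles (TSV + JSON metadata), model
# archives (JSON named arrays + metadata). Everything is human-diffable at
# the scale this package targets; missing values are empty fields in TSV.

write_tsv_matrix <- function(m, path) {
  df <- as.data.frame(m)
  df <- cbind(id = if (is.null(rownames(m))) seq_len(nrow(m)) else rownames(m),
              df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
}

read_tsv_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, na.strings = "",
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1L]]
  m
}

#' Write / read a synthetic dataset bundle
#'
#' A bundle directory holds `A.tsv` (items x users), `S.tsv` and `P.tsv`
#' (features x entities, missing values as empty fields), `W_star.tsv`,
#' and `meta.json` (kind, sparsity, seed, geometry).
#'
#' @param dataset A [simulate_dataset()] object.
#' @param dir Bundle directory (created if needed).
#' @return `write_dataset_bundle()` returns `dir` invisibly;
#'   `read_dataset_bundle()` a `"jeli_synth"` object.
#' @export
write_dataset_bundle <- function(dataset, dir) {
  stopifnot(inherits(dataset, "jeli_synth"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv_matrix(dataset$A, file.path(dir, "A.tsv"))
  write_tsv_matrix(dataset$S, file.path(dir, "S.tsv"))
  write_tsv_matrix(dataset$P, file.path(dir, "P.tsv"))
  write_tsv_matrix(dataset$W_star, file.path(dir, "W_star.tsv"))
  meta <- dataset[c("kind", "sparsity", "mask_rate", "seed", "n_features",
                    "dim", "n_items", "n_users")]
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = I(17))
  invisible(dir)
}

#' @rdname write_dataset_bundle
#' @export
read_dataset_bundle <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  A <- read_tsv_matrix(file.path(dir, "A.tsv"))
  storage.mode(A) <- "integer"
  W <- read_tsv_matrix(file.path(dir, "W_star.tsv"))
  out <- list(S = read_tsv_matrix(file.path(dir, "S.tsv")),
              P = read_tsv_matrix(file.path(dir, "P.tsv")),
              A = A, W_star = W, s_star = rowSums(W))
  structure(c(out, meta), class = "jeli_synth")
}

#' Load and validate a dataset from delimited files
#'
#' Reads an association matrix and the item/user feature tables (TSV with
#' a header row and an id column; empty fields become missing values),
#' checks that `A` only takes values in `{-1, 0, 1}` (reporting the first
#' offending cell), that the feature axes agree, and that shapes are
#' consistent; reports shapes and the sparsity number.
#'
#' @param a_path,s_path,p_path Paths to `A`, `S`, `P`.
#' @param prior_path Optional path to a prior triplet file; a missing file
#'   yields an empty prior with a message.
#' @return List with `A`, `S`, `P`, `prior` (data frame or `NULL`).
#' @export
load_dataset <- function(a_path, s_path, p_path, prior_path = NULL) {
  A <- read_tsv_matrix(a_path)
  S <- read_tsv_matrix(s_path)
  P <- read_tsv_matrix(p_path)
  bad <- which(!(A %in% c(-1, 0, 1)) | is.na(A))
  if (length(bad) > 0L) {
    rc <- arrayInd(bad[1L], dim(A))
    stop(sprintf("A contains an invalid value %s at row %d ('%s'), column %d ('%s')",
                 format(A[bad[1L]]), rc[1L], rownames(A)[rc[1L]], rc[2L],
                 colnames(A)[rc[2L]]), call. = FALSE)
  }
  storage.mode(A) <- "integer"
  if (nrow(S) != nrow(P) || !identical(rownames(S), rownames(P)))
    stop("S and P do not share the feature axis", call. = FALSE)
  if (nrow(A) != ncol(S) || ncol(A) != ncol(P))
    stop("A must be items x users, matching the columns of S and P",
         call. = FALSE)
  prior <- NULL
  if (!is.null(prior_path)) {
    if (file.exists(prior_path)) {
      prior <- read_kg(prior_path)$triplets
    } else {
      message("prior file not found; using an empty prior graph")
    }
  }
  message(sprintf("loaded %d items x %d users, %d features; sparsity number %.3f",
                  nrow(A), ncol(A), nrow(S), mean(A == 0)))
  list(A = A, S = S, P = P, prior = prior)
}

MODEL_ARCHIVE_VERSION <- "jeli-model-1"

#' Save / load a fitted model archive
#'
#' The archive is a single JSON document holding every parameter array at
#' full floating-point precision plus the configuration, the entity index,
#' the graph triplets and the training feature tables, so that predictions
#' after a round trip reproduce the pre-save predictions exactly.
#'
#' @param fit A fitted [jeli()] model.
#' @param path Archive path.
#' @return `load_model()` returns the restored `"jeli"` object;
#'   `save_model()` returns `path` invisibly.
#' @export
save_model <- function(fit, path) {
  stopifnot(inherits(fit, "jeli"))
  p <- fit$rhofm
  arch <- list(
    version = MODEL_ARCHIVE_VERSION,
    config = fit$config,
    omega0 = p$omega0, omega1 = p$omega1, omega2m = p$omega2m,
    W = p$W, W_rownames = rownames(p$W),
    relations = fit$relations$labels,
    R = as.numeric(fit$relations$R), R_dim = dim(fit$relations$R),
    e_rel = fit$relations$e,
    biases = as.numeric(fit$biases),
    entities = fit$kg$entities,
    partition = as.list(fit$kg$partition),
    tau = fit$kg$tau,
    triplets = fit$kg$triplets,
    S = fit$S, S_rownames = rownames(fit$S), S_colnames = colnames(fit$S),
    P = fit$P, P_rownames = rownames(fit$P), P_colnames = colnames(fit$P),
    loss = fit$loss)
  jsonlite::write_json(arch, path, auto_unbox = TRUE,
                       digits = I(17), na = "null")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  arch <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                   error = function(e)
                     stop("cannot read model archive: ",
                          conditionMessage(e), call. = FALSE))
  if (!identical(arch$version, MODEL_ARCHIVE_VERSION))
    stop(sprintf("model archive version mismatch: found '%s', expected '%s'",
                 if (is.null(arch$version)) "<none>" else arch$version,
                 MODEL_ARCHIVE_VERSION), call. = FALSE)
  as_mat <- function(x) {
    m <- as.matrix(x); storage.mode(m) <- "double"; m
  }
  W <- as_mat(arch$W); rownames(W) <- arch$W_rownames
  S <- as_mat(arch$S); dimnames(S) <- list(arch$S_rownames, arch$S_colnames)
  P <- as_mat(arch$P); dimnames(P) <- list(arch$P_rownames, arch$P_colnames)
  cfg <- arch$config
  params <- rhofm_params(W, omega0 = arch$omega0, omega1 = arch$omega1,
                         omega2m = arch$omega2m, order = cfg$order,
                         ridge = cfg$ridge, structure = "linear")
  partition <- unlist(arch$partition)
  kg <- structure(list(triplets = as.data.frame(arch$triplets),
                       entities = arch$entities, partition = partition,
                       relations = arch$relations, tau = arch$tau),
                  class = "jeli_kg")
  n_ent <- length(arch$entities)
  F_ <- nrow(W); n_i <- ncol(S); n_u <- ncol(P)
  Xent <- matrix(0, n_ent, F_)
  Xent[seq_len(n_i), ] <- t(impute0(S))
  Xent[n_i + seq_len(n_u), ] <- t(impute0(P))
  Xent[cbind(n_i + n_u + seq_len(F_), seq_len(F_))] <- 1
  structure(list(
    rhofm = params,
    relations = list(labels = arch$relations,
                     R = array(arch$R, arch$R_dim),
                     e = as_mat(arch$e_rel),
                     mure = setdiff(arch$relations, c("+", "-"))),
    biases = stats::setNames(arch$biases, arch$entities),
    kg = kg, Xent = Xent, holdout = NULL, A = NULL, A_train = NULL,
    S = S, P = P, loss = arch$loss, skipped_negatives = NA_integer_,
    config = cfg), class = "jeli")
}
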