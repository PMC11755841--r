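# Internal helpers shared across the package.

#' Standard logistic sigmoid
#'
#' @param x Numeric vector or matrix.
#' @return `1 / (1 + exp(-x))`, same shape as `x`.
#' @keywords internal
sigmoid <- function(x) 1 / (1 + exp(-x))

# Replace missing entries by zero; the package-wide imputation convention
# ("padding with zeroes" at scoring time).
impute0 <- function(x) {
  x[is.na(x)] <- 0
  x
}

# Derive a reproducible 32-bit sub-seed from a base seed and a stream label.
# Keeps all derived seeds in [0, 2^31 - 1].
derive_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  s <- 0
  for (p in parts) s <- (s * 69069 + as.numeric(p) + 1) %% 2147483647
  as.integer(s)
}

stopifnot_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 || x != floor(x))
    stop(sprintf("'%s' must be a positive integer, got %s", name,
                 paste(format(x), collapse = ", ")), call. = FALSE)
  invisible(as.integer(x))
}
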