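# Shared fixtures: everything is generated in code at test time.

# A small synthetic dataset for fast end-to-end tests.
tiny_dataset <- function(seed = 7L, n_features = 6L, n_items = 40L,
                         n_users = 30L, ...) {
  simulate_dataset(n_features = n_features, n_items = n_items,
                   n_users = n_users, seed = seed, ...)
}

# The 2-item / 1-user / 1-feature toy instance whose knowledge graph can be
# enumerated by hand: exactly four triplets.
toy_kg_inputs <- function() {
  A <- matrix(c(1L, -1L), 2L, 1L, dimnames = list(c("i1", "i2"), "u1"))
  S <- matrix(c(1, -1), 1L, 2L, dimnames = list("f1", c("i1", "i2")))
  P <- matrix(0, 1L, 1L, dimnames = list("f1", "u1"))
  list(A = A, S = S, P = P)
}

expect_same_matrix <- function(a, b, tol = 1e-12) {
  expect_equal(unname(as.matrix(a)), unname(as.matrix(b)), tolerance = tol)
}
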