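# Small designs and fixtures built in code, shared across test files.

# Random multi-block design with optional custom weights.
random_design <- function(n = 12, p = c(6, 8), seed = 1, center = TRUE,
                          q = "colsum", d = "identity", w = NULL) {
  withr::with_seed(seed, {
    x <- lapply(seq_along(p), function(k) matrix(rnorm(n * p[k]), n, p[k]))
    names(x) <- paste0("blk", seq_along(p))
  })
  cia_design(x, center = center, q = q, d = d, w = w)
}

# Noiseless rank-1 design: X_k = t %*% t(a_k) with sparse unit a_k.
# Returns the design plus the true loadings and supports.
rank1_design <- function(n = 20, p = c(12, 15), nnz = c(3, 4), seed = 1) {
  withr::with_seed(seed, {
    t_scores <- rnorm(n)
    a <- lapply(seq_along(p), function(k) {
      v <- numeric(p[k])
      v[seq_len(nnz[k])] <- rnorm(nnz[k])
      v / sqrt(sum(v^2))
    })
    x <- lapply(seq_along(p), function(k) tcrossprod(t_scores, a[[k]]))
    names(x) <- paste0("blk", seq_along(p))
  })
  # no centering/standardization: zero-variance-free but we keep the exact
  # rank-1 structure by using identity metrics
  design <- cia_design(x, center = FALSE, q = "identity")
  list(design = design, a = a, nnz = nnz)
}

# Tiny scenario config for fast Monte-Carlo tests.
tiny_config <- function(sigma2 = 2.5, n = 40, p = c(24, 30), n_el = 4,
                        n_en = c(2, 3), n_networks = 5) {
  scenario_config(NULL, n = n, p = p, sigma2 = sigma2, n_el = n_el,
                  n_en = n_en, n_networks = n_networks)
}

expect_unit_norm <- function(x, tol = 1e-8) {
  expect_equal(sum(x^2), 1, tolerance = tol)
}
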