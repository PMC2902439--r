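# Independent oracles used to freeze expected values.

# BDe marginal likelihood via the sequential Polya-urn predictive product
# (chain rule), an independent derivation of the same quantity as the
# closed-form Gamma-function ratio in bde_score().
oracle_bde_logml <- function(y, parents = NULL, ess = 1) {
  y <- as.integer(y)
  k <- if (is.null(parents)) 0L else ncol(parents)
  q <- 2^k
  code <- rep(1L, length(y))
  if (k > 0)
    for (b in seq_len(k))
      code <- code + as.integer(parents[, b] != 0) * 2L^(b - 1L)
  ajc <- ess / (2 * q)
  seen <- matrix(0, q, 2)
  lp <- 0
  for (i in seq_along(y)) {
    j <- code[i]
    cc <- y[i] + 1L
    lp <- lp + log((seen[j, cc] + ajc) / (sum(seen[j, ]) + 2 * ajc))
    seen[j, cc] <- seen[j, cc] + 1
  }
  lp
}

# weighted least squares through the normal equations, solved directly
oracle_wls <- function(x, y, w) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% (w * X), t(X) %*% (w * y))
  drop(beta)
}

# small synthetic bundle for unit tests
tiny_bundle <- function(seed = 1, n_a = 300, n_b = 280, ...) {
  simulate_bundle(synth_config(seed = seed, n_genes_A = n_a,
                               n_genes_B = n_b, ...))
}

# signed loadings straight from planted truth (no SVD re-estimation)
truth_signs <- function(truth, system = "A", k = 2) {
  U <- truth[[paste0("U_", system)]]
  binarize_loadings(list(U = U, genes = rownames(U)), k)
}
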