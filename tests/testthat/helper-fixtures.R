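# Small random fixtures shared across tests; all generated in code.

make_dist <- function(p, seed = 1) {
  random_tree(p, seed = seed)
}

# proportions matrix (samples x OTUs) with plenty of exact zeros
make_props <- function(n, p, seed = 1) {
  set.seed(seed)
  z <- matrix(rexp(n * p), n, p)
  z[matrix(runif(n * p) < 0.3, n, p)] <- 0
  z <- z / pmax(rowSums(z), 1e-12)
  colnames(z) <- paste0("otu", seq_len(p))
  rownames(z) <- paste0("s", seq_len(n))
  z
}

# brute-force kernel oracle: explicit double sum over OTU pairs
kernel_by_double_sum <- function(z_a, z_b, C, gamma) {
  fa <- power_transform(z_a, gamma)
  fb <- power_transform(z_b, gamma)
  K <- matrix(0, nrow(z_a), nrow(z_b))
  for (a in seq_len(nrow(z_a))) {
    for (b in seq_len(nrow(z_b))) {
      s <- 0
      for (i in seq_len(ncol(z_a))) {
        for (j in seq_len(ncol(z_b))) {
          s <- s + fa[a, i] * C[i, j] * fb[b, j]
        }
      }
      K[a, b] <- s
    }
  }
  K
}

# draw y ~ N(X beta, sigma_b2 K + sigma_e2 I) through a Cholesky root
draw_mvn_outcome <- function(X, beta, K, sigma_b2, sigma_e2) {
  n <- nrow(X)
  Sigma <- sigma_b2 * K + sigma_e2 * diag(n)
  drop(X %*% beta) + drop(crossprod(chol(Sigma), rnorm(n)))
}
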