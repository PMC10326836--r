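# Independent oracles and fixture builders shared across tests.

# dense (np x np) multivariate-normal log-density with covariance C (x) R
# (vec is column-major over the n x p matrix E, so cov = kronecker(R, C));
# brute-force reference for the structured likelihood
dense_mvn_loglik <- function(E, C, R) {
  n <- nrow(E); p <- ncol(E)
  Sigma <- kronecker(R, C)
  ch <- chol(Sigma)
  v <- as.vector(E)
  -0.5 * n * p * log(2 * pi) - sum(log(diag(ch))) -
    0.5 * sum(backsolve(ch, v, transpose = TRUE)^2)
}

# Brownian conditional expectation of internal-node states by explicit joint
# MVN conditioning on a full (tips + nodes) covariance matrix
dense_gls_nodes <- function(tree, lam, tip_logX, logZ0) {
  ttree <- lambda_transform(tree, lam)
  dn <- ape::dist.nodes(ttree)
  n <- length(tree$tip.label)
  root <- n + 1L
  depths <- dn[root, ]
  V <- (outer(depths, depths, "+") - dn) / 2
  tips <- seq_len(n)
  nodes <- (n + 1L):(n + tree$Nnode)
  p <- length(logZ0)
  est <- matrix(NA_real_, length(nodes), p)
  for (j in seq_len(p)) {
    mu_t <- rep(logZ0[j], n)
    est[, j] <- logZ0[j] +
      V[nodes, tips] %*% solve(V[tips, tips], tip_logX[, j] - mu_t)
  }
  est
}

# small fixture: ultrametric 3-tip tree of depth 2 used throughout
tree3 <- function() ape::read.tree(text = "((A:1,B:1):1,C:2);")

# simplex rows matrix with labels
simplex_table <- function(values, hosts, taxa) {
  m <- matrix(values, nrow = length(hosts), byrow = TRUE)
  m <- m / rowSums(m)
  rownames(m) <- hosts
  colnames(m) <- taxa
  m
}

# quick simulated dataset bundle for inference tests
sim_dataset <- function(n, p, lam, seed, spectrum = "equal") {
  tree <- simulate_pure_birth(n, seed = seed)
  Z0 <- sample_root(p, seed = seed + 1)
  R <- random_spd(p, 0.25, seed = seed + 2, spectrum = spectrum)
  sim <- simulate_microbiota(tree, model_params(lam, Z0, R), seed = seed + 3)
  list(tree = tree, Z0 = Z0, R = R, table = sim$table, truth = sim$truth)
}

# scaled-down sampler settings for fits inside the test suite
fast_fit_args <- list(chains = 1, iter = 400, warmup = 200, max_treedepth = 5)
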