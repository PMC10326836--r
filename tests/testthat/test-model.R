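test_that("composition_table enforces simplex rows and the floor", {
  m <- simplex_table(c(0.6, 0.4, 0.5, 0.5), c("A", "B"), c("t1", "t2"))
  expect_silent(composition_table(m))
  bad <- m; bad[1, 1] <- 0.7
  expect_error(composition_table(bad), "sum to 1")
  zeroed <- m; zeroed[1, ] <- c(1, 0)
  expect_error(composition_table(zeroed), "floor")
})

test_that("assemble_latent_logX adds the latent totals on the log scale", {
  m <- simplex_table(c(0.5, 0.5, 0.2, 0.8), c("A", "B"), c("t1", "t2"))
  expect_equal(assemble_latent_logX(m, c(0, 0)), log(m))
  expect_equal(unname(assemble_latent_logX(m, c(log(2), 0))[1, ]), c(0, 0))
  logY <- c(0.7, -1.2)
  X <- assemble_latent_logX(m, logY)
  expect_equal(unname(rowSums(exp(X))), exp(logY))  # row-sum identity
})

test_that("log_likelihood matches a univariate oracle on a star tree", {
  star <- ape::read.tree(text = "(A:2,B:2,C:2,D:2,E:2);")
  n <- 5
  data <- matrix(1, n, 1, dimnames = list(star$tip.label, "t1"))
  logY <- c(0.3, -0.5, 1.1, 0.0, -0.2)
  R <- matrix(0.4, 1, 1)
  params <- model_params(0, c(t1 = 1), R, logY)
  ll <- log_likelihood(params, data, star)
  oracle <- sum(stats::dnorm(logY, 0, sqrt(2 * 0.4), log = TRUE))
  expect_equal(ll, oracle, tolerance = 1e-8)
})

test_that("log_likelihood matches the dense Kronecker oracle", {
  # p = 2 cherry, then a batch of random small instances
  cherry <- ape::read.tree(text = "(A:1.5,B:1.5);")
  m <- simplex_table(c(0.3, 0.7, 0.6, 0.4), c("A", "B"), c("t1", "t2"))
  R <- matrix(c(0.5, 0.2, 0.2, 0.8), 2, 2)
  logY <- c(0.4, -0.3)
  Z0 <- c(0.25, 0.75)
  ll <- log_likelihood(model_params(1, Z0, R, logY), m, cherry)
  E <- assemble_latent_logX(m, logY) - matrix(log(Z0), 2, 2, byrow = TRUE)
  expect_equal(ll, dense_mvn_loglik(E, phylo_covariance(cherry), R),
               tolerance = 1e-8)

  for (k in 1:12) {
    set.seed(7000 + k)
    n <- sample(2:4, 1); p <- sample(2:3, 1)
    tree <- simulate_pure_birth(n, seed = 7100 + k)
    Z0 <- sample_root(p, seed = 7200 + k)
    R <- random_spd(p, 0.3, seed = 7300 + k, spectrum = "varied")
    set.seed(7400 + k)
    Z <- matrix(rexp(n * p), n, p)
    Z <- Z / rowSums(Z)
    dimnames(Z) <- list(tree$tip.label, paste0("t", seq_len(p)))
    logY <- rnorm(n, 0, 0.5)
    lam <- runif(1)
    ll <- log_likelihood(model_params(lam, Z0, R, logY), Z, tree)
    C <- phylo_covariance(lambda_transform(tree, lam))
    E <- assemble_latent_logX(Z, logY) - matrix(log(Z0), n, p, byrow = TRUE)
    expect_equal(ll, dense_mvn_loglik(E, C, R), tolerance = 1e-8)
  }
})

test_that("lambda is unidentifiable on a star tree", {
  star <- ape::read.tree(text = "(A:2,B:2,C:2,D:2);")
  m <- simplex_table(runif(8, 0.1, 1), star$tip.label, c("t1", "t2"))
  R <- random_spd(2, 0.3, seed = 5, spectrum = "varied")
  logY <- c(0.1, -0.4, 0.6, 0)
  Z0 <- c(0.4, 0.6)
  lls <- vapply(c(0, 0.3, 0.7, 1), function(l)
    log_likelihood(model_params(l, Z0, R, logY), m, star), numeric(1))
  expect_lt(diff(range(lls)), 1e-8)
})

test_that("likelihood responds to a global shift of the latent totals", {
  dat <- sim_dataset(8, 3, 1, seed = 42)
  logY <- dat$truth$logYtilde
  ll0 <- log_likelihood(model_params(1, dat$Z0, dat$R, logY),
                        dat$table, dat$tree)
  ll1 <- log_likelihood(model_params(1, dat$Z0, dat$R, logY + 1),
                        dat$table, dat$tree)
  expect_gt(abs(ll0 - ll1), 1e-6)
})

test_that("likelihood stays finite as R is rescaled over two decades", {
  dat <- sim_dataset(10, 3, 0.5, seed = 17)
  logY <- dat$truth$logYtilde
  for (f in c(0.1, 0.5, 1, 2, 10)) {
    ll <- log_likelihood(model_params(0.5, dat$Z0, dat$R * f, logY),
                         dat$table, dat$tree)
    expect_true(is.finite(ll))
  }
})

test_that("collapsed posterior matches a dense marginal oracle and its
           gradient matches finite differences", {
  tree <- simulate_pure_birth(6, seed = 5)
  Z0 <- sample_root(3, seed = 2)
  R <- random_spd(3, 0.25, seed = 3, spectrum = "varied")
  sim <- simulate_microbiota(tree, model_params(0.7, Z0, R), seed = 7)
  Z <- sim$table
  sc <- tree_depth(tree)
  nt <- tree; nt$edge.length <- nt$edge.length / sc
  C <- phylo_covariance(nt)
  eig <- eigen(C, symmetric = TRUE)
  logZ <- log(Z)[nt$tip.label, ]
  n <- nrow(Z); p <- ncol(Z)
  sigma_y <- 0.8; mu_y <- 0.3; lam <- 0.6
  th <- phylosym:::.pack_params(lam, Z0, R * sc, mu_y = mu_y)
  f <- function(t) phylosym:::.psym_lp_grad(t, logZ, eig$vectors,
                                            pmax(eig$values, 0),
                                            max(diag(C)), sigma_y, 2.5, 1.5)
  r0 <- f(th)
  num <- vapply(seq_along(th), function(i) {
    e <- rep(0, length(th)); e[i] <- 1e-6
    (f(th + e)$lp - f(th - e)$lp) / 2e-6
  }, numeric(1))
  expect_lt(max(abs(num - r0$grad)), 1e-5)

  # dense oracle: marginal over logYtilde ~ N(mu_y, sigma_y^2 I) is MVN with
  # covariance R (x) C_lam + sigma_y^2 (J_p (x) I_n)
  Clam <- lam * C + (1 - lam) * max(diag(C)) * diag(n)
  E0 <- logZ - matrix(log(Z0) + mu_y, n, p, byrow = TRUE)
  Sig <- kronecker(R * sc, Clam) +
    sigma_y^2 * kronecker(matrix(1, p, p), diag(n))
  ch <- chol(Sig)
  ll_dense <- -0.5 * n * p * log(2 * pi) - sum(log(diag(ch))) -
    0.5 * sum(backsolve(ch, as.vector(E0), transpose = TRUE)^2)
  lvec <- th[(p + 2):length(th)]
  isdiag <- logical(0)
  for (j in 1:p) for (i in j:p) isdiag <- c(isdiag, i == j)
  prior <- log(lam) + log(1 - lam) - 0.5 * mu_y^2 / 100 +
    sum(dnorm(lvec[isdiag], 0, 1.5, log = TRUE)) +
    sum(dnorm(lvec[!isdiag], 0, 2.5, log = TRUE))
  expect_equal(r0$lp, ll_dense + prior, tolerance = 1e-8)
})

test_that("model_params validates its inputs", {
  expect_error(model_params(1.5, c(0.5, 0.5), diag(2)), "lambda")
  expect_error(model_params(1, c(0.5, 0.4), diag(2)), "simplex")
  expect_error(model_params(1, c(0.5, 0.5), matrix(c(1, 2, 0, 1), 2)),
               "symmetric")
  expect_error(model_params(1, c(0.5, 0.5), matrix(c(1, 2, 2, 1), 2)),
               "positive definite")
})
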