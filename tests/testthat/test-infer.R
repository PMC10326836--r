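test_that("fit is deterministic given the seed", {
  dat <- sim_dataset(15, 3, 0.5, seed = 21)
  f1 <- do.call(fit, c(list(dat$tree, dat$table, seed = 4, quiet = TRUE),
                       fast_fit_args))
  f2 <- do.call(fit, c(list(dat$tree, dat$table, seed = 4, quiet = TRUE),
                       fast_fit_args))
  expect_identical(f1$summary$mean, f2$summary$mean)
  f3 <- do.call(fit, c(list(dat$tree, dat$table, seed = 5, quiet = TRUE),
                       fast_fit_args))
  expect_false(identical(f1$summary$mean, f3$summary$mean))
})

test_that("posterior summary is coherent and covers every parameter", {
  dat <- sim_dataset(15, 3, 1, seed = 23)
  ft <- do.call(fit, c(list(dat$tree, dat$table, seed = 1, quiet = TRUE),
                       fast_fit_args))
  s <- ft$summary
  # lambda, Z0, mu_logY, vech(R), logYtilde
  expect_equal(nrow(s), 1 + 3 + 1 + 6 + 15)
  expect_true(all(s$`q2.5` <= s$mean + 1e-12))
  expect_true(all(s$mean <= s$`q97.5` + 1e-12))
  expect_true(all(is.finite(s$rhat)))
  expect_true(all(is.finite(s$ess)))
})

test_that("mean_estimates returns valid parameters inside their intervals", {
  dat <- sim_dataset(15, 3, 1, seed = 25)
  ft <- do.call(fit, c(list(dat$tree, dat$table, seed = 2, quiet = TRUE),
                       fast_fit_args))
  est <- mean_estimates(ft)
  expect_lt(abs(sum(est$Z0) - 1), 1e-8)
  expect_true(all(eigen(est$R, symmetric = TRUE,
                        only.values = TRUE)$values > 0))
  s <- ft$summary
  lam_row <- s[s$parameter == "lambda", ]
  expect_gte(est$lambda, lam_row$`q2.5`)
  expect_lte(est$lambda, lam_row$`q97.5`)
})

test_that("covariance significance matrix is symmetric with +1 diagonal", {
  dat <- sim_dataset(15, 3, 0.5, seed = 27)
  ft <- do.call(fit, c(list(dat$tree, dat$table, seed = 3, quiet = TRUE),
                       fast_fit_args))
  sig <- covariance_significance(ft)
  expect_identical(sig, t(sig))
  expect_true(all(diag(sig) == 1L))
  expect_true(all(sig %in% c(-1L, 0L, 1L)))
})

test_that("permutation p-values follow the add-one rule and reproduce", {
  dat <- sim_dataset(12, 3, 1, seed = 29)
  p1 <- do.call(lambda_permutation_test,
                c(list(tree = dat$tree, data = dat$table, n_perm = 5,
                       seed = 11), fast_fit_args))
  expect_equal(p1$p_value,
               (1 + sum(p1$null_lambdas >= p1$observed_lambda)) / 6)
  expect_length(p1$null_lambdas, 5)
  expect_gt(p1$p_value, 0)
  p2 <- do.call(lambda_permutation_test,
                c(list(tree = dat$tree, data = dat$table, n_perm = 5,
                       seed = 11), fast_fit_args))
  expect_identical(p1$null_lambdas, p2$null_lambdas)
})

test_that("a single shared group label degenerates to the full shuffle", {
  dat <- sim_dataset(12, 3, 1, seed = 33)
  free <- do.call(lambda_permutation_test,
                  c(list(tree = dat$tree, data = dat$table, n_perm = 4,
                         seed = 9), fast_fit_args))
  one_group <- do.call(lambda_permutation_test,
                       c(list(tree = dat$tree, data = dat$table, n_perm = 4,
                              seed = 9,
                              groups = rep("all", 12)), fast_fit_args))
  expect_identical(free$null_lambdas, one_group$null_lambdas)
})

test_that("degenerate trait groups are rejected or logged", {
  dat <- sim_dataset(6, 3, 1, seed = 35)
  singletons <- stats::setNames(letters[1:6], rownames(dat$table))
  expect_error(
    lambda_permutation_test(dat$tree, dat$table, n_perm = 2,
                            groups = singletons),
    "no permutation possible")
  mixed <- stats::setNames(c("a", "a", "a", "a", "b", "c"),
                           rownames(dat$table))
  expect_message(
    do.call(lambda_permutation_test,
            c(list(tree = dat$tree, data = dat$table, n_perm = 2, seed = 1,
                   groups = mixed), fast_fit_args)),
    "singleton")
})

test_that("constrained shuffles only exchange hosts within a group", {
  dat <- sim_dataset(10, 3, 1, seed = 37)
  hosts <- rownames(dat$table)
  groups <- stats::setNames(rep(c("g1", "g2"), each = 5), hosts)
  # run with a fit stub by exploiting determinism: check the permutation
  # machinery directly through reproducibility across group encodings
  a <- do.call(lambda_permutation_test,
               c(list(tree = dat$tree, data = dat$table, n_perm = 3,
                      seed = 2, groups = groups), fast_fit_args))
  b <- do.call(lambda_permutation_test,
               c(list(tree = dat$tree, data = dat$table, n_perm = 3,
                      seed = 2,
                      groups = data.frame(g = groups,
                                          row.names = hosts)),
                 fast_fit_args))
  expect_identical(a$null_lambdas, b$null_lambdas)
})

test_that("split-Rhat and ESS behave on well-mixed and stuck chains", {
  set.seed(1)
  good <- matrix(rnorm(4000), 1000, 4)
  expect_lt(split_rhat(good), 1.01)
  expect_gt(ess_basic(good), 2000)
  stuck <- cbind(rnorm(1000), rnorm(1000) + 6)
  expect_gt(split_rhat(stuck), 1.5)
  constant <- matrix(1, 100, 2)
  expect_equal(split_rhat(constant), 1)
})
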