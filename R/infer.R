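#' @useDynLib phylosym, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# ---- unconstrained parameterization -----------------------------------------
# sampled layout: [logit lambda, alr(Z0) (p-1), log sigma_y, vech(L) with
# log diag]; logYtilde is marginalised in the sampler and drawn from its
# exact Gaussian conditional per posterior draw

.pack_params <- function(lambda, Z0, R, mu_y = 0) {
  p <- length(Z0)
  a <- stats::qlogis(min(max(lambda, 1e-6), 1 - 1e-6))
  g <- log(Z0[-p]) - log(Z0[p])
  L <- t(chol(R))
  lvec <- numeric(p * (p + 1) / 2)
  k <- 1
  for (j in seq_len(p)) for (i in j:p) {
    lvec[k] <- if (i == j) log(L[i, j]) else L[i, j]
    k <- k + 1
  }
  c(a, g, mu_y, lvec)
}

.unpack_L <- function(lvec, p) {
  L <- matrix(0, p, p)
  k <- 1
  for (j in seq_len(p)) for (i in j:p) {
    L[i, j] <- if (i == j) exp(lvec[k]) else lvec[k]
    k <- k + 1
  }
  L
}

.unpack_params <- function(th, p) {
  a <- th[1]
  g <- th[seq_len(p - 1) + 1]
  mu_y <- th[p + 1]
  lvec <- th[(p + 2):length(th)]
  gfull <- c(g, 0)
  Z0 <- exp(gfull - max(gfull))
  Z0 <- Z0 / sum(Z0)
  L <- .unpack_L(lvec, p)
  list(lambda = stats::plogis(a), Z0 = Z0, mu_y = mu_y, R = L %*% t(L))
}

.default_prior <- function()
  list(sigma_y = 0.5, sd_loff = 2.5, sd_ldiag = 1.5)

# ---- fitting ----------------------------------------------------------------

#' Fit the compositional Brownian model by NUTS
#'
#' Samples the joint posterior of the phylogenetic signal `lambda`, the
#' ancestral composition `Z0`, the evolutionary variance-covariance matrix
#' `R` and the latent log total abundances `logYtilde`, using a No-U-Turn
#' Hamiltonian Monte Carlo sampler with dual-averaging step-size and
#' diagonal-metric adaptation. Because the latent `logYtilde` enters the
#' matrix-normal likelihood linearly with a Gaussian prior, it is
#' marginalised analytically inside the sampler (the collapsed posterior
#' over lambda, Z0, mu_logY and R is sampled) and then drawn from its exact
#' Gaussian conditional for every retained draw, so the returned draws
#' come from the full joint posterior. The tree is rescaled to unit depth
#' internally for numerical conditioning; `R` is reported back on the
#' original time scale (the scale factor is stored as `depth_scale`).
#'
#' Defaults follow the reference analysis: 4 chains of 4,000 iterations
#' including 2,000 warmup. A warning (never an error) is raised when any
#' split-Rhat exceeds 1.01, any ESS falls below 200, or post-warmup
#' divergences occur.
#'
#' @param tree Ultrametric host phylogeny (tips must cover `data` rows).
#' @param data Composition table (see [composition_table()]).
#' @param chains,iter,warmup Sampler settings (iter includes warmup).
#' @param seed Integer seed; chains use `seed`, `seed + 1`, ...
#' @param adapt_delta Target acceptance statistic (default 0.9).
#' @param max_treedepth Cap on NUTS doublings per iteration (default 10).
#' @param prior List with elements `sy_scale` (Gaussian sd of the log
#'   scale of the latent log totals: logYtilde ~ N(mu_y, sigma_y^2) with
#'   log(sigma_y) ~ N(0, sy_scale^2) and mu_y ~ N(0, 10) learned from the
#'   data), `sd_loff`
#'   and `sd_ldiag` (Gaussian sds of the off-diagonal and log-diagonal
#'   elements of the Cholesky factor of R, on the unit-depth tree).
#' @param quiet Suppress convergence warnings if `TRUE`.
#' @return An object of class `phylosym_fit`: posterior summary table
#'   (`$summary`: mean, q2.5, q97.5, rhat, ess per scalar), per-chain
#'   constrained draws (`$draws`), sampler diagnostics (`$diagnostics`),
#'   the aligned inputs and the depth scale factor.
#' @export
fit <- function(tree, data, chains = 4, iter = 4000, warmup = 2000,
                seed = 1, adapt_delta = 0.9, max_treedepth = 10,
                prior = .default_prior(), quiet = FALSE) {
  data <- as.matrix(data)
  if (nrow(data) < 2 || ncol(data) < 2)
    stop("fit needs at least 2 hosts and 2 taxa", call. = FALSE)
  if (!setequal(rownames(data), tree$tip.label))
    stop("tree tips and data rows differ; use align() first", call. = FALSE)
  if (warmup >= iter) stop("iter must exceed warmup", call. = FALSE)
  data <- data[tree$tip.label, , drop = FALSE]
  n <- nrow(data); p <- ncol(data)

  depth_scale <- tree_depth(tree)
  ntree <- tree
  ntree$edge.length <- ntree$edge.length / depth_scale
  C <- phylo_covariance(ntree)
  eig <- eigen(C, symmetric = TRUE)
  Tdepth <- max(diag(C))
  logZ <- log(data)

  # data-informed initial values, jittered per chain
  Z0_init <- colMeans(data); Z0_init <- Z0_init / sum(Z0_init)
  R_init <- stats::cov(logZ) + diag(0.05, p)
  base_init <- .pack_params(0.5, Z0_init, R_init)

  chain_out <- vector("list", chains)
  for (ch in seq_len(chains)) {
    set.seed(seed + ch - 1)
    init <- base_init + stats::rnorm(length(base_init), 0, 0.05)
    chain_out[[ch]] <- .psym_nuts(logZ, eig$vectors, pmax(eig$values, 0),
                                  Tdepth, init, as.integer(iter),
                                  as.integer(warmup), adapt_delta,
                                  as.integer(max_treedepth),
                                  prior$sigma_y,
                                  prior$sd_loff, prior$sd_ldiag,
                                  as.double(seed) * 1000 + ch)
    chain_out[[ch]]$logy <- .psym_sample_logy(chain_out[[ch]]$draws, logZ,
                                              eig$vectors,
                                              pmax(eig$values, 0), Tdepth,
                                              prior$sigma_y,
                                              as.double(seed) * 1000 + ch + 500000)
  }

  par_names <- c("lambda",
                 paste0("Z0[", colnames(data), "]"),
                 "mu_logY",
                 paste0("R[", rep(colnames(data), times = p), ",",
                        rep(colnames(data), each = p), "]")[
                          as.vector(upper.tri(diag(p), diag = TRUE))],
                 paste0("logYtilde[", rownames(data), "]"))
  ut <- upper.tri(diag(p), diag = TRUE)
  draws <- lapply(chain_out, function(co) {
    m <- co$draws
    out <- matrix(NA_real_, nrow(m), length(par_names),
                  dimnames = list(NULL, par_names))
    for (i in seq_len(nrow(m))) {
      pr <- .unpack_params(m[i, ], p)
      out[i, ] <- c(pr$lambda, pr$Z0, pr$mu_y,
                    (pr$R / depth_scale)[ut], co$logy[i, ])
    }
    out
  })

  summ <- .posterior_summary(draws)
  diagnostics <- list(
    n_divergent = sum(vapply(chain_out, `[[`, 0, "n_divergent")),
    n_max_treedepth = sum(vapply(chain_out, `[[`, 0, "n_max_treedepth")),
    stepsize = vapply(chain_out, `[[`, 0, "stepsize"),
    mean_accept = vapply(chain_out, `[[`, 0, "mean_accept"))

  out <- structure(list(
    summary = summ, draws = draws, diagnostics = diagnostics,
    tree = tree, data = data, depth_scale = depth_scale,
    taxon_ids = colnames(data), host_ids = rownames(data),
    config = list(chains = chains, iter = iter, warmup = warmup,
                  seed = seed, adapt_delta = adapt_delta,
                  max_treedepth = max_treedepth, prior = prior)),
    class = "phylosym_fit")

  if (!quiet) {
    n_kept <- (iter - warmup) * chains
    if (diagnostics$n_divergent > 0)
      warning(sprintf("%d divergent transitions after warmup (of %d draws)",
                      diagnostics$n_divergent, n_kept), call. = FALSE)
    bad_rhat <- summ$rhat > 1.01 & is.finite(summ$rhat)
    if (any(bad_rhat))
      warning(sprintf("%d parameters with split-Rhat > 1.01 (max %.3f)",
                      sum(bad_rhat), max(summ$rhat, na.rm = TRUE)),
              call. = FALSE)
    low_ess <- summ$ess < 200 & is.finite(summ$ess)
    if (any(low_ess))
      warning(sprintf("%d parameters with ESS < 200 (min %.0f)",
                      sum(low_ess), min(summ$ess, na.rm = TRUE)),
              call. = FALSE)
  }
  out
}

#' @export
print.phylosym_fit <- function(x, ...) {
  cat(sprintf("Compositional Brownian model fit: %d hosts, %d taxa\n",
              length(x$host_ids), length(x$taxon_ids)))
  cat(sprintf("%d chains x %d iterations (%d warmup); %d divergences\n",
              x$config$chains, x$config$iter, x$config$warmup,
              x$diagnostics$n_divergent))
  show <- x$summary[!grepl("^logYtilde", x$summary$parameter), ]
  print(utils::head(show, 25), row.names = FALSE, digits = 3)
  if (nrow(show) > 25) cat("...", nrow(x$summary), "parameters total\n")
  invisible(x)
}

.posterior_summary <- function(draws) {
  par_names <- colnames(draws[[1]])
  arr <- simplify2array(lapply(draws, identity))  # iter x par x chain
  summ <- data.frame(parameter = par_names,
                     mean = NA_real_, q2.5 = NA_real_, q97.5 = NA_real_,
                     rhat = NA_real_, ess = NA_real_,
                     stringsAsFactors = FALSE, check.names = FALSE)
  for (j in seq_along(par_names)) {
    m <- arr[, j, , drop = TRUE]
    if (is.null(dim(m))) m <- matrix(m, ncol = 1)
    v <- as.vector(m)
    summ$mean[j] <- mean(v)
    qs <- stats::quantile(v, c(0.025, 0.975), names = FALSE)
    summ$`q2.5`[j] <- qs[1]
    summ$`q97.5`[j] <- qs[2]
    summ$rhat[j] <- split_rhat(m)
    summ$ess[j] <- ess_basic(m)
  }
  summ
}

#' Posterior mean point estimates
#'
#' Extracts posterior means as a [model_params()] bundle: `Z0` is
#' renormalized to the simplex; if the element-wise mean of `R` is not
#' positive definite it is projected to the nearest SPD matrix by
#' eigenvalue clipping (with a message).
#'
#' @param post A `phylosym_fit`.
#' @return A `phylosym_params` list (lambda, Z0, R, logYtilde).
#' @export
mean_estimates <- function(post) {
  stopifnot(inherits(post, "phylosym_fit"))
  mu <- post$summary$mean
  names(mu) <- post$summary$parameter
  p <- length(post$taxon_ids); n <- length(post$host_ids)
  lambda <- unname(mu["lambda"])
  Z0 <- unname(mu[paste0("Z0[", post$taxon_ids, "]")])
  Z0 <- Z0 / sum(Z0)
  R <- matrix(0, p, p, dimnames = list(post$taxon_ids, post$taxon_ids))
  ut <- upper.tri(R, diag = TRUE)
  rn <- paste0("R[", rep(post$taxon_ids, times = p), ",",
               rep(post$taxon_ids, each = p), "]")[as.vector(ut)]
  R[ut] <- unname(mu[rn])
  R <- R + t(R) - diag(diag(R))
  ev <- eigen(R, symmetric = TRUE)
  if (min(ev$values) <= 0) {
    message("posterior-mean R was indefinite; projected to the nearest SPD matrix")
    vals <- pmax(ev$values, 1e-8 * max(ev$values))
    R <- ev$vectors %*% diag(vals, p) %*% t(ev$vectors)
    dimnames(R) <- list(post$taxon_ids, post$taxon_ids)
  }
  logY <- unname(mu[paste0("logYtilde[", post$host_ids, "]")])
  model_params(min(max(lambda, 0), 1), Z0, R, logY)
}

#' Significance of evolutionary covariances
#'
#' A covariance is called significant when 0 lies outside its 95%
#' (or `level`) credible interval: +1 if the interval is entirely
#' positive, -1 if entirely negative, 0 otherwise. Diagonal entries
#' (variances) are +1 by construction.
#'
#' @param post A `phylosym_fit`.
#' @param level Credible level (default 0.95).
#' @return p x p integer sign matrix with taxon dimnames.
#' @export
covariance_significance <- function(post, level = 0.95) {
  stopifnot(inherits(post, "phylosym_fit"))
  taxa <- post$taxon_ids
  p <- length(taxa)
  alpha <- (1 - level) / 2
  all_draws <- do.call(rbind, post$draws)
  sig <- matrix(0L, p, p, dimnames = list(taxa, taxa))
  for (j in seq_len(p)) for (k in j:p) {
    nm <- paste0("R[", taxa[j], ",", taxa[k], "]")
    v <- all_draws[, nm]
    qs <- stats::quantile(v, c(alpha, 1 - alpha), names = FALSE)
    s <- if (qs[1] > 0) 1L else if (qs[2] < 0) -1L else 0L
    sig[j, k] <- sig[k, j] <- s
  }
  diag(sig) <- 1L
  sig
}

# ---- permutation test -------------------------------------------------------

#' Permutation test for the significance of phylosymbiosis
#'
#' Shuffles which host species carries which microbiota (breaking the
#' phylogenetic structure), refits the model on each shuffled table, and
#' compares the observed posterior-mean lambda with the null distribution.
#' With `groups` given, shuffling only exchanges hosts sharing the same
#' label (for several traits, the same label tuple), testing whether the
#' conservatism of those traits explains the signal. The p-value uses the
#' add-one rule `(1 + #{null >= observed}) / (1 + n_perm)` and is declared
#' significant at 0.05 when the observed lambda exceeds at least 95% of
#' the null values.
#'
#' @inheritParams fit
#' @param n_perm Number of permutations (reference analysis: 100).
#' @param groups Optional per-host labels (named by host, or in data row
#'   order); a data.frame of several trait columns is combined into label
#'   tuples.
#' @param observed_fit Optional precomputed `phylosym_fit` on the
#'   unpermuted data (to avoid refitting).
#' @param ... Passed on to [fit()] (e.g. `chains`, `iter`, `warmup`).
#' @return A list of class `phylosym_perm`: `observed_lambda`,
#'   `null_lambdas`, `p_value`, `significant`, `constraint`.
#' @export
lambda_permutation_test <- function(tree, data, n_perm = 100, groups = NULL,
                                    seed = 1, observed_fit = NULL, ...) {
  data <- as.matrix(data)
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  data <- data[tree$tip.label, , drop = FALSE]
  n <- nrow(data)

  if (is.null(groups)) {
    glab <- rep("all", n)
  } else {
    if (is.data.frame(groups) || is.matrix(groups)) {
      gdf <- as.data.frame(groups)
      if (!is.null(rownames(groups)) &&
          all(rownames(data) %in% rownames(groups)))
        gdf <- gdf[rownames(data), , drop = FALSE]
      glab <- do.call(paste, c(gdf, sep = "\r"))
    } else {
      glab <- as.character(groups)
      if (!is.null(names(groups))) {
        if (!all(rownames(data) %in% names(groups)))
          stop("groups is missing labels for some hosts", call. = FALSE)
        glab <- as.character(groups[rownames(data)])
      }
    }
    if (length(glab) != n)
      stop("groups must supply one label per host", call. = FALSE)
  }
  gsplit <- split(seq_len(n), glab)
  if (all(lengths(gsplit) == 1L))
    stop("no permutation possible: every trait group has a single host",
         call. = FALSE)
  singletons <- names(gsplit)[lengths(gsplit) == 1L]
  if (length(singletons) > 0)
    message(length(singletons),
            " singleton group(s) contribute no exchange: ",
            paste(utils::head(singletons, 5), collapse = ", "))

  if (is.null(observed_fit))
    observed_fit <- fit(tree, data, seed = seed, quiet = TRUE, ...)
  observed_lambda <- observed_fit$summary$mean[
    observed_fit$summary$parameter == "lambda"]

  null_lambdas <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    set.seed(seed * 100000 + b)
    perm <- seq_len(n)
    for (idx in gsplit)
      if (length(idx) > 1) perm[idx] <- idx[sample.int(length(idx))]
    pdata <- data
    rownames(pdata) <- rownames(data)[perm]
    pdata <- pdata[rownames(data), , drop = FALSE]
    pfit <- fit(tree, pdata, seed = seed, quiet = TRUE, ...)
    null_lambdas[b] <- pfit$summary$mean[pfit$summary$parameter == "lambda"]
  }
  p_value <- (1 + sum(null_lambdas >= observed_lambda)) / (1 + n_perm)
  structure(list(observed_lambda = observed_lambda,
                 null_lambdas = null_lambdas,
                 p_value = p_value,
                 significant = p_value <= 0.05,
                 constraint = if (is.null(groups)) "none" else "trait-groups",
                 n_perm = n_perm),
            class = "phylosym_perm")
}

#' @export
print.phylosym_perm <- function(x, ...) {
  cat(sprintf(
    "Permutation test for phylosymbiosis (%s constraint)\n  observed lambda = %.3f, %d permutations, p = %.4f (%s)\n",
    x$constraint, x$observed_lambda, x$n_perm, x$p_value,
    if (x$significant) "significant at 0.05" else "not significant"))
  invisible(x)
}
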