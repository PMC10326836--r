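#' Split-chain Gelman-Rubin statistic
#'
#' Each chain is split in half before computing the classic potential
#' scale reduction factor, so within-chain drift also inflates the
#' statistic. Values near 1 indicate convergence.
#'
#' @param m Matrix of draws, iterations x chains (a vector is treated as
#'   one chain).
#' @return The split-Rhat (NA for fewer than 4 usable draws, 1 for a
#'   constant quantity).
#' @export
split_rhat <- function(m) {
  m <- as.matrix(m)
  half <- floor(nrow(m) / 2)
  if (half < 2) return(NA_real_)
  sm <- cbind(m[seq_len(half), , drop = FALSE],
              m[half + seq_len(half), , drop = FALSE])
  means <- colMeans(sm)
  vars <- apply(sm, 2, stats::var)
  W <- mean(vars)
  B <- half * stats::var(means)
  if (W == 0) return(1)
  sqrt(((half - 1) / half * W + B / half) / W)
}

#' Effective sample size of MCMC draws
#'
#' Multi-chain ESS using chain-averaged autocovariances and Geyer's
#' initial monotone positive sequence to truncate the autocorrelation sum.
#'
#' @inheritParams split_rhat
#' @return Estimated ESS (capped at the total draw count; NA if too few
#'   draws).
#' @export
ess_basic <- function(m) {
  m <- as.matrix(m)
  n <- nrow(m); nchain <- ncol(m)
  if (n < 4) return(NA_real_)
  max_lag <- n - 1
  acov <- sapply(seq_len(nchain), function(ch) {
    a <- stats::acf(m[, ch], lag.max = max_lag, type = "covariance",
                    plot = FALSE, demean = TRUE)$acf[, 1, 1]
    a * (n - 1) / n
  })
  acov <- matrix(acov, nrow = max_lag + 1)
  mean_var <- mean(acov[1, ]) * n / (n - 1)
  chain_means <- colMeans(m)
  var_plus <- mean_var * (n - 1) / n
  if (nchain > 1) var_plus <- var_plus + stats::var(chain_means)
  if (var_plus == 0) return(n * nchain)
  rho <- 1 - (mean_var - rowMeans(acov)) / var_plus
  # Geyer: sum consecutive pairs while positive, enforce monotone decrease
  max_pairs <- floor((length(rho) - 1) / 2)
  pair_sums <- numeric(0)
  for (k in seq_len(max_pairs)) {
    ps <- rho[2 * k] + rho[2 * k + 1]
    if (ps <= 0) break
    pair_sums <- c(pair_sums, ps)
  }
  if (length(pair_sums) > 1) pair_sums <- cummin(pair_sums)
  tau <- 1 + 2 * sum(pair_sums)
  tau <- max(tau, 1 / log10(n * nchain + 10))
  min(n * nchain / tau, n * nchain)
}
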