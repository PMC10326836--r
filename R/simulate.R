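#' Random symmetric positive definite rate matrix
#'
#' Builds R = Q diag(e) Q' with Q a Haar-random orthogonal matrix composed
#' with a random diagonal sign flip. With the default equal spectrum every
#' eigenvalue is exactly `eigenvalue` (so R is `eigenvalue * I`); the
#' `"varied"` spectrum draws log-normal eigenvalues rescaled to mean
#' `eigenvalue`, which produces nonzero off-diagonal covariances and is
#' used for covariance-recovery checks.
#'
#' @param p Number of taxa (>= 1).
#' @param eigenvalue Target eigenvalue (equal spectrum) or mean eigenvalue
#'   (varied spectrum); default 1/4.
#' @param seed Integer seed.
#' @param spectrum `"equal"` (default) or `"varied"`.
#' @return p x p symmetric positive definite matrix.
#' @export
random_spd <- function(p, eigenvalue = 0.25, seed = 1,
                       spectrum = c("equal", "varied")) {
  spectrum <- match.arg(spectrum)
  if (p < 1) stop("p must be >= 1", call. = FALSE)
  if (eigenvalue <= 0) stop("eigenvalue must be > 0", call. = FALSE)
  set.seed(seed)
  qr_ <- qr(matrix(stats::rnorm(p * p), p, p))
  Q <- qr.Q(qr_) %*% diag(sign(diag(qr.R(qr_))), p)
  Q <- Q %*% diag(sample(c(-1, 1), p, replace = TRUE), p)
  e <- switch(spectrum,
              equal = rep(eigenvalue, p),
              varied = {
                v <- stats::rlnorm(p, 0, 0.6)
                v * eigenvalue / mean(v)
              })
  R <- Q %*% diag(e, p) %*% t(Q)
  (R + t(R)) / 2
}

#' Sample an ancestral composition
#'
#' Draws log root abundances uniformly on \code{[-4, 0]} and normalizes to
#' the simplex, the root-state distribution of the simulation design.
#'
#' @param p Number of taxa.
#' @param seed Integer seed.
#' @return Simplex p-vector.
#' @export
sample_root <- function(p, seed = 1) {
  if (p < 1) stop("p must be >= 1", call. = FALSE)
  set.seed(seed)
  u <- stats::runif(p, -4, 0)
  z <- exp(u)
  z / sum(z)
}

#' Simulate microbiota evolution along a host phylogeny
#'
#' Evolves log absolute abundances branchwise on the lambda-transformed
#' tree: the root state is `log(Z0)` and each child node adds a
#' MVN(0, t * R) increment over a branch of length t. Tip compositions are
#' the row-normalized exponentials; the latent truth (lambda, Z0, R, the
#' per-tip log totals logYtilde and all internal-node log-abundance
#' states) is returned alongside for recovery tests.
#'
#' @param tree Ultrametric host phylogeny.
#' @param params A [model_params()] bundle (logYtilde ignored; R = 0 is
#'   allowed here and yields noise-free tips).
#' @param seed Integer seed.
#' @param floor Optional detection floor: tip entries below it are raised
#'   to the floor and rows renormalized (off by default).
#' @return List with `table` (composition matrix, rows in tip order) and
#'   `truth` (lambda, Z0, R, logYtilde, node_states, tip_logX).
#' @export
simulate_microbiota <- function(tree, params, seed = 1, floor = NULL) {
  p <- length(params$Z0)
  n <- length(tree$tip.label)
  ttree <- lambda_transform(tree, params$lambda)
  set.seed(seed)
  CR <- if (all(params$R == 0)) matrix(0, p, p) else t(chol(params$R))
  n_node <- n + tree$Nnode
  states <- matrix(NA_real_, n_node, p)
  root <- n + 1L
  states[root, ] <- log(params$Z0)
  # pre-order traversal: ape cladewise edge order lists parents before children
  eo <- ape::reorder.phylo(ttree, "cladewise")
  for (k in seq_len(nrow(eo$edge))) {
    par <- eo$edge[k, 1]; child <- eo$edge[k, 2]
    t_br <- eo$edge.length[k]
    states[child, ] <- states[par, ] +
      sqrt(t_br) * as.vector(CR %*% stats::rnorm(p))
  }
  tip_logX <- states[seq_len(n), , drop = FALSE]
  rownames(tip_logX) <- tree$tip.label
  colnames(tip_logX) <- names(params$Z0) %||% paste0("taxon", seq_len(p))
  X <- exp(tip_logX)
  Z <- X / rowSums(X)
  logYtilde <- log(rowSums(X))  # Y0 = sum(Z0) = 1 by convention
  if (!is.null(floor)) {
    Z[Z < floor] <- floor
    Z <- Z / rowSums(Z)
  }
  node_states <- states[(n + 1L):n_node, , drop = FALSE]
  rownames(node_states) <- as.character((n + 1L):n_node)
  list(table = Z,
       truth = list(lambda = params$lambda, Z0 = params$Z0, R = params$R,
                    logYtilde = logYtilde, node_states = node_states,
                    tip_logX = tip_logX))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a simulation grid
#'
#' Factorial simulation study over tree sizes, taxon counts and lambda
#' values. Each replicate draws a pure-birth tree, a root composition, a
#' random SPD rate matrix and a simulated composition table, written as
#' plain-text files (`tree.nwk`, `z.tsv`, `truth.json`) in its own folder,
#' with a JSON manifest listing every cell. The defaults reproduce the
#' reference design (4 x 4 x 5 cells x 100 replicates = 8,000 datasets);
#' `n_reps` shrinks it for desk-scale runs.
#'
#' @param out_dir Output directory (created if missing).
#' @param n_values,p_values,lambda_values Grid axes.
#' @param n_reps Replicates per cell (reference design: 100).
#' @param seed Integer seed; per-replicate seeds are drawn from it.
#' @param eigenvalue Eigenvalue of the simulated R (default 1/4).
#' @param spectrum Passed to [random_spd()].
#' @return The manifest (invisibly), also written to
#'   `out_dir/manifest.json`.
#' @export
run_grid <- function(out_dir,
                     n_values = c(20, 50, 100, 250),
                     p_values = c(3, 5, 10, 15),
                     lambda_values = c(1, 0.75, 0.5, 0.25, 0),
                     n_reps = 100, seed = 1, eigenvalue = 0.25,
                     spectrum = "equal") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cells <- expand.grid(n = n_values, p = p_values, lambda = lambda_values,
                       rep = seq_len(n_reps), KEEP.OUT.ATTRS = FALSE)
  set.seed(seed)
  cells$seed <- sample.int(.Machine$integer.max - 1, nrow(cells))
  cells$dir <- sprintf("n%d_p%d_lam%s_rep%d", cells$n, cells$p,
                       gsub("\\.", "", format(cells$lambda)), cells$rep)
  for (i in seq_len(nrow(cells))) {
    d <- file.path(out_dir, cells$dir[i])
    dir.create(d, showWarnings = FALSE)
    s <- cells$seed[i]
    tree <- simulate_pure_birth(cells$n[i], seed = s)
    Z0 <- sample_root(cells$p[i], seed = s + 1)
    R <- random_spd(cells$p[i], eigenvalue = eigenvalue, seed = s + 2,
                    spectrum = spectrum)
    sim <- simulate_microbiota(tree,
                               model_params(cells$lambda[i], Z0, R),
                               seed = s + 3)
    write_newick(tree, file.path(d, "tree.nwk"))
    write_composition(sim$table, file.path(d, "z.tsv"))
    jsonlite::write_json(
      list(lambda = cells$lambda[i], Z0 = Z0, R = R,
           logYtilde = sim$truth$logYtilde,
           node_states = sim$truth$node_states, seed = s),
      file.path(d, "truth.json"), digits = NA, matrix = "rowmajor")
  }
  manifest <- list(grid = list(n = n_values, p = p_values,
                               lambda = lambda_values, n_reps = n_reps),
                   seed = seed, n_datasets = nrow(cells),
                   datasets = cells[, c("dir", "n", "p", "lambda", "rep",
                                        "seed")])
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(manifest)
}
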