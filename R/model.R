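#' Construct and validate a composition table
#'
#' A composition table is an n x p numeric matrix of relative abundances:
#' one row per host species (rownames = host ids), one column per microbial
#' taxon (colnames = taxon ids). Every row must lie on the simplex (sum to 1
#' within `1e-8`) and every entry must be at least the detection floor, so
#' no exact zeros enter the log-scale model.
#'
#' @param values Numeric matrix (or data.frame) of relative abundances.
#' @param host_ids Optional row labels (defaults to rownames).
#' @param taxon_ids Optional column labels (defaults to colnames).
#' @param floor Minimum admissible entry (default `1e-5`, i.e. 0.001%).
#' @return A validated numeric matrix with dimnames.
#' @export
composition_table <- function(values, host_ids = rownames(values),
                              taxon_ids = colnames(values), floor = 1e-5) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(host_ids) || is.null(taxon_ids))
    stop("composition table needs host (row) and taxon (column) labels",
         call. = FALSE)
  rownames(values) <- as.character(host_ids)
  colnames(values) <- as.character(taxon_ids)
  if (anyDuplicated(rownames(values)))
    stop("duplicated host ids", call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicated taxon ids", call. = FALSE)
  if (anyNA(values)) stop("composition table contains NA", call. = FALSE)
  rs <- rowSums(values)
  if (any(abs(rs - 1) > 1e-8))
    stop("composition rows must sum to 1 (max deviation ",
         format(max(abs(rs - 1))), ")", call. = FALSE)
  if (any(values < floor - 1e-12))
    stop("composition entries below the detection floor ", floor,
         "; apply the floor step (see prepare_table) first", call. = FALSE)
  values
}

#' Reassemble latent log absolute abundances
#'
#' The model observes relative abundances Z and treats each host's total
#' abundance (relative to the root's) as a latent variable logYtilde. The
#' latent log absolute abundance matrix is
#' \code{logX[i, j] = log(Z[i, j]) + logYtilde[i]}.
#'
#' @param data Composition table (n x p).
#' @param logYtilde Numeric n-vector of latent log relative total abundances.
#' @return n x p matrix of latent log abundances.
#' @export
assemble_latent_logX <- function(data, logYtilde) {
  data <- as.matrix(data)
  if (length(logYtilde) != nrow(data))
    stop("logYtilde must have one entry per host row", call. = FALSE)
  log(data) + matrix(logYtilde, nrow(data), ncol(data))
}

#' Model parameter bundle
#'
#' @param lambda Phylogenetic signal in \code{[0, 1]}.
#' @param Z0 Ancestral composition (simplex p-vector).
#' @param R p x p symmetric positive definite evolutionary
#'   variance-covariance matrix (per unit branch length).
#' @param logYtilde n-vector of latent log relative total abundances
#'   (may be omitted for simulation, where it is an output).
#' @return A list of class `phylosym_params`.
#' @export
model_params <- function(lambda, Z0, R, logYtilde = NULL) {
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0 || lambda > 1)
    stop("lambda must be in [0, 1]", call. = FALSE)
  Z0 <- as.numeric(Z0)
  if (abs(sum(Z0) - 1) > 1e-8 || any(Z0 <= 0))
    stop("Z0 must be a strictly positive simplex vector", call. = FALSE)
  R <- as.matrix(R)
  if (nrow(R) != ncol(R) || nrow(R) != length(Z0))
    stop("R must be p x p with p = length(Z0)", call. = FALSE)
  if (max(abs(R - t(R))) > 1e-8) stop("R must be symmetric", call. = FALSE)
  ch <- tryCatch(chol(R), error = function(e) NULL)
  if (is.null(ch) && !all(R == 0))
    stop("R must be positive definite (Cholesky failed)", call. = FALSE)
  structure(list(lambda = lambda, Z0 = Z0, R = R, logYtilde = logYtilde),
            class = "phylosym_params")
}

#' Log-likelihood of the compositional Brownian model
#'
#' The latent log abundances logX (rows = hosts, columns = taxa) follow a
#' matrix-normal distribution: mean row `log(Z0)` for every host and
#' covariance \code{C \%x\% R}, where C is the phylogenetic covariance of the
#' lambda-transformed tree and R the between-taxon evolutionary
#' variance-covariance matrix.
#'
#' @param params A [model_params()] bundle with `logYtilde` set.
#' @param data Composition table; rows must be labelled by tree tips.
#' @param tree Ultrametric host phylogeny covering all data rows.
#' @return The log-density (a single finite number for valid inputs).
#' @export
log_likelihood <- function(params, data, tree) {
  data <- as.matrix(data)
  if (!all(rownames(data) %in% tree$tip.label))
    stop("data rows not found in tree: ",
         paste(setdiff(rownames(data), tree$tip.label), collapse = ", "),
         call. = FALSE)
  if (length(tree$tip.label) != nrow(data))
    stop("tree has tips without data rows; prune with align() first",
         call. = FALSE)
  data <- data[tree$tip.label, , drop = FALSE]
  n <- nrow(data); p <- ncol(data)
  if (length(params$Z0) != p)
    stop("length(Z0) must match the number of taxa", call. = FALSE)
  if (is.null(params$logYtilde) || length(params$logYtilde) != n)
    stop("params$logYtilde must hold one latent value per host", call. = FALSE)
  C <- phylo_covariance(lambda_transform(tree, params$lambda))
  X <- assemble_latent_logX(data, params$logYtilde)
  E <- X - matrix(log(params$Z0), n, p, byrow = TRUE)
  matrix_normal_logdens(E, C, params$R)
}

# log-density at E = X - M of the matrix normal MN(0, C, R), i.e. the
# np-dimensional MVN with covariance C (x) R, via Cholesky factors of C and R
matrix_normal_logdens <- function(E, C, R) {
  n <- nrow(E); p <- ncol(E)
  LC <- tryCatch(chol(C), error = function(e)
    stop("phylogenetic covariance C is not positive definite", call. = FALSE))
  LR <- tryCatch(chol(R), error = function(e)
    stop("R is not positive definite", call. = FALSE))
  logdetC <- 2 * sum(log(diag(LC)))
  logdetR <- 2 * sum(log(diag(LR)))
  # tr(R^-1 E' C^-1 E) = || LC^-T E LR^-1 ||_F^2
  A <- backsolve(LC, E, transpose = TRUE)      # LC' \ E
  B <- t(backsolve(LR, t(A), transpose = TRUE))
  quad <- sum(B * B)
  -0.5 * n * p * log(2 * pi) - 0.5 * p * logdetC - 0.5 * n * logdetR -
    0.5 * quad
}
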