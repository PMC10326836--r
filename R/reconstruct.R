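# shared-path covariance between every pair of nodes (tips + internal) of a
# tree: cov(x, y) = (depth_x + depth_y - d(x, y)) / 2
.node_covariance <- function(tree) {
  dn <- ape::dist.nodes(tree)
  root <- length(tree$tip.label) + 1L
  depths <- dn[root, ]
  (outer(depths, depths, "+") - dn) / 2
}

#' Ancestral microbiota composition by generalized least squares
#'
#' Conditional on the fitted parameters, internal-node log abundances are
#' the Brownian conditional expectations on the lambda-transformed tree:
#' for each taxon, `logZ0 + V_nt V_tt^-1 (tip_logX - logZ0)`, where the V
#' blocks are shared-path covariances between internal nodes and tips.
#' Node compositions are the row-normalized exponentials of these
#' estimates; the root row equals the supplied `Z0` exactly.
#'
#' @param tree Ultrametric host phylogeny (n tips).
#' @param lam Phylogenetic signal used for the transform (typically the
#'   posterior mean).
#' @param tip_logX n x p matrix of latent log abundances at the tips
#'   (from [assemble_latent_logX()] with the posterior-mean logYtilde),
#'   rows named by tips.
#' @param logZ0 p-vector of log ancestral abundances (log of the
#'   posterior-mean Z0).
#' @param jitter If `TRUE`, add 1e-10 to the diagonal of the tip block
#'   when it is numerically singular.
#' @return List of class `phylosym_ancestral`: `node_ids` (root first),
#'   `log_abundance_states` ((n-1) x p GLS estimates), `compositions`
#'   ((n-1) x p simplex rows), `node_ages` (time before present).
#' @export
gls_ancestral <- function(tree, lam, tip_logX, logZ0, jitter = FALSE) {
  n <- length(tree$tip.label)
  p <- length(logZ0)
  tip_logX <- as.matrix(tip_logX)
  if (nrow(tip_logX) != n || ncol(tip_logX) != p)
    stop("tip_logX must be n x p with n = number of tips", call. = FALSE)
  if (!is.null(rownames(tip_logX)))
    tip_logX <- tip_logX[tree$tip.label, , drop = FALSE]

  ttree <- lambda_transform(tree, lam)
  V <- .node_covariance(ttree)
  tips <- seq_len(n)
  nodes <- (n + 1L):(n + tree$Nnode)
  Vtt <- V[tips, tips, drop = FALSE]
  Vnt <- V[nodes, tips, drop = FALSE]
  ch <- tryCatch(chol(Vtt), error = function(e) NULL)
  if (is.null(ch)) {
    if (!jitter)
      stop("tip covariance block is singular; retry with jitter = TRUE ",
           "(adds 1e-10 to the diagonal)", call. = FALSE)
    ch <- chol(Vtt + diag(1e-10, n))
  }
  centred <- tip_logX - matrix(logZ0, n, p, byrow = TRUE)
  W <- backsolve(ch, backsolve(ch, centred, transpose = TRUE))
  est <- matrix(logZ0, length(nodes), p, byrow = TRUE) + Vnt %*% W

  node_ids <- if (!is.null(tree$node.label) &&
                  length(tree$node.label) == tree$Nnode &&
                  !anyDuplicated(tree$node.label) &&
                  all(nzchar(tree$node.label)))
    tree$node.label else paste0("node", nodes)
  rownames(est) <- node_ids
  colnames(est) <- colnames(tip_logX)

  comp <- exp(est - apply(est, 1, max))
  comp <- comp / rowSums(comp)
  # the root has zero variance: pin it to Z0 exactly
  Z0 <- exp(logZ0); Z0 <- Z0 / sum(Z0)
  comp[1, ] <- Z0
  est[1, ] <- logZ0

  depth <- tree_depth(tree)
  node_depths <- ape::node.depth.edgelength(tree)[nodes]
  structure(list(node_ids = node_ids,
                 log_abundance_states = est,
                 compositions = comp,
                 node_ages = depth - node_depths,
                 node_numbers = nodes),
            class = "phylosym_ancestral")
}

#' Report large composition shifts along edges
#'
#' Lists tree edges on which any taxon's reconstructed relative abundance
#' changes by more than `threshold` (absolute difference) between parent
#' and child node, sorted by decreasing |delta|. Edges ending in tips are
#' included when `tip_compositions` is supplied (rows named by tips).
#'
#' @param anc A `phylosym_ancestral` object.
#' @param tree The phylogeny used for the reconstruction.
#' @param threshold Absolute composition change to report (default 0.10).
#' @param tip_compositions Optional n x p composition table for the tips.
#' @return data.frame with columns parent, child, taxon, delta.
#' @export
shift_report <- function(anc, tree, threshold = 0.10,
                         tip_compositions = NULL) {
  n <- length(tree$tip.label)
  comp_of <- function(node) {
    if (node > n) return(anc$compositions[match(node, anc$node_numbers), ])
    if (is.null(tip_compositions)) return(NULL)
    tip_compositions[tree$tip.label[node], ]
  }
  rows <- list()
  for (k in seq_len(nrow(tree$edge))) {
    par <- tree$edge[k, 1]; child <- tree$edge[k, 2]
    pc <- comp_of(par); cc <- comp_of(child)
    if (is.null(pc) || is.null(cc)) next
    delta <- as.numeric(cc) - as.numeric(pc)
    hit <- which(abs(delta) > threshold)
    for (j in hit) {
      rows[[length(rows) + 1L]] <- data.frame(
        parent = if (par > n) anc$node_ids[match(par, anc$node_numbers)]
                 else tree$tip.label[par],
        child = if (child > n) anc$node_ids[match(child, anc$node_numbers)]
                else tree$tip.label[child],
        taxon = colnames(anc$compositions)[j] %||% paste0("taxon", j),
        delta = delta[j], stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0)
    return(data.frame(parent = character(0), child = character(0),
                      taxon = character(0), delta = numeric(0)))
  out <- do.call(rbind, rows)
  out[order(-abs(out$delta)), , drop = FALSE]
}
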