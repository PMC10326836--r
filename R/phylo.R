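#' Read and validate a host phylogeny from a Newick file
#'
#' Reads a rooted, ultrametric, strictly bifurcating time-tree, the form of
#' host phylogeny the Brownian model assumes. Validation failures are
#' collected and reported together.
#'
#' @param path Path to a Newick file with branch lengths on all edges.
#' @param resolve_polytomies If `TRUE`, polytomies are resolved into
#'   zero-length bifurcations (`ape::multi2di`); by default they are
#'   rejected.
#' @param check_ultrametric If `FALSE`, skip the ultrametricity check
#'   (the model itself still assumes an ultrametric tree).
#' @param tol Relative tolerance (fraction of tree depth) for the
#'   ultrametricity check.
#' @return An `ape` \code{phylo} object passing [validate_phylogeny()].
#' @export
read_newick <- function(path, resolve_polytomies = FALSE,
                        check_ultrametric = TRUE, tol = 1e-6) {
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("Newick parse error: ",
                                            conditionMessage(e), call. = FALSE))
  if (is.null(tree)) stop("Newick parse error: no tree found in ", path,
                          call. = FALSE)
  if (inherits(tree, "multiPhylo")) tree <- tree[[1L]]
  validate_phylogeny(tree, resolve_polytomies = resolve_polytomies,
                     check_ultrametric = check_ultrametric, tol = tol)
}

#' Validate a phylogeny against the model's assumptions
#'
#' Checks that the tree is rooted and strictly bifurcating, has at least two
#' tips with unique labels, carries nonnegative branch lengths on every edge,
#' and is ultrametric within a relative tolerance.
#'
#' @inheritParams read_newick
#' @param tree An `ape` \code{phylo} object.
#' @return The (possibly polytomy-resolved) tree, invisibly unchanged
#'   otherwise.
#' @export
validate_phylogeny <- function(tree, resolve_polytomies = FALSE,
                               check_ultrametric = TRUE, tol = 1e-6) {
  stopifnot(inherits(tree, "phylo"))
  problems <- character(0)
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    problems <- c(problems, "missing branch length on one or more edges")
  if (length(tree$tip.label) < 2L)
    problems <- c(problems, "tree must have at least 2 tips")
  if (anyDuplicated(tree$tip.label))
    problems <- c(problems, "duplicated tip labels")
  if (!is.null(tree$edge.length) && !anyNA(tree$edge.length) &&
      any(tree$edge.length < 0))
    problems <- c(problems, "negative branch lengths")
  if (!ape::is.binary(tree) || !ape::is.rooted(tree)) {
    if (resolve_polytomies) {
      tree <- ape::multi2di(tree, random = FALSE)
      if (is.null(tree$edge.length)) tree$edge.length <- numeric(0)
      tree$edge.length[is.na(tree$edge.length)] <- 0
    } else {
      problems <- c(problems,
                    "tree has polytomies (set resolve_polytomies = TRUE to resolve)")
    }
  }
  if (length(problems) == 0 && !ape::is.rooted(tree))
    problems <- c(problems, "tree is not rooted")
  if (length(problems) == 0 && check_ultrametric) {
    depths <- tip_depths(tree)
    depth <- max(depths)
    if (depth <= 0 || diff(range(depths)) > tol * depth)
      problems <- c(problems, sprintf(
        "tree is not ultrametric (tip depth range %.3g-%.3g, relative tolerance %g)",
        min(depths), max(depths), tol))
  }
  if (length(problems) > 0)
    stop("invalid phylogeny:\n  - ", paste(problems, collapse = "\n  - "),
         call. = FALSE)
  tree
}

#' Root-to-tip path lengths
#' @param tree A \code{phylo} object.
#' @return Named numeric vector of tip depths, in tip-label order.
#' @export
tip_depths <- function(tree) {
  d <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  names(d) <- tree$tip.label
  d
}

#' Depth (root-to-tip distance) of an ultrametric tree
#' @param tree A \code{phylo} object.
#' @return Maximum root-to-tip path length.
#' @export
tree_depth <- function(tree) max(ape::node.depth.edgelength(tree))

#' Pagel's lambda transformation of an ultrametric tree
#'
#' Multiplies internal branch lengths by `lam` and extends each terminal
#' branch so that the tip keeps its original depth: a pendant branch of
#' length t becomes `lam * t + (1 - lam) * T` where T is the tree depth.
#' Equivalently, off-diagonal entries of the phylogenetic covariance are
#' scaled by `lam` while the diagonal is unchanged. `lam = 1` is the
#' identity; `lam = 0` yields a star phylogeny of the same depth.
#'
#' @param tree An ultrametric \code{phylo} object.
#' @param lam Signal strength in \code{[0, 1]}.
#' @return The transformed \code{phylo} object (same topology and depth).
#' @export
lambda_transform <- function(tree, lam) {
  if (!is.numeric(lam) || length(lam) != 1L || is.na(lam) ||
      lam < 0 || lam > 1)
    stop("lam must be a single number in [0, 1]", call. = FALSE)
  if (lam == 1) return(tree)
  depth <- tree_depth(tree)
  n_tip <- length(tree$tip.label)
  is_pendant <- tree$edge[, 2] <= n_tip
  out <- tree
  out$edge.length[!is_pendant] <- lam * tree$edge.length[!is_pendant]
  out$edge.length[is_pendant] <-
    lam * tree$edge.length[is_pendant] + (1 - lam) * depth
  out
}

#' Phylogenetic covariance matrix of a tree
#'
#' Entry (i, j) is the shared root-to-MRCA path length of tips i and j;
#' the diagonal holds tip depths. Row/column order follows
#' \code{tree$tip.label}.
#'
#' @param tree A \code{phylo} object.
#' @return A symmetric positive semi-definite matrix with tip labels as
#'   dimnames.
#' @export
phylo_covariance <- function(tree) {
  C <- ape::vcv.phylo(tree)
  C[tree$tip.label, tree$tip.label, drop = FALSE]
}

#' Simulate a pure-birth (Yule) tree
#'
#' Ultrametric, strictly bifurcating trees with a fixed number of tips,
#' generated by the constant-rate pure-birth process (via
#' \code{phytools::pbtree}). Deterministic given `seed`.
#'
#' @param n Number of tips (>= 2).
#' @param seed Integer seed.
#' @param birth Speciation rate (default 1; only sets the time scale).
#' @return A \code{phylo} object with `n` tips.
#' @export
simulate_pure_birth <- function(n, seed, birth = 1) {
  if (!is.numeric(n) || length(n) != 1L || n < 2 || n != round(n))
    stop("n must be an integer >= 2", call. = FALSE)
  set.seed(seed)
  if (n == 2) {
    # pbtree's conditioned sampler is degenerate at n = 2; a cherry with an
    # exponential depth is the exact pure-birth outcome
    depth <- stats::rexp(1, rate = 2 * birth)
    tree <- ape::read.tree(text = sprintf("(t1:%.10f,t2:%.10f);", depth, depth))
    return(tree)
  }
  tree <- phytools::pbtree(b = birth, n = n, quiet = TRUE)
  # snap pendant edges so tip depths are exactly equal (waiting-time
  # accumulation leaves ~1e-9 discrepancies)
  depths <- ape::node.depth.edgelength(tree)[seq_len(n)]
  pendant <- match(seq_len(n), tree$edge[, 2])
  tree$edge.length[pendant] <- tree$edge.length[pendant] +
    (max(depths) - depths)
  tree
}

#' Write a tree to a Newick file
#' @param tree A \code{phylo} object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 12)
  invisible(path)
}
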