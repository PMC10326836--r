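#' Centered log-ratio transform
#'
#' Maps each composition row to log-space centred by its row-mean log:
#' `clr(z) = log(z) - mean(log(z))`. Rows of the output sum to zero. The
#' transform is invariant to rescaling a row before renormalization.
#'
#' @param table Composition matrix with strictly positive entries.
#' @return Matrix of the same shape with zero-sum rows.
#' @export
clr_transform <- function(table) {
  table <- as.matrix(table)
  if (any(table <= 0))
    stop("clr requires strictly positive entries; apply the detection-floor ",
         "step (prepare_table) first", call. = FALSE)
  lz <- log(table)
  lz - rowMeans(lz)
}

#' Project extant and ancestral compositions into CLR-PCA space
#'
#' Fits a PCA on the CLR-transformed extant rows only; ancestral
#' compositions are CLR-transformed and projected passively, so they have
#' no influence on the axes.
#'
#' @param table Extant composition table (n x p).
#' @param ancestors One simplex p-vector or a matrix of them (rows).
#' @param k Number of components to keep (<= p).
#' @return List of class `phylosym_projection`: `loadings` (p x k),
#'   `scores` (extant rows), `ancestor_scores`, `explained_variance`
#'   (k-vector of fractions), `center` (CLR centroid).
#' @export
project_with_ancestor <- function(table, ancestors, k = 5) {
  table <- as.matrix(table)
  p <- ncol(table)
  if (k > p) stop("k must not exceed the number of taxa", call. = FALSE)
  if (is.null(dim(ancestors))) ancestors <- matrix(ancestors, nrow = 1)
  ancestors <- as.matrix(ancestors)
  if (ncol(ancestors) != p)
    stop("ancestors must share the extant taxon set", call. = FALSE)
  X <- clr_transform(table)
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  k <- min(k, ncol(pc$rotation))
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  anc_scores <- scale(clr_transform(ancestors), center = pc$center,
                      scale = FALSE) %*% pc$rotation[, seq_len(k), drop = FALSE]
  structure(list(loadings = pc$rotation[, seq_len(k), drop = FALSE],
                 scores = pc$x[, seq_len(k), drop = FALSE],
                 ancestor_scores = anc_scores,
                 explained_variance = ev[seq_len(k)],
                 center = pc$center),
            class = "phylosym_projection")
}

#' Distances from the ancestral composition to diet centroids
#'
#' Computes, on the first five PC axes, the Euclidean distance between the
#' projected ancestral composition and the centroid of each diet category
#' among extant hosts. Used to ask which present-day dietary guild the
#' reconstructed ancestral microbiota resembles most.
#'
#' @param proj A `phylosym_projection` with at least 5 components.
#' @param diet_labels Per-host categories, named by host or in the order
#'   of `proj$scores` rows.
#' @param ancestor_score Optional 1 x k score row (defaults to the first
#'   row of `proj$ancestor_scores`).
#' @return data.frame with columns diet, d (sorted ascending) plus the
#'   centroid coordinates; class `phylosym_centroids`.
#' @export
diet_centroid_distances <- function(proj, diet_labels,
                                    ancestor_score = NULL) {
  if (ncol(proj$scores) < 5)
    stop("need at least five PC axes; refit the projection with k >= 5",
         call. = FALSE)
  scores <- proj$scores[, 1:5, drop = FALSE]
  if (!is.null(names(diet_labels)) && !is.null(rownames(scores)))
    diet_labels <- diet_labels[rownames(scores)]
  diet_labels <- as.character(diet_labels)
  if (length(diet_labels) != nrow(scores))
    stop("one diet label per extant host is required", call. = FALSE)
  if (is.null(ancestor_score))
    ancestor_score <- proj$ancestor_scores[1, 1:5]
  ancestor_score <- as.numeric(ancestor_score)[1:5]
  keep <- !is.na(diet_labels)
  empty <- setdiff(unique(diet_labels), diet_labels[keep])
  if (length(empty) > 0)
    warning("diet classes with no members omitted: ",
            paste(empty, collapse = ", "), call. = FALSE)
  cats <- sort(unique(diet_labels[keep]))
  cent <- t(vapply(cats, function(cl)
    colMeans(scores[diet_labels == cl & keep, , drop = FALSE]),
    numeric(5)))
  d <- sqrt(rowSums((cent - matrix(ancestor_score, nrow(cent), 5,
                                   byrow = TRUE))^2))
  out <- data.frame(diet = cats, d = d, cent, stringsAsFactors = FALSE)
  colnames(out)[3:7] <- paste0("PC", 1:5)
  out <- out[order(out$d), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("phylosym_centroids", "data.frame")
  out
}

#' Integration clustering of the evolutionary covariance matrix
#'
#' Builds an undirected weighted graph over taxa with edge weights
#' `max(R[j, k], 0)` (negative covariances are discarded) and partitions
#' it by greedy modularity maximization (`igraph::cluster_fast_greedy`).
#' Taxa that covary positively in a concerted way fall in the same
#' cluster ("integrated" subsets of the microbiota).
#'
#' @param R Symmetric covariance matrix (p x p).
#' @param taxon_ids Optional taxon labels (defaults to colnames).
#' @return List of class `phylosym_clusters`: `membership` (named integer
#'   vector), `clusters` (list of taxon-id vectors), `modularity`.
#' @export
integration_clusters <- function(R, taxon_ids = colnames(R)) {
  R <- as.matrix(R)
  if (max(abs(R - t(R))) > 1e-8) stop("R must be symmetric", call. = FALSE)
  p <- nrow(R)
  if (is.null(taxon_ids)) taxon_ids <- paste0("taxon", seq_len(p))
  W <- pmax(R, 0)
  diag(W) <- 0
  if (all(W == 0)) {
    message("no positive covariances: every taxon forms its own cluster")
    membership <- seq_len(p)
    names(membership) <- taxon_ids
    return(structure(list(membership = membership,
                          clusters = as.list(taxon_ids),
                          modularity = NA_real_),
                     class = "phylosym_clusters"))
  }
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  igraph::V(g)$name <- taxon_ids
  cl <- igraph::cluster_fast_greedy(g)
  membership <- igraph::membership(cl)
  names(membership) <- taxon_ids
  structure(list(membership = membership,
                 clusters = split(taxon_ids, membership),
                 modularity = max(igraph::modularity(cl), -1)),
            class = "phylosym_clusters")
}

#' Mantel-test baseline for phylosymbiosis
#'
#' Pearson correlation between host patristic distances and Bray-Curtis
#' dissimilarities of the microbiota (upper triangles), with a permutation
#' p-value under the add-one rule. This is the correlative test the
#' process-based lambda permutation test is compared against.
#'
#' @param tree Host phylogeny (untransformed; n >= 4).
#' @param data Composition table aligned to the tree.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed.
#' @return List of class `phylosym_mantel`: `statistic`, `p_value`,
#'   `n_perm`.
#' @export
mantel_baseline <- function(tree, data, n_perm = 999, seed = 1) {
  data <- as.matrix(data)
  n <- nrow(data)
  if (n < 4) stop("Mantel baseline needs at least 4 hosts", call. = FALSE)
  data <- data[tree$tip.label, , drop = FALSE]
  D_phy <- ape::cophenetic.phylo(tree)[rownames(data), rownames(data)]
  D_bc <- as.matrix(vegan::vegdist(data, method = "bray"))
  ut <- upper.tri(D_phy)
  x <- D_phy[ut]; y <- D_bc[ut]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant dissimilarities: Mantel correlation undefined",
         call. = FALSE)
  stat <- stats::cor(x, y)
  set.seed(seed)
  null <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    perm <- sample.int(n)
    null[b] <- stats::cor(x, D_bc[perm, perm][ut])
  }
  p_value <- (1 + sum(null >= stat)) / (1 + n_perm)
  structure(list(statistic = stat, p_value = p_value, n_perm = n_perm,
                 null = null),
            class = "phylosym_mantel")
}

#' Posterior-predictive adequacy check
#'
#' Simulates `n_sims` datasets from the fitted parameters on the host
#' tree, projects both the empirical and the simulated compositions into
#' the empirical CLR-PCA space, and reports, per principal component, the
#' fraction of empirical scores lying inside the 2.5-97.5% envelope of
#' the simulated scores. High coverage means the model can generate
#' compositions like the observed ones.
#'
#' @param tree Host phylogeny.
#' @param fitted A [model_params()] bundle (e.g. from [mean_estimates()]).
#' @param data Empirical composition table.
#' @param n_sims Number of posterior-predictive simulations (default 20).
#' @param seed Integer seed.
#' @param k Number of components to report (default 5, capped at p).
#' @return List of class `phylosym_adequacy`: `coverage` (per-PC
#'   fraction), `envelopes` (per-PC 2.5/97.5% bounds), `empirical_scores`,
#'   `simulated_scores`, `degenerate` flag (TRUE when `n_sims` is too
#'   small for a meaningful envelope).
#' @export
adequacy_check <- function(tree, fitted, data, n_sims = 20, seed = 1,
                           k = 5) {
  data <- as.matrix(data)[tree$tip.label, , drop = FALSE]
  p <- ncol(data)
  k <- min(k, p)
  X <- clr_transform(data)
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  emp <- pc$x[, seq_len(k), drop = FALSE]
  sims <- vector("list", n_sims)
  for (s in seq_len(n_sims)) {
    sim <- simulate_microbiota(tree, fitted, seed = seed + s - 1)
    zt <- pmax(sim$table, 1e-12)
    zt <- zt / rowSums(zt)
    sims[[s]] <- scale(clr_transform(zt), center = pc$center,
                       scale = FALSE) %*% pc$rotation[, seq_len(k),
                                                      drop = FALSE]
  }
  sim_all <- do.call(rbind, sims)
  env <- t(apply(sim_all, 2, stats::quantile, probs = c(0.025, 0.975)))
  colnames(env) <- c("lower", "upper")
  coverage <- vapply(seq_len(k), function(j)
    mean(emp[, j] >= env[j, 1] & emp[, j] <= env[j, 2]), numeric(1))
  names(coverage) <- colnames(emp)
  structure(list(coverage = coverage, envelopes = env,
                 empirical_scores = emp, simulated_scores = sim_all,
                 n_sims = n_sims,
                 degenerate = n_sims < 2),
            class = "phylosym_adequacy")
}
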