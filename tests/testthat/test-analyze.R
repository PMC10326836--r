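test_that("clr transform centres log compositions", {
  u <- simplex_table(rep(1, 4), "A", paste0("t", 1:4))
  expect_equal(unname(clr_transform(u)), matrix(0, 1, 4))
  m <- simplex_table(c(0.8, 0.2), "A", c("t1", "t2"))
  cm <- (log(0.8) + log(0.2)) / 2
  expect_equal(unname(clr_transform(m)),
               matrix(c(log(0.8) - cm, log(0.2) - cm), 1))
  set.seed(3)
  z <- matrix(rexp(30), 5, 6); z <- z / rowSums(z)
  dimnames(z) <- list(paste0("h", 1:5), paste0("t", 1:6))
  expect_lt(max(abs(rowSums(clr_transform(z)))), 1e-12)
  scaled <- z * 7; scaled <- scaled / rowSums(scaled)
  expect_equal(clr_transform(z), clr_transform(scaled))
  z0 <- z; z0[1, 1] <- 0
  expect_error(clr_transform(z0), "floor")
})

test_that("PCA projection is passive for ancestors and exact for extants", {
  set.seed(11)
  z <- matrix(rexp(60), 10, 6); z <- z / rowSums(z)
  dimnames(z) <- list(paste0("h", 1:10), paste0("t", 1:6))
  anc <- sample_root(6, seed = 12)
  proj <- project_with_ancestor(z, anc, k = 5)
  expect_true(all(proj$explained_variance >= 0 &
                    proj$explained_variance <= 1))
  expect_true(all(diff(proj$explained_variance) <= 1e-12))
  expect_lte(sum(proj$explained_variance), 1 + 1e-12)
  # passive projection of an extant row reproduces its active score
  self <- scale(clr_transform(z[3, , drop = FALSE]), center = proj$center,
                scale = FALSE) %*% proj$loadings
  expect_lt(max(abs(self - proj$scores[3, ])), 1e-9)
  # ancestor at the clr centroid projects to the origin
  centroid_clr <- colMeans(clr_transform(z))
  anc_centroid <- exp(centroid_clr) / sum(exp(centroid_clr))
  proj2 <- project_with_ancestor(z, anc_centroid, k = 5)
  expect_lt(max(abs(proj2$ancestor_scores)), 1e-9)
  expect_error(project_with_ancestor(z, anc, k = 7), "exceed")
})

test_that("diet centroid distances are Euclidean on the first five PCs", {
  set.seed(21)
  scores <- matrix(rnorm(60), 12, 5)
  proj <- structure(list(scores = scores,
                         ancestor_scores = matrix(0, 1, 5)),
                    class = "phylosym_projection")
  diets <- rep(c("plants", "meat"), each = 6)
  # mirrored clouds: ancestor at the origin is equidistant
  scores[7:12, ] <- -scores[1:6, ]
  proj$scores <- scores
  cd <- diet_centroid_distances(proj, diets)
  expect_equal(cd$d[1], cd$d[2], tolerance = 1e-12)
  # ancestor placed exactly at one centroid
  cent <- colMeans(scores[diets == "plants", ])
  cd2 <- diet_centroid_distances(proj, diets, ancestor_score = cent)
  expect_equal(cd2$d[cd2$diet == "plants"], 0, tolerance = 1e-12)
  expect_true(!is.unsorted(cd2$d))
})

test_that("integration clustering recovers planted covariance blocks", {
  taxa <- paste0("t", 1:6)
  R <- matrix(-0.2, 6, 6)
  R[1:3, 1:3] <- 0.5
  R[4:6, 4:6] <- 0.5
  diag(R) <- 1
  dimnames(R) <- list(taxa, taxa)
  cl <- integration_clusters(R)
  expect_length(cl$clusters, 2)
  expect_setequal(cl$clusters[[cl$membership[["t1"]]]], taxa[1:3])
  expect_setequal(cl$clusters[[cl$membership[["t4"]]]], taxa[4:6])
  expect_gt(cl$modularity, 0)

  # permuting taxa permutes but does not change the partition
  perm <- c(4, 1, 6, 2, 5, 3)
  clp <- integration_clusters(R[perm, perm])
  same <- function(c1) unname(sort(vapply(c1, paste, "", collapse = "+")))
  expect_identical(same(lapply(cl$clusters, sort)),
                   same(lapply(clp$clusters, sort)))
  # adding a constant to the diagonal changes nothing (diagonal ignored)
  cld <- integration_clusters(R + diag(5, 6))
  expect_identical(same(lapply(cl$clusters, sort)),
                   same(lapply(cld$clusters, sort)))

  pair <- diag(0.3, 4)
  pair[1, 2] <- pair[2, 1] <- 0.2
  dimnames(pair) <- list(paste0("x", 1:4), paste0("x", 1:4))
  clpair <- integration_clusters(pair)
  expect_equal(clpair$membership[["x1"]], clpair$membership[["x2"]])

  allneg <- matrix(-0.1, 3, 3); diag(allneg) <- 0.5
  dimnames(allneg) <- list(letters[1:3], letters[1:3])
  expect_message(cls <- integration_clusters(allneg), "own cluster")
  expect_length(cls$clusters, 3)
})

test_that("mantel statistic is 1 when dissimilarity equals patristic distance", {
  tree <- ape::read.tree(text = "(A:0.3,B:0,C:0,D:0.4);")
  x <- c(A = 0, B = 0.3, C = 0.3, D = 0.7)
  z <- cbind(t1 = x, t2 = 1 - x)
  mt <- mantel_baseline(tree, z, n_perm = 99, seed = 1)
  expect_equal(mt$statistic, 1, tolerance = 1e-12)
  # only 4! row orders exist, so the add-one p cannot go below 1/24
  expect_lte(mt$p_value, 0.25)
})

test_that("mantel permutation null is calibrated on shuffled data", {
  rej <- 0
  reps <- 40
  for (r in seq_len(reps)) {
    dat <- sim_dataset(25, 4, 1, seed = 700 + 13 * r)
    set.seed(r)
    shuffled <- dat$table[sample(nrow(dat$table)), , drop = FALSE]
    rownames(shuffled) <- rownames(dat$table)
    mt <- mantel_baseline(dat$tree, shuffled, n_perm = 199, seed = r)
    rej <- rej + (mt$p_value <= 0.05)
  }
  expect_gte(rej / reps, 0.0)
  expect_lte(rej / reps, 0.125)
})

test_that("mantel errors on degenerate inputs", {
  tree <- ape::read.tree(text = "(A:1,B:1,C:1,D:1);")
  z <- simplex_table(rep(c(0.5, 0.5), 4), LETTERS[1:4], c("t1", "t2"))
  expect_error(mantel_baseline(tree, z), "constant")
})

test_that("adequacy check covers model-generated data", {
  dat <- sim_dataset(40, 5, 0.8, seed = 61)
  params <- model_params(0.8, dat$Z0, dat$R)
  ad <- adequacy_check(dat$tree, params, dat$table, n_sims = 20, seed = 3)
  expect_gte(mean(ad$coverage[1:2]), 0.8)
  expect_equal(nrow(ad$simulated_scores), 40 * 20)
  ad1 <- adequacy_check(dat$tree, params, dat$table, n_sims = 1, seed = 3)
  expect_true(ad1$degenerate)
  expect_true(all(is.finite(ad1$coverage)))
})
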