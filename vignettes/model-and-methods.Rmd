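---
title: "A phylogenetic Brownian model of microbiota composition: model, priors, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A phylogenetic Brownian model of microbiota composition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylosym)
```

## The model

`phylosym` asks how much of the variation in microbiota composition among
host species is explained by host evolutionary history (*phylosymbiosis*),
and what the microbiota of ancestral hosts looked like. The data are a
rooted ultrametric host phylogeny and, for each extant host species, the
relative abundances $Z_{ij}$ of $p$ microbial taxa (rows on the simplex).

The model works on *absolute* abundances, which metabarcoding does not
observe. Writing $X_{ij}$ for the absolute abundance of taxon $j$ in host
$i$ and $Y_i = \sum_j X_{ij}$ for the total, the observed composition is
$Z_{ij} = X_{ij} / Y_i$. We assume $\log X_{ij}$ evolves along the host
tree as a multivariate Brownian motion: over a branch of length $t$, the
$p$-vector of log abundances gains an increment
$\mathcal{N}(0,\, t\,R)$, where the $p \times p$ SPD matrix $R$ holds the
evolutionary variances (diagonal) and covariances (off-diagonal,
"integration") of the taxa. The root state is $\log X_0$; because only
ratios are observable we pin the root total to one ($Y_0 \equiv 1$), so
$\log X_0 = \log Z_0$ with $Z_0$ on the simplex — the ancestral
composition. Each host's total enters as a latent variable
$\log \tilde Y_i = \log (Y_i / Y_0)$, and the latent matrix
$\log X = \log Z + \log \tilde Y \mathbf{1}^\top$ is matrix-normal with
mean rows $\log Z_0^\top$ and covariance $C_\lambda \otimes R$.

Phylosymbiosis is measured by Pagel's $\lambda \in [0, 1]$: the tree's
internal branches are multiplied by $\lambda$ and each terminal branch is
extended by $(1-\lambda)$ of the tree depth, so the depth is unchanged
while every off-diagonal entry of the phylogenetic covariance $C$ is
scaled by $\lambda$. $\lambda = 1$ leaves the tree intact (compositional
divergence tracks host divergence); $\lambda = 0$ yields a star phylogeny
(no phylogenetic structure). $\lambda$ is estimated jointly with $Z_0$,
$R$ and the latent totals.

### Assumptions worth stating

* every taxon is present in every host, possibly below detection — hence
  the detection floor (0.001% by default) rather than structural zeros;
  the model is meant for high taxonomic levels (e.g. bacterial orders);
* $R$ is constant in time and across the tree; no directional trend;
* the tree is fixed, ultrametric and bifurcating.

## Inference

The joint posterior of $(\lambda, Z_0, R, \log\tilde Y)$ is sampled with
a No-U-Turn Hamiltonian Monte Carlo sampler (multinomial variant, dual
averaging of the step size targeting acceptance 0.9, diagonal metric
adaptation), implemented in compiled code with analytic gradients.
Defaults are 4 chains of 4,000 iterations with 2,000 warmup; convergence
is monitored with split-$\hat R$ and effective sample sizes, warning at
$\hat R > 1.01$ or ESS $< 200$.

Two structural choices make sampling fast and robust:

* **Eigen-factorization of the tree covariance.** With
  $C = U\,\mathrm{diag}(d)\,U^\top$ computed once,
  $C_\lambda = U\,\mathrm{diag}(\lambda d + (1-\lambda)T)\,U^\top$ for
  every $\lambda$, so each likelihood evaluation is
  $O(np + p^3)$ after a single $O(n^3)$ decomposition.
* **Exact marginalization of the latent totals.** $\log\tilde Y$ enters
  the matrix-normal likelihood linearly and carries a Gaussian
  distribution $\mathcal{N}(\mu_y, \sigma_y^2 I)$, so it is integrated
  out in closed form (a rank-one Woodbury update per eigen-row of $C$).
  The sampler explores only $(\lambda, Z_0, \sigma_y, \mu_y, R)$ —
  roughly $p(p+1)/2 + p + 3$ dimensions instead of that plus $n$ — and
  each retained draw is completed with an exact Gaussian conditional draw
  of $\log\tilde Y$. The reported draws therefore come from the full
  joint posterior, without the funnel geometry that the explicit latent
  parameterization induces.

### Priors (and why)

The priors are the package's own choices; they matter mostly for the
parts of $R$ that the compositional data only weakly identify.

* $\lambda \sim \mathrm{Uniform}(0, 1)$ — the transform is only defined
  there; sampled through a logit with the matching Jacobian.
* $Z_0$: additive-log-ratio parameterization with a flat prior on the
  unconstrained scale, keeping $\sum_j Z_{0j} = 1$ exactly.
* $R = LL^\top$ through its Cholesky factor, with independent Gaussians
  on the elements of $L$: $\mathcal{N}(0, 2.5)$ off-diagonal and
  $\mathcal{N}(0, 1.5)$ on the log-diagonal, on the depth-one rescaled
  tree. This guarantees SPD draws and has simple analytic gradients; it
  is weakly informative for the variances met in practice (the tree is
  rescaled to unit depth internally and $R$ is rescaled back for
  reporting).
* Latent totals: $\log\tilde Y_i \sim \mathcal{N}(\mu_y, \sigma_y^2)$
  i.i.d., with the mean $\mu_y \sim \mathcal{N}(0, 10)$ sampled and the
  scale $\sigma_y$ a fixed hyperparameter (default 0.5). Three lessons
  from simulation shaped this. First, the mean matters: the total
  abundances implied by Brownian log-abundance evolution do not center on
  the root's total, and forcing a zero-mean latent makes $\lambda$ absorb
  the common offset as spurious phylogenetic signal. Second, the scale
  governs how strongly the "overall abundance" direction of $R$ — which
  relative abundances identify only weakly — is regularized: a very
  diffuse scale (say 5) makes even strong planted evolutionary
  covariances undetectable, while the default keeps them detectable at
  moderate sample sizes. Third, the scale cannot be learned freely: the
  true latent totals are themselves phylogenetically structured, so the
  likelihood drives a free $\sigma_y$ toward zero, and the posterior of
  $R$ then converges on the *compositionally projected* covariance
  $\tilde P R \tilde P^\top$ (with $\tilde P = I - \mathbf{1}\bar
  w^\top$, $\bar w$ the abundance weights), not on $R$ itself. The
  projection has real consequences (see Known limitations): even when
  the true $R$ is diagonal, the identified covariance has nonzero
  off-diagonals of order $\bar w_j R_{jj}$, and at the default
  $\sigma_y$ the method flags an appreciable share of them as
  significant. Significance statements about $R$ should therefore be
  read as statements about the latent-scale-regularized, compositionally
  identified covariance. Users can raise `prior$sigma_y` (e.g. to 1.3)
  to suppress these projection effects at the cost of missing weaker
  genuine covariances.

### Significance of $\lambda$: permutations

$\lambda$ is nonnegative, so its credible interval cannot be used as a
null test. Instead the package shuffles which host species carries which
microbiota, refits, and compares the observed posterior-mean $\lambda$
with the null distribution (default 100 permutations; p-value with the
add-one rule, significance declared at $p \le 0.05$, i.e. the observed
$\lambda$ exceeds at least 95% of the null values). With a trait table
the shuffle can be constrained to hosts sharing the same diet, realm,
flying ability, or combinations — if $\lambda$ survives such constrained
shuffles, the conservatism of those traits does not explain the signal.

Covariances in $R$ are called significant when 0 lies outside their 95%
credible interval.

## The simulator and what it does (not) emulate

`simulate_pure_birth` draws Yule trees; `sample_root` draws root log
abundances uniformly on $[-4, 0]$ and normalizes; `random_spd` mixes a
fixed spectrum (eigenvalues 1/4 by default — note that with a literally
equal spectrum the result is $\tfrac14 I$; a `"varied"` spectrum option
draws eigenvalues with the same mean for covariance-recovery studies)
through a Haar-random orthogonal matrix; `simulate_microbiota` evolves
log abundances branchwise on the $\lambda$-transformed tree, recording
internal-node states, true latent totals and tip compositions.
`run_grid` reproduces the full factorial design
($n \in \{20, 50, 100, 250\}$, $p \in \{3, 5, 10, 15\}$,
$\lambda \in \{0, 0.25, 0.5, 0.75, 1\}$, 100 replicates — 8,000
datasets) or any scaled-down version of it.

The simulator emulates neutral compositional drift of a fixed taxon set.
It does **not** emulate sequencing (read counts, rarefaction),
taxon gain/loss, sample-to-sample within-species variation, or selection
toward preferred compositions; passing tests on simulated data therefore
demonstrates correctness of the inference machinery under the model's own
assumptions, not robustness to everything real data do.

## Ancestral reconstruction

Conditional on point estimates (posterior means, matching the convention
of reporting $Z_0$ at the root and GLS estimates elsewhere),
`gls_ancestral` computes for each taxon the Brownian conditional
expectation of every internal node on the $\lambda$-transformed tree —
$\hat x_{\text{nodes}} = \log Z_0 + V_{nt} V_{tt}^{-1}(x_{\text{tips}} -
\log Z_0)$ with shared-path covariances $V$ — then exponentiates and
renormalizes each node row to the simplex. On a star tree the estimates
collapse to $Z_0$; node estimates shrink toward the root as nodes get
older, so deep reconstructions are flatter than the truth (the test suite
checks that reconstruction error grows with node age). `shift_report`
lists edges with composition changes above a threshold (default 0.10
absolute).

## Downstream analyses

* `clr_transform` + `project_with_ancestor`: PCA of the
  centered-log-ratio transformed extant compositions; ancestral
  compositions are projected passively so they do not bend the axes.
* `diet_centroid_distances`: Euclidean distances on the first five
  (unscaled) PC axes between the projected ancestor and each diet
  centroid; distances are not whitened by axis variance — the axes keep
  their natural scale.
* `integration_clusters`: greedy modularity clustering
  (`igraph::cluster_fast_greedy`) of the graph whose edge weights are the
  positive entries of $R$ (negative covariances set to 0, per the
  analysis convention this reproduces).
* `mantel_baseline`: Pearson correlation between patristic distances (on
  the untransformed tree) and Bray–Curtis dissimilarities, permutation
  p-value with the add-one rule. Included as the correlative baseline the
  process-based test is compared against.
* `adequacy_check`: simulates from the fitted parameters and reports, per
  PC of the empirical CLR-PCA, the fraction of empirical scores inside
  the 2.5–97.5% envelope of simulated scores — a quantitative stand-in
  for the visual overlay this check is usually done with.

## Numerical choices and degenerate inputs

* Ultrametricity tolerance: relative $10^{-6}$ of depth; polytomies are
  rejected unless explicitly resolved to zero-length bifurcations.
* Eigenvalues of $C$ are clamped at $10^{-10}$ so $\lambda \to 1$ cannot
  produce a non-positive row variance through floating-point negatives.
* The composition floor ($10^{-5}$) is applied then rows renormalized;
  the post-renormalization bound $\varepsilon / (1 + p\varepsilon)$ is
  what validation enforces.
* $\lambda$ is sampled on the closed interval via the logit; at
  $\lambda = 0$ the covariance is diagonal and remains valid.
* Posterior-mean $R$ is projected to the nearest SPD matrix by
  eigenvalue clipping in the rare case element-wise averaging leaves it
  indefinite.
* Step size is floored at $10^{-5}$ during adaptation; a divergence is a
  Hamiltonian error above 1,000.

## Problem sizes used by the test suite

The full reference analysis (4 chains × 4,000 iterations; 100
permutations; hundreds of host species) is the package default. The test
suite and the acceptance script run the same code paths at documented
desk scales chosen to finish in minutes on one core: recovery at
$n = 50$, $p = 5$ with 2 chains × 1,200 iterations; permutation
calibration with 20 permutations and single short chains
(400 iterations, tree depth capped at 5) whose only consumer is the
posterior-mean $\lambda$; the weak-signal power comparison at $n = 100$,
$p = 10$ with 19 permutations. These scales are stated here as the
package's own test design.

## Known limitations

* Only the contrast part of $R$ is identified by compositional data at
  finite sample size; the remaining direction is shaped by the latent
  total prior, and the identified covariance is the compositional
  projection of $R$. With uneven compositions this projection turns a
  diagonal $R$ into one with genuinely nonzero off-diagonals, so
  covariance significance has an irreducible trade-off between power for
  true covariances and false flags of projection artifacts, tuned by
  `prior$sigma_y` (see Priors). Integration conclusions are
  correspondingly prior-aware.
* Ancestral states are conditional expectations — over-smooth relative
  to any single evolutionary history, with uncertainty growing with node
  age.
* No taxon gain/loss process: taxa absent in many hosts at the chosen
  taxonomic level violate the "present everywhere" assumption.
* Non-ultrametric trees, directional trends, early-burst variance decay
  and branch-specific $R$ are out of scope.
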