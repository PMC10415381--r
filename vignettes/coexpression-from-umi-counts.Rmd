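---
title: "Estimating cell-type-specific co-expression from UMI counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating cell-type-specific co-expression from UMI counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(umicoex)
```

## The measurement model

For $n$ cells of one cell type and $p$ genes, the observed UMI count
$x_{ij}$ is modelled as a Poisson readout of a latent relative expression
level $z_{ij}$ scaled by the cell's sequencing depth $s_i$:

$$(z_{i1},\dots,z_{ip}) \sim F_p(\boldsymbol\mu, \boldsymbol\Sigma),
\qquad x_{ij}\,|\,z_{ij} \sim \mathrm{Poisson}(s_i z_{ij}).$$

$F_p$ is an arbitrary non-negative multivariate distribution; nothing about
its shape is assumed. Co-expression of a gene pair is the correlation of
their latent expressions,
$\rho_{jj'} = \sigma_{jj'}/\sqrt{\sigma_{jj}\sigma_{j'j'}}$. This target is
defined before measurement, so it is not confounded by depth variation and
not attenuated by Poisson noise — the two artifacts that corrupt
correlations of raw or normalized counts.

The depth $s_i$ is the cell's *full-transcriptome* UMI total. The
`count_matrix` container therefore carries depths alongside the counts, and
`top_expressed_genes()` never recomputes them after subsetting to a panel:
a panel row sum is not a sequencing depth.

## Moment estimation by IRLS

The model implies
$\mathbb E(x_{ij}) = s_i\mu_j$,
$\mathrm{Var}(x_{ij}) = s_i\mu_j + s_i^2\sigma_{jj}$, and
$\mathbb E[(x_{ij}-s_i\mu_j)(x_{ij'}-s_i\mu_{j'})] = s_i^2\sigma_{jj'}$.
Each parameter is estimated by weighted least squares on the corresponding
regression equation; each problem is one-dimensional and has a closed-form
ratio solution (`wls_mean`, `wls_variance`, `wls_covariance`). The weights
are the inverse variances of the residuals,
$w_{ij} = 1/(s_i\mu_j + s_i^2\mu_j^2\theta)$, with $h = w^2$ for the
variance equations and $g_{ijj'} = w_{ij}w_{ij'}$ for covariances, and are
refreshed each iteration from the current estimates.

Per-gene over-dispersion estimates $\sigma_{jj}/\mu_j^2$ are too noisy to
weight with, so a single $\theta$ — the cross-gene median — is used inside
the weights (the variance *estimates* themselves are not shrunk). Details
that matter in edge cases:

* **Initialization** is ordinary least squares (unit weights).
* **Convergence** is declared when
  $\Delta^{(t)} = \max_j |\log\hat\sigma_{jj}^{(t)} -
  \log\hat\sigma_{jj}^{(t-1)}|$ (natural log) drops below `tol = 0.05`;
  genes whose variance estimate is non-positive at either iteration are
  excluded from $\Delta$. A hard cap of `max_iter = 10` guards against
  cycling; on model-generated data convergence occurs within 5 iterations
  (this is tested).
* **Degenerate genes.** All-zero genes are flagged `ZERO_GENE` and
  excluded up front. Genes whose final variance estimate is non-positive
  (moment estimators admit this) are flagged `NEGATIVE_VARIANCE`; their
  network rows are zeroed and they report $p = q = 1$ rather than aborting
  the run.
* If the median over-dispersion ratio is negative (possible when latent
  variation is absent), $\theta$ is set to 0 and the weights reduce to
  inverse Poisson variances.
* Correlation estimates outside $[-1, 1]$ are clipped, and the clip count
  is reported in the result and the run manifest.

Pairwise covariances for all $p(p-1)/2$ pairs are computed as two matrix
cross-products (residuals and weights pre-scaled by $s_i$), which is
algebraically identical to the per-pair weighted least squares loop — a
property the test suite asserts.

## The independence test

For a pair with independent latent expressions,
$\mathrm{Var}(\xi_{ijj'}) = (s_i\mu_j + s_i^2\sigma_{jj})
(s_i\mu_{j'} + s_i^2\sigma_{j'j'}) = 1/g_{ijj'}$, and the standardized
weighted covariance

$$T_{jj'} = \frac{\sum_i s_i^2 (x_{ij}-s_i\mu_j)(x_{ij'}-s_i\mu_{j'})
g_{ijj'}}{\sqrt{\sum_i s_i^4 (s_i\mu_j + s_i^2\sigma_{jj})
(s_i\mu_{j'} + s_i^2\sigma_{j'j'}) g_{ijj'}^2}}$$

is asymptotically standard normal. By default the variance factors in the
denominator reuse the regularized variances $s\mu + s^2\mu^2\theta$ — the
same quantities that define $g$ — so the denominator simplifies to
$\sqrt{\sum_i s_i^4 g_{ijj'}}$ and the statistic is internally consistent
with the weighting; `regularized_var = FALSE` plugs in the raw
$\hat\sigma_{jj}$ instead. Two-sided p values come from the normal null and
q values from Benjamini-Hochberg across the tested (unflagged) pairs.
Simulation under the null reproduces a mean near 0, a standard deviation
near 1 and a uniform p distribution at $n = 1000$ cells.

## The count simulator

Latent expression is marginally $\mathrm{Gamma}(\alpha_j, \beta_j)$ with
$\mu_j = \alpha_j\beta_j$, $\sigma_{jj} = \alpha_j\beta_j^2$, coupled by a
Gaussian copula with correlation matrix $R$
($z_{ij} = F_j^{-1}(\Phi(v_{ij}))$); counts are
$\mathrm{Poisson}(s_i z_{ij})$, so each gene is marginally negative
binomial (verified by goodness-of-fit in the tests). Note that $R$ is the
*copula* correlation; the induced Pearson correlation of skewed Gammas is
slightly smaller, which is why recovery checks use a $\pm 0.05$ band.

Defaults, chosen once to emulate a highly expressed gene panel from a
droplet experiment:

* `default_marginals()`: means log-uniform over `1e-5`–`1e-1` (four
  decades of relative expression) and a common over-dispersion
  `theta = 0.5`, so $\sigma_{jj} = 0.5\,\mu_j^2$.
* `sample_depths()`: log-normal integer depths, median 5000,
  `sdlog = 0.5` — a long right tail spanning roughly 1,500–17,000, the
  shape seen in droplet data; or a constant-depth model for experiments
  isolating the effect of depth variation.
* `block_correlation()` builds planted-cluster copulas (equal blocks,
  constant within/between values) with the true labels attached; a
  non-positive-semidefinite configuration is an error, and `nearest_pd()`
  repair is opt-in, never silent.

What the simulator does **not** emulate: batch effects, cell-level
covariates, zero-inflation beyond what Gamma-Poisson produces, gene-length
effects, ambient RNA, or doublets. Passing tests on these simulations
therefore demonstrate correctness of the estimator under its own
measurement model, not robustness to every artifact of real experiments.

## Null data by permutation

`permute_null_counts()` rebuilds a dataset with expression profiles
preserved and all cross-gene dependence destroyed: normalized expressions
$y_{ij} = x_{ij}/s_i$ are permuted independently within each gene, and new
counts are drawn from $\mathrm{Poisson}(t_i\,y^p_{ij})$, with targets
$t_i$ equal to the observed depths (varying-depth null), their median
(constant-depth null), or a custom vector.

The depths attached to the result are the targets $t_i$, not the panel row
sums. The reason is structural: a depth is a full-transcriptome total, and
when the matrix in hand is a gene panel, its row sum equals
$t_i \sum_j y^p_{ij}$ — the second factor is a per-cell summary of the
permuted panel shared by all genes, and dividing by it couples genes that
were just decorrelated. At desk scale (hundreds of genes forming the whole
simulated panel) this compositional factor is large enough to re-introduce
a visible expression-dependent trend in average co-expression; with a
full-transcriptome matrix it is negligible, and `depths_as = "realized"`
restores row-sum depths for that case.

## Baselines

`normalize_counts()` implements the two standard transforms — scaled
($10^4 x/s$) and log-normalized ($\log(10^4 x/s + 1)$) — and
`correlation_test()` the conventional Pearson/Spearman test with
$t = r\sqrt{(n-2)/(1-r^2)}$ referred to the standard normal. The normal
reference (rather than $t_{n-2}$) is deliberate, matching how these
baselines are conventionally evaluated in this setting; at the cell numbers
involved the difference is negligible. Spearman uses average ranks, as
count data are heavily tied. These baselines exist to reproduce the two
artifacts: cells sharing a count pair $(a, b)$ fall on artifact lines after
normalization (slope $b/a$ scaled; slope 1, intercept $\log b - \log a$
log-normalized), inflating false positives under varying depths, and
attenuation makes baseline correlations grow spuriously with expression
level.

## Differential co-expression

Two groups are balanced by downsampling (`subsample_balance`), networks are
estimated per group, and the difference $\Delta\rho$ is tested by label
permutation: cells are pooled and re-split `B = 100` times, the full
estimate is recomputed on each pseudo-group (moments are deliberately not
cached across permutations), and the two-sided empirical p value uses the
add-one estimator $(1 + \#\{|\Delta^{(b)}| \ge |\Delta|\})/(1 + B)$, so
p values live on $\{1/(B{+}1), \dots, 1\}$ and are never zero. Permutation
p values are exact per pair; because pairs share cells and a common
$\theta$, the *fraction* of pairs below a threshold in one run is more
variable than an independent-pairs binomial calculation suggests — a
property to keep in mind when reading calibration checks.

## Module extraction

Modules are extracted by average-linkage hierarchical clustering of the
significant absolute edge weights at soft-threshold power 1. The default
dissimilarity is one minus the topological overlap of the adjacency — the
standard co-expression module measure, scoring genes as close when they
share neighbors. This choice is deliberate: pilot simulations showed that
clustering directly on $1 - |\hat\rho|$ is fragile to noise in individual
edges of low-expression genes, while topological overlap, which averages
each edge over $p$ shared-neighbor terms, recovers planted clusters
reliably under the same conditions (`dissimilarity = "adjacency"` remains
available). Genes with no edges — flagged genes, or genes with no
significant pair — are left unassigned (`NA`, the conventional "grey"
module) instead of consuming clusters in a fixed-$k$ cut. An optional
strong-signal filter restricts to genes whose total absolute differential
weight exceeds the median. This clustering stack is a documented substitute
for a full weighted-network module pipeline, not a re-implementation of
one.

## Evaluation metrics

* `attenuation_factor(s, mu, cv)` $= \sqrt{s\,\mathrm{CV}^2/(1/\mu +
  s\,\mathrm{CV}^2)}$: the factor by which Poisson measurement shrinks a
  pair's count-based correlation ($\rho_{jj'} \times a_{ij}a_{ij'}$);
  strictly increasing in each argument and $\to 1$ as expression grows.
* `precision_recall()` sweeps pair rankings by p value or absolute
  estimate; area by trapezoid over recall.
* `adjusted_rand_index()` uses the pair-counting contingency formula
  (cross-checked against an independent implementation in the tests).
* `subspace_distance(U, V)` $= \|UU^\top - VV^\top\|_F/\sqrt{2k}$,
  normalized to $[0,1]$ and equal to the root-mean-square sine of the
  principal angles. The $\sqrt{2k}$ convention is fixed and documented
  here because more than one normalization circulates.
* `mean_correlation_bias()` is the Spearman correlation between per-gene
  expression and per-gene average estimated co-expression — near zero for
  an unbiased estimator when expression is assigned independently of the
  network.

## Simulation designs behind the headline checks

The test suite and `scripts/acceptance.R` run these designs (sizes chosen
as sensible desk-scale versions of the full experiments):

* **Convergence**: 25 runs at $p = 100$, $n = 1000$, long-tailed depths.
* **Null centering**: permuted null at $p = 200$, $n = 1000$, varying
  depths; grand mean of per-gene average co-expression within $\pm 0.01$
  of zero and no expression trend.
* **Null calibration**: $\sim$10,000 independent pairs at $n = 1000$;
  the statistic's mean/SD and a KS test of p uniformity.
* **Recovery at 0.5**: 250 pairs at copula correlation 0.5, means over
  four decades, $n = 1000$; mean $\hat\rho$ within $\pm 0.05$ and no
  positive trend in expression, while the log-normalized Pearson baseline
  collapses in the lowest expression quartile.
* **Cluster recovery**: $p = 100$, $n = 2000$, four planted clusters at
  within-correlation 0.6 over a background of 0.15, means over
  `1e-5`–`1e-2` and independent of cluster membership. The background plus
  the wide expression range is what makes the design discriminating: an
  attenuation-biased estimator ranks high-expression background edges
  above low-expression within-cluster edges and scrambles the clusters,
  while the model-based estimate recovers them.
* **Differential null**: two groups of 500 cells from one generative
  model at $p = 50$, $B = 100$ permutations.

## Known limitations

* Moment-based variance estimates can be negative for genes expressed in
  a handful of cells; such genes are excluded from the network rather than
  rescued. At four decades of dynamic range this affects a few percent of
  genes at $n = 1000$.
* The asymptotic normal null for $T$ relies on $n$ moderately large;
  calibration is verified at $n \approx 1000$, not at tens of cells.
* Cells are assumed pre-assigned to a single type and exchangeable;
  between-individual heterogeneity is not modelled.
* The constraint $\sum_j \mu_j = 1$ of the full-transcriptome model is not
  enforced on gene panels; $\hat\mu$ is relative to the depths supplied.
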