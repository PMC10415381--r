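# umicoex

Cell-type-specific gene co-expression estimation and testing from
single-cell RNA-seq UMI counts.

## The problem

Droplet-based scRNA-seq measures the expression of gene *j* in cell *i* as a
UMI count *x*<sub>ij</sub>, while the quantity whose correlations define
co-expression is the latent relative expression *z*<sub>ij</sub> — the
fraction of the cell's molecules contributed by the gene. Two features of
the data break naive correlation analysis of counts or of normalized
counts:

* **Sequencing depth variation.** Depths *s*<sub>i</sub> (total UMIs per
  cell) commonly span 400–20,000 in one experiment. Depth acts as a shared
  multiplicative factor across genes, so independent genes appear
  correlated; log- or scale-normalization does not remove the artifact.
* **Measurement error.** Counts are noisy Poisson readouts of
  *s*<sub>i</sub>*z*<sub>ij</sub>. This attenuates count-based correlations
  by a factor that grows toward 1 with expression level, so highly expressed
  genes spuriously look more co-expressed (the mean-correlation bias).

## The model and estimator

The package models, for cells of one type,

```
(z_i1, ..., z_ip) ~ F_p(mu, Sigma),    x_ij | z_ij ~ Poisson(s_i z_ij),
```

with no distributional assumption on *F*<sub>p</sub>, and defines
co-expression as `rho_jj' = sigma_jj' / sqrt(sigma_jj sigma_j'j')`, the
correlation of the latent expressions. First and second moments are
estimated from the regression equations implied by the model,

```
x_ij                         = s_i mu_j                      + e_ij
(x_ij - s_i mu_j)^2          = s_i mu_j + s_i^2 sigma_jj     + eta_ij
(x_ij - s_i mu_j)(x_ij'-...) = s_i^2 sigma_jj'               + xi_ijj'
```

by iteratively re-weighted least squares: weights
`w_ij = 1/(s_i mu_j + s_i^2 mu_j^2 theta)` are the inverse residual
variances with the over-dispersion `theta = sigma_jj / mu_j^2` regularized
across genes by its median, `h = w^2` for variances and `g = w_j w_j'` for
covariances. Each update has a closed form; the procedure typically
converges in a handful of iterations (tolerance 0.05 on the max change of
`log sigma_jj`). Pairwise independence is tested with the standardized
covariance statistic *T*, asymptotically N(0,1) under the null, with
Benjamini-Hochberg control across all pairs.

Around the estimator, the package provides a Gamma-Poisson Gaussian-copula
count simulator, a permutation + Poisson-resampling null generator,
Pearson/Spearman-on-normalized-counts baselines with the conventional
normal-theory test, two-group differential co-expression with a
label-permutation test, topological-overlap module extraction, and
evaluation metrics (attenuation factor, precision-recall, adjusted Rand
index, subspace distance).

## Worked example

```r
library(umicoex)

# simulate 800 cells x 60 genes: three planted co-expression clusters
# (copula correlation 0.6), long-tailed depths with median 5000
marg <- default_marginals(60, mu_range = c(1e-4, 1e-2), seed = 1)
R <- block_correlation(60, 3, within = 0.6)
spec <- simulation_spec(marg$mu, marg$sigma_jj, R,
                        depths = list(model = "lognormal", median = 5000),
                        n_cells = 800, seed = 2)
cm <- simulate_counts(spec)
cm
#> count_matrix: 800 cells x 60 genes; depth median 5167.5 (range 1282-21192)

net <- estimate_network(cm)
net
#> coexp_result: 60 genes (1770 pairs)
#>   theta = 0.4875; 0 flagged gene(s); 0 clipped correlation(s)
#>   582 pair(s) with q < 0.05
```

`theta` is the regularized over-dispersion (truth here: 0.5); the 582
pairs at q < 0.05 are essentially the 570 within-cluster pairs plus a
handful of borderline background pairs. The strongest edges sit inside the
planted clusters with `rho` near the simulated 0.6:

```r
edges <- as_edge_list(net)
head(edges[order(edges$pval), ], 3)
#>     gene_i gene_j       rho    tstat         pval         qval
#> 616    g21    g36 0.6313835 18.08486 4.193947e-73 7.423286e-70
#> 624    g29    g36 0.6291315 17.62333 1.631072e-69 1.443498e-66
#> 399    g21    g29 0.6123081 17.41673 6.160252e-68 3.634549e-65

modules <- extract_modules(net$rho, k = 3)
adjusted_rand_index(modules, attr(R, "labels"))
#> [1] 1
```

A thin command-line wrapper over the same functions is installed at
`inst/cli/umicoex.R` (subcommands `estimate`, `simulate`, `permute-null`,
`diff`, `eval`).

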