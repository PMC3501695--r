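# spfa: spatial factor analysis of population genetic structure

In species with spatially limited dispersal, allele frequencies are
autocorrelated in geographic space ("isolation by distance", IBD). When a
genotype matrix from such a species is ordinated with PCA, the leading
components pick up this autocorrelation and draw sinusoidal gradients and
horseshoe-shaped point clouds that reflect the geometry of the habitat, not
population history. Real genetic discontinuities — say, two populations
separated by a barrier to gene flow — are blurred or masked by these
artifacts.

`spfa` implements **spatial factor analysis**, a low-rank factor model that
removes IBD autocorrelation before the ordination. The model is

```
G = U V + E,      E[, l] ~ N(0, Sigma_theta),
Sigma_theta[i, j] = exp( -d(X_i, X_j) / theta ),
```

where `G` is the column-standardized n x L genotype matrix, `U` (n x K) are
factor scores, `V` (K x L) are loadings with orthonormal rows
(`V V' = I_K`), and the residual columns share an exponential (kriging)
spatial covariance over the individuals' coordinates `X` with scale
`theta`. The fit whitens the data with the Cholesky inverse `C`
(`C'C = Sigma_theta^{-1}`), takes a rank-K SVD of `C G`, maps the fitted
part back through `C^{-1}`, and re-factorizes — a few triangular solves and
SVDs, so it scales like ordinary PCA. As `theta -> 0` the model *is*
ordinary PCA; larger `theta` absorbs spatial structure up to roughly that
scale into the residuals, removing it from the factors.

Because the right scale is not known in advance, the package scans a grid
of ratios `theta / d-bar` (d-bar = mean pairwise distance) and selects the
scale minimizing **Wilks' Lambda** `det(W)/det(W + B)` of the factor scores
for a candidate grouping — small Lambda means the groups separate well
after the spatial noise at that scale has been removed.

The package also provides:

* a structured-coalescent simulator (`simulate_stepping_stone`, Rcpp) for
  linear stepping-stone habitats with a divergence-time barrier, the
  standard validation design for spatial ordination methods;
* a Gaussian fixture generator with exact exponential covariance
  (`gaussian_fixture`) for algebra-level validation;
* Moran's I diagnostics (`moran_I`, `build_weights`) for factor maps;
* a baseline genotype PCA (`spfa_pca`), delimited/VCF readers, writers,
  and a command-line interface (`spfa_cli`, `inst/cli/spfa-cli.R`).

## Worked example

Two populations of 50 demes each sit on a line with a barrier in the
middle; adjacent demes exchange migrants at 4Nm = 1 and the populations
diverged tau = 10 coalescent units ago. PCA barely separates them because
the within-population IBD gradients dominate the leading components.

```r
library(spfa)

sim  <- simulate_stepping_stone(tau = 10, n_snps = 10000, seed = 42)
scan <- theta_scan(sim, K = 2)
scan
#> theta scan (K = 2, metric = euclidean): 30 ratios in [0.01, 10]
#> minimum Wilks' Lambda = 0.02241 at theta/d-bar = 0.2212

fit <- spfa(sim, K = 2, theta_ratio = scan$argmin_ratio)
fit
#> Spatial factor analysis fit: 100 individuals x 10000 loci, K = 2
#> theta = 7.448 (theta/d-bar = 0.2212, metric = euclidean)
#> singular values: 623.4, 103.5

wilks_lambda(spfa_pca(sim, K = 2)$scores, sim$labels)   # 0.1683
wilks_lambda(fit$scores, sim$labels)                    # 0.0224
```

The scan finds its minimum at `theta/d-bar` around 0.2; at that scale the
spFA scores separate the two sides of the barrier about seven times more
sharply than PCA (Wilks' Lambda 0.022 vs 0.168). Factor 1 is a step
function across the barrier (left/right means -56 and +56), the signature
of a genuine discontinuity rather than a smooth cline, and `plot(fit)`
draws the factor maps along the transect.

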