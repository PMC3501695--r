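Package: spfa
Title: Spatial Factor Analysis of Population Genetic Structure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Low-rank factor analysis of genotype matrices that corrects for
    spatial autocorrelation generated by isolation-by-distance. Residual
    spatial covariance is modelled with an exponential (kriging) kernel and
    removed by Cholesky whitening before a rank-K singular value
    decomposition, so that principal-component-like factor maps are freed of
    the horseshoe and sinusoidal artifacts that continuous gene flow imprints
    on ordinations. Includes Wilks' Lambda scale selection over a grid of
    spatial scales, Moran's I diagnostics, a baseline genotype PCA, a
    stepping-stone coalescent simulator for method validation, readers and
    writers for delimited and VCF genotype data, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils,
    graphics,
    grDevices,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
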