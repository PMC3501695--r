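test_that("simulations are deterministic given the seed", {
  s1 <- simulate_stepping_stone(n_demes_per_pop = 6, n_snps = 300, seed = 9)
  s2 <- simulate_stepping_stone(n_demes_per_pop = 6, n_snps = 300, seed = 9)
  expect_identical(s1$genotypes, s2$genotypes)
  s3 <- simulate_stepping_stone(n_demes_per_pop = 6, n_snps = 300, seed = 10)
  expect_false(identical(s1$genotypes, s3$genotypes))
})

test_that("simulated structure matches the model definition", {
  sim <- simulate_stepping_stone(n_demes_per_pop = 8, tau = 2,
                                 samples_per_deme = 2, n_snps = 200,
                                 seed = 4)
  expect_equal(nrow(sim$genotypes), 2 * 8 * 2)
  expect_true(all(sim$genotypes %in% 0:2))
  # every SNP polymorphic in the total sample (haplotype level guarantees
  # at least variance at the allele level; genotype columns may rarely be
  # constant and are then dropped downstream)
  freq <- colMeans(sim$genotypes) / 2
  expect_true(all(freq > 0 & freq < 1))
  expect_equal(as.vector(table(sim$labels)), c(16, 16))
  # coordinates increase along the line; labels split at the barrier
  expect_true(all(diff(unique(sim$coords[, 1])) > 0))
  expect_equal(unname(sim$coords[, 1] <= 8), sim$labels == "pop1")
})

test_that("genetic similarity decays with distance under pure IBD", {
  sim <- simulate_stepping_stone(n_demes_per_pop = 25, tau = 0,
                                 n_snps = 1500, seed = 2)
  std <- center_scale(sim$genotypes)
  Cs <- tcrossprod(std$values) / ncol(std$values)
  D <- pairwise_distances(sim$coords)$values
  ut <- upper.tri(D)
  expect_lt(cor(D[ut], Cs[ut], method = "spearman"), -0.3)
})

test_that("oscillating PC maps appear under pure IBD", {
  sim <- simulate_stepping_stone(n_demes_per_pop = 25, tau = 0,
                                 n_snps = 1500, seed = 2)
  p <- spfa_pca(sim, K = 1)
  W <- build_weights(sim$coords, scheme = "lattice_adjacency")
  expect_gt(abs(moran_I(p$scores[, 1], W)), 0.5)
})

test_that("swapping population labels leaves Wilks' Lambda unchanged", {
  sim <- simulate_stepping_stone(n_demes_per_pop = 10, tau = 5,
                                 n_snps = 400, seed = 6)
  p <- spfa_pca(sim, K = 2)
  lab2 <- factor(ifelse(sim$labels == "pop1", "pop2", "pop1"))
  expect_equal(wilks_lambda(p$scores, sim$labels),
               wilks_lambda(p$scores, lab2), tolerance = 1e-12)
})

test_that("long divergence separates the populations in PCA", {
  sim <- simulate_stepping_stone(tau = 100, n_snps = 10000, seed = 1)
  p <- spfa_pca(sim, K = 2)
  expect_lt(wilks_lambda(p$scores, sim$labels), 0.2)
})

test_that("invalid simulation parameters are rejected", {
  expect_error(simulate_stepping_stone(n_demes_per_pop = 0), ">= 1")
  expect_error(simulate_stepping_stone(four_Nm = 0), "positive")
  expect_error(simulate_stepping_stone(tau = -1), ">= 0")
})

test_that("gaussian fixture columns have the exponential covariance", {
  fx <- gaussian_fixture(n = 30, L = 5000, theta_true = 4, group_shift = 0,
                         seed = 3)
  D <- abs(outer(1:30, 1:30, "-"))
  S <- exp(-D / 4)
  emp <- tcrossprod(fx$genotypes) / ncol(fx$genotypes)
  expect_lt(max(abs(emp - S)), 0.1)
})

test_that("whitening at the generating scale decorrelates fixture rows", {
  fx <- gaussian_fixture(n = 30, L = 5000, theta_true = 4, group_shift = 0,
                         seed = 8)
  D <- pairwise_distances(fx$coords)
  Cw <- whitening_transform(spatial_covariance(D, theta = 4))
  Yw <- Cw$C %*% fx$genotypes
  Cr <- cor(t(Yw))
  expect_lt(mean(abs(Cr[upper.tri(Cr)])), 0.05)
})

test_that("fixture quantization produces genotype-valued entries", {
  fx <- gaussian_fixture(n = 10, L = 50, theta_true = 2, seed = 1,
                         quantize = TRUE)
  expect_true(all(fx$genotypes %in% 0:2))
  expect_identical(fx$genotypes,
                   gaussian_fixture(n = 10, L = 50, theta_true = 2, seed = 1,
                                    quantize = TRUE)$genotypes)
})

test_that("growing theta removes IBD factors sequentially in amplitude", {
  # Under pure IBD there is no true low-rank structure: as theta grows, the
  # fitted factors collapse one by one to the sampling-noise floor of the
  # singular spectrum, finest scale first.
  sim <- simulate_stepping_stone(tau = 0, n_snps = 3000, seed = 1)
  d_at <- function(r) spfa(sim, K = 3, theta_ratio = r)$d
  d1 <- d_at(0.1); d2 <- d_at(0.2); d5 <- d_at(0.5)
  # ratio 0.1: all three factors carry structure well above the noise floor
  expect_gt(d1[3] / d5[3], 3)
  # ratio 0.2: factors 2-3 have collapsed, factor 1 still structured
  expect_gt(d2[1] / d2[2], 4)
  expect_lt(d2[2], d1[2] / 2)
  # ratio 0.5: the whole spectrum sits at the noise floor
  expect_lt(d5[1] / d5[3], 1.5)
})
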