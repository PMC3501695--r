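#' Stepping-stone coalescent simulation of two diverging populations
#'
#' Simulates diploid genotypes under a linear stepping-stone model: two
#' populations of `n_demes_per_pop` demes each are arranged on a line with a
#' barrier between them; adjacent demes within a population exchange
#' migrants at scaled rate `4Nm = four_Nm`, there is no gene flow across the
#' barrier more recently than the divergence time `tau`, and earlier than
#' `tau` the two arrays form one continuous stepping stone (so `tau = 0` is
#' a single equilibrium isolation-by-distance population). Each SNP is an
#' independent coalescent realization carrying one segregating mutation
#' (dropped uniformly on the tree's branch length), so all loci are
#' polymorphic in the haplotype sample.
#'
#' Conventions: `tau` is in Kingman coalescent units of 2N generations for
#' a diploid deme (the time scale on which a pair of lineages in one deme
#' coalesces at rate 1); it is converted internally to the event
#' simulator's clock. `four_Nm` follows the Kimura-Weiss stepping-stone
#' parameterization: `m` is a deme's total migrant fraction per generation,
#' exchanged half with each adjacent neighbour, so the scaled per-lineage
#' per-neighbour backward migration rate is `four_Nm / 2`.
#'
#' Demes sit at integer coordinates `1..2*n_demes_per_pop` on a line (y = 0)
#' with the barrier at the midpoint; individuals inherit their deme's
#' coordinates (tied coordinates from `samples_per_deme > 1` are jittered
#' downstream by the fitting functions).
#'
#' @param n_demes_per_pop demes in each of the two populations (default 50).
#' @param four_Nm scaled migration rate between adjacent demes (default 1).
#' @param tau divergence time in coalescent units of 2N generations
#'   (default 0 = pure isolation by distance).
#' @param samples_per_deme diploid individuals sampled per deme (default 1).
#' @param n_snps number of independent SNPs (default 10000).
#' @param seed integer seed; simulations are reproducible given the seed.
#' @return A list of class `"spfa_sim"` with `genotypes` (`n x L` 0/1/2
#'   matrix with individual and locus names), `coords` (`n x 2`),
#'   `labels` (factor, `pop1`/`pop2` by side of the barrier), and `params`.
#' @examples
#' sim <- simulate_stepping_stone(n_demes_per_pop = 5, n_snps = 100, seed = 1)
#' table(sim$labels)
#' @export
simulate_stepping_stone <- function(n_demes_per_pop = 50L, four_Nm = 1,
                                    tau = 0, samples_per_deme = 1L,
                                    n_snps = 10000L, seed = 1L) {
  n_demes_per_pop <- as.integer(n_demes_per_pop)
  samples_per_deme <- as.integer(samples_per_deme)
  n_snps <- as.integer(n_snps)
  if (n_demes_per_pop < 1L) stop("n_demes_per_pop must be >= 1")
  if (samples_per_deme < 1L) stop("samples_per_deme must be >= 1")
  if (n_snps < 1L) stop("n_snps must be >= 1")
  if (!is.numeric(four_Nm) || four_Nm <= 0) stop("four_Nm must be positive")
  if (!is.numeric(tau) || tau < 0) stop("tau must be >= 0")

  n_demes <- 2L * n_demes_per_pop
  set.seed(seed)
  # the C++ event clock runs in 4N-generation units; tau is given in
  # Kingman units of 2N generations
  G <- sim_stepping_stone_cpp(n_demes, four_Nm / 2, tau / 2,
                              samples_per_deme, n_snps, 2L)
  n <- nrow(G)
  deme <- rep(seq_len(n_demes), each = samples_per_deme)
  ids <- sprintf("ind_%03d", seq_len(n))
  rownames(G) <- ids
  colnames(G) <- sprintf("snp_%05d", seq_len(n_snps))
  coords <- cbind(x = as.numeric(deme), y = 0)
  rownames(coords) <- ids
  labels <- factor(ifelse(deme <= n_demes_per_pop, "pop1", "pop2"),
                   levels = c("pop1", "pop2"))
  structure(list(genotypes = G, coords = coords, labels = labels,
                 params = list(n_demes_per_pop = n_demes_per_pop,
                               four_Nm = four_Nm, tau = tau,
                               samples_per_deme = samples_per_deme,
                               n_snps = n_snps, seed = as.integer(seed),
                               ploidy = 2L,
                               generator = "stepping_stone")),
            class = "spfa_sim")
}

#' Gaussian fixture with exact exponential spatial covariance
#'
#' Generates continuous data whose columns have exactly the exponential
#' covariance `exp(-d / theta_true)` over `n` points equispaced on a line,
#' plus an optional mean shift of `-group_shift/2` for the first half of the
#' individuals and `+group_shift/2` for the second half. Because the spatial
#' covariance is exact, the fixture exercises the whitening algebra without
#' coalescent noise: whitening at `theta_true` decorrelates the rows, and a
#' moderate `group_shift` makes the Wilks-Lambda scale scan recover
#' `theta_true`. The default shift (0.5, i.e. a quarter of the unit spatial
#' standard deviation on each side) keeps group signal and spatial noise of
#' comparable size, which is the regime where scale selection is
#' informative; much larger shifts make every scale separate the groups
#' perfectly and the scan degenerates.
#'
#' @param n individuals (points on the line), `>= 2`.
#' @param L number of columns, `>= 2`.
#' @param theta_true generating spatial scale (distance units).
#' @param group_shift difference between the two halves' means (default 0.5).
#' @param seed integer seed.
#' @param quantize convert to 0/1/2 genotypes by column terciles (default
#'   `FALSE`; continuous data exercise the linear algebra exactly).
#' @return A list of class `"spfa_sim"` like [simulate_stepping_stone()],
#'   with `params$generator = "gaussian"` and `params$theta_true`.
#' @export
gaussian_fixture <- function(n, L, theta_true, group_shift = 0.5, seed = 1L,
                             quantize = FALSE) {
  n <- as.integer(n); L <- as.integer(L)
  if (n < 2L || L < 2L) stop("n and L must be >= 2")
  if (!is.numeric(theta_true) || theta_true <= 0)
    stop("theta_true must be positive")
  x <- seq_len(n)
  D <- abs(outer(x, x, "-"))
  S <- exp(-D / theta_true)
  Lc <- t(chol(S))
  set.seed(seed)
  Z <- matrix(stats::rnorm(n * L), n, L)
  half <- n %/% 2L
  mu <- c(rep(-group_shift / 2, half), rep(group_shift / 2, n - half))
  Y <- Lc %*% Z + mu
  if (quantize) {
    Y <- apply(Y, 2L, function(col) {
      q <- stats::quantile(col, c(1 / 3, 2 / 3))
      as.integer(cut(col, c(-Inf, q, Inf))) - 1L
    })
  }
  ids <- sprintf("ind_%03d", x)
  rownames(Y) <- ids
  colnames(Y) <- sprintf("var_%05d", seq_len(L))
  coords <- cbind(x = as.numeric(x), y = 0)
  rownames(coords) <- ids
  labels <- factor(c(rep("pop1", half), rep("pop2", n - half)),
                   levels = c("pop1", "pop2"))
  structure(list(genotypes = Y, coords = coords, labels = labels,
                 params = list(n = n, L = L, theta_true = theta_true,
                               group_shift = group_shift,
                               seed = as.integer(seed), quantize = quantize,
                               generator = "gaussian")),
            class = "spfa_sim")
}

#' @export
print.spfa_sim <- function(x, ...) {
  p <- x$params
  cat(sprintf("simulated dataset (%s): %d individuals x %d loci\n",
              p$generator, nrow(x$genotypes), ncol(x$genotypes)))
  if (p$generator == "stepping_stone")
    cat(sprintf("  demes/pop = %d, 4Nm = %g, tau = %g, seed = %d\n",
                p$n_demes_per_pop, p$four_Nm, p$tau, p$seed))
  invisible(x)
}
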