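#' Wilks-Lambda scan over spatial scales
#'
#' Fits the spatial factor model over a grid of scale ratios `theta / d-bar`
#' and records Wilks' Lambda of the `K` factor scores for a given grouping.
#' The ratio minimizing Lambda is the scale at which the factors separate
#' the groups best, the criterion used to select `theta`.
#'
#' @param genotypes genotype matrix or `"spfa_sim"` object (whose labels are
#'   then the default `groups`).
#' @param coords coordinates (default: taken from the simulation object).
#' @param groups group labels for [wilks_lambda()].
#' @param K number of factors (default 2).
#' @param grid increasing vector of positive `theta / d-bar` ratios; default
#'   30 logarithmically spaced points on `[0.01, 10]`.
#' @param metric,radius,jitter_seed see [spfa()].
#' @return A list of class `"spfa_scan"`: `grid`, `lambdas`, `argmin_ratio`,
#'   `argmin_theta`, `K`, `d_bar`, `metric`.
#' @seealso [spfa()], [wilks_lambda()]
#' @export
theta_scan <- function(genotypes, coords = NULL, groups = NULL, K = 2L,
                       grid = default_theta_grid(),
                       metric = c("euclidean", "sq_euclidean",
                                  "great_circle"),
                       radius = 1, jitter_seed = 1L) {
  metric <- match.arg(metric)
  if (inherits(genotypes, "spfa_sim")) {
    if (is.null(coords)) coords <- genotypes$coords
    if (is.null(groups)) groups <- genotypes$labels
    genotypes <- genotypes$genotypes
  }
  if (is.null(coords) || is.null(groups))
    stop("coords and groups are required")
  if (length(grid) < 1L || any(!is.finite(grid)) || any(grid <= 0))
    stop("grid must be positive and non-empty")
  if (is.unsorted(grid, strictly = TRUE))
    stop("grid must be strictly increasing")

  std <- center_scale(genotypes)
  X <- if (inherits(coords, "spfa_coords")) coords else
    prepare_coordinates(coords,
                        frame = if (metric == "great_circle") "lonlat"
                                else "planar",
                        jitter_seed = jitter_seed)
  Dd <- pairwise_distances(X, metric = metric, radius = radius)
  K <- as.integer(K)

  lambdas <- vapply(grid, function(r) {
    f <- tryCatch(spfa_fit_std(std$values, Dd, r * Dd$mean_pairwise, K),
                  error = function(e)
                    stop(sprintf("scan failed at ratio %.4g: %s", r,
                                 conditionMessage(e)), call. = FALSE))
    wilks_lambda(f$scores, groups)
  }, numeric(1L))

  i <- which.min(lambdas)
  structure(list(grid = grid, lambdas = lambdas,
                 argmin_ratio = grid[i],
                 argmin_theta = grid[i] * Dd$mean_pairwise,
                 K = K, d_bar = Dd$mean_pairwise, metric = metric),
            class = "spfa_scan")
}

#' Default scale-ratio grid
#'
#' 30 logarithmically spaced `theta / d-bar` ratios spanning 0.01 to 10.
#'
#' @param n_points number of grid points (default 30).
#' @param lo,hi grid range (defaults 0.01 and 10).
#' @return numeric vector of ratios.
#' @export
default_theta_grid <- function(n_points = 30L, lo = 0.01, hi = 10) {
  exp(seq(log(lo), log(hi), length.out = n_points))
}

#' @export
print.spfa_scan <- function(x, ...) {
  cat(sprintf(
    "theta scan (K = %d, metric = %s): %d ratios in [%.3g, %.3g]\n",
    x$K, x$metric, length(x$grid), min(x$grid), max(x$grid)))
  cat(sprintf("minimum Wilks' Lambda = %.4g at theta/d-bar = %.4g\n",
              min(x$lambdas), x$argmin_ratio))
  invisible(x)
}

#' @export
as.data.frame.spfa_scan <- function(x, ...)
  data.frame(ratio = x$grid, lambda = x$lambdas)

#' @export
plot.spfa_scan <- function(x, ...) {
  graphics::plot(x$grid, x$lambdas, log = "x", type = "b",
                 xlab = "theta / d-bar", ylab = "Wilks' Lambda", ...)
  graphics::abline(v = x$argmin_ratio, lty = 2)
  invisible(x)
}

#' Wilks-Lambda comparison of PCA and spFA across divergence times
#'
#' For each divergence time `tau`, simulates stepping-stone datasets,
#' fits both genotype PCA and the spatial factor model, and records the mean
#' Wilks' Lambda of the barrier-side grouping per method. The spatial scale
#' is either the fixed `theta_ratio` (default 0.32, the scan-selected value
#' for this design) or re-selected per replicate by [theta_scan()] when
#' `scan = TRUE`.
#'
#' @param tau_values divergence times to simulate.
#' @param n_demes_per_pop,four_Nm,samples_per_deme,n_snps simulation
#'   parameters, see [simulate_stepping_stone()].
#' @param K factors (default 2).
#' @param replicates simulation replicates per `tau` (default 3).
#' @param seed master seed; per-replicate seeds are derived from it.
#' @param theta_ratio fixed scale ratio for spFA (default 0.32).
#' @param scan if `TRUE`, select the ratio per replicate by a scan.
#' @param grid scan grid when `scan = TRUE`.
#' @return A data frame of class `"spfa_comparison"` with columns `tau`,
#'   `method` (`pca` / `spfa`), `lambda` (mean over replicates) and
#'   `replicates`.
#' @export
method_comparison_curve <- function(tau_values, n_demes_per_pop = 50L,
                                    four_Nm = 1, samples_per_deme = 1L,
                                    n_snps = 10000L, K = 2L,
                                    replicates = 3L, seed = 1L,
                                    theta_ratio = 0.32, scan = FALSE,
                                    grid = default_theta_grid()) {
  if (length(tau_values) < 1L) stop("tau_values must be non-empty")
  replicates <- as.integer(replicates)
  if (replicates < 1L) stop("replicates must be >= 1")
  set.seed(seed)
  seeds <- matrix(sample.int(.Machine$integer.max, length(tau_values) *
                               replicates),
                  nrow = replicates)
  rows <- list()
  for (ti in seq_along(tau_values)) {
    tau <- tau_values[ti]
    lp <- ls <- numeric(replicates)
    for (r in seq_len(replicates)) {
      sim <- tryCatch(
        simulate_stepping_stone(n_demes_per_pop = n_demes_per_pop,
                                four_Nm = four_Nm, tau = tau,
                                samples_per_deme = samples_per_deme,
                                n_snps = n_snps, seed = seeds[r, ti]),
        error = function(e)
          stop(sprintf("simulation failed at tau = %g, replicate %d: %s",
                       tau, r, conditionMessage(e)), call. = FALSE))
      p <- spfa_pca(sim, K = K)
      lp[r] <- wilks_lambda(p$scores, sim$labels)
      if (scan) {
        sc <- theta_scan(sim, K = K, grid = grid)
        ls[r] <- min(sc$lambdas)
      } else {
        f <- spfa(sim, K = K, theta_ratio = theta_ratio)
        ls[r] <- wilks_lambda(f$scores, sim$labels)
      }
    }
    rows[[length(rows) + 1L]] <-
      data.frame(tau = tau, method = c("pca", "spfa"),
                 lambda = c(mean(lp), mean(ls)), replicates = replicates)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("spfa_comparison", "data.frame")
  out
}
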