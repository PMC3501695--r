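# Rank-K SVD. For wide matrices (L >> n) the left factor comes from an
# eigendecomposition of the n x n Gram matrix, which is much cheaper than a
# full SVD and exact for the leading factors.
svd_rank <- function(A, K) {
  n <- nrow(A); L <- ncol(A)
  if (L >= n) {
    E <- eigen(tcrossprod(A), symmetric = TRUE)
    d <- sqrt(pmax(E$values, 0))
    U <- E$vectors[, seq_len(K), drop = FALSE]
    dK <- d[seq_len(K)]
    if (any(dK <= 0)) stop("matrix rank below K")
    Vt <- sweep(crossprod(U, A), 1L, dK, "/")
    list(u = U, d = dK, vt = Vt, d_all = d)
  } else {
    s <- svd(A)
    list(u = s$u[, seq_len(K), drop = FALSE], d = s$d[seq_len(K)],
         vt = t(s$v[, seq_len(K), drop = FALSE]), d_all = s$d)
  }
}

# Deterministic sign convention: per factor, the loading entry of largest
# absolute value is made positive (ties resolved to the lowest locus index,
# which is what which.max returns).
apply_sign_convention <- function(scores, loadings) {
  for (k in seq_len(nrow(loadings))) {
    j <- which.max(abs(loadings[k, ]))
    if (loadings[k, j] < 0) {
      loadings[k, ] <- -loadings[k, ]
      scores[, k] <- -scores[, k]
    }
  }
  list(scores = scores, loadings = loadings)
}

# Core spatial factor fit on an already standardized matrix and distance
# object; shared by spfa() and theta_scan().
spfa_fit_std <- function(Gstd, Ddist, theta, K) {
  n <- nrow(Gstd)
  S <- spatial_covariance(Ddist, theta)
  L <- S$chol_lower
  Gw <- forwardsolve(L, Gstd)                  # C G, C = L^{-1}
  s1 <- svd_rank(Gw, K)
  # back-transform the rank-K fit: M = C^{-1} (U~ S~ V~') = (L U~ S~) V~'
  B <- L %*% sweep(s1$u, 2L, s1$d, "*")
  s2 <- svd(B)
  scores <- s2$u %*% diag(s2$d, K, K)
  loadings <- crossprod(s2$v, s1$vt)           # rows orthonormal
  sg <- apply_sign_convention(scores, loadings)
  list(scores = sg$scores, loadings = sg$loadings, d = s2$d,
       d_whitened = s1$d, jitter = S$jitter)
}

#' Spatial factor analysis of a genotype matrix
#'
#' Fits the rank-`K` factor model `G = U V + E` in which the residuals `E`
#' are spatially autocorrelated across individuals with exponential
#' covariance `Sigma[i, j] = exp(-d(X_i, X_j) / theta)`. The fit whitens the
#' standardized genotypes with the Cholesky inverse `C` (`C'C = Sigma^{-1}`),
#' takes a rank-`K` SVD of `C G`, back-transforms the fitted part through
#' `C^{-1}`, and re-factorizes, so the returned loadings `V` have orthonormal
#' rows (`V V' = I_K`) and the scores are left singular vectors scaled by
#' their singular values (as in [stats::prcomp()]). With very small `theta`
#' the model reduces to ordinary genotype PCA (see [spfa_pca()]).
#'
#' @param genotypes `n x L` matrix of allele counts 0/1/2 (NA allowed), any
#'   numeric matrix, or a [simulate_stepping_stone()] /
#'   [gaussian_fixture()] result (in which case `coords` defaults to the
#'   simulated coordinates).
#' @param coords `n x 2` coordinate matrix or an [prepare_coordinates()]
#'   object.
#' @param K number of factors, `1 <= K <= min(n, L')`.
#' @param theta spatial scale in distance units; give exactly one of `theta`
#'   and `theta_ratio`.
#' @param theta_ratio spatial scale as a multiple of the mean pairwise
#'   distance d-bar.
#' @param metric distance metric, see [pairwise_distances()].
#' @param radius sphere radius for the `great_circle` metric.
#' @param jitter_seed seed for coordinate tie-breaking.
#' @return An object of class `"spfa"`; see Details.
#' @details The returned object is a list with components `scores` (`n x K`),
#'   `loadings` (`K x L'`, orthonormal rows), `d` (singular values),
#'   `d_whitened` (singular values of the whitened matrix `C G`, a useful
#'   diagnostic: factors whose spatial signal has been absorbed into the
#'   residual covariance collapse to the noise floor), `K`, `theta`,
#'   `theta_ratio`, `d_bar`, `metric`, `method` (`"spfa"` or `"pca"`),
#'   `standardize` (the [center_scale()] result), `coords`, `n`, `L`, and
#'   `call`.
#' @seealso [spfa_pca()], [theta_scan()], [moran_I()]
#' @examples
#' sim <- simulate_stepping_stone(n_demes_per_pop = 5, n_snps = 200, seed = 1)
#' fit <- spfa(sim, K = 2, theta_ratio = 0.3)
#' fit
#' @export
spfa <- function(genotypes, coords = NULL, K = 2L, theta = NULL,
                 theta_ratio = NULL,
                 metric = c("euclidean", "sq_euclidean", "great_circle"),
                 radius = 1, jitter_seed = 1L) {
  metric <- match.arg(metric)
  cl <- match.call()
  if (inherits(genotypes, "spfa_sim")) {
    if (is.null(coords)) coords <- genotypes$coords
    genotypes <- genotypes$genotypes
  }
  if (is.null(coords)) stop("coords are required")
  if (is.null(theta) + is.null(theta_ratio) != 1L)
    stop("give exactly one of theta and theta_ratio")

  std <- center_scale(genotypes)
  X <- if (inherits(coords, "spfa_coords")) coords else
    prepare_coordinates(coords,
                        frame = if (metric == "great_circle") "lonlat"
                                else "planar",
                        jitter_seed = jitter_seed)
  Dd <- pairwise_distances(X, metric = metric, radius = radius)
  if (is.null(theta)) theta <- theta_ratio * Dd$mean_pairwise
  if (!is.numeric(theta) || theta <= 0) stop("theta must be positive")

  n <- nrow(std$values); Lp <- ncol(std$values)
  K <- as.integer(K)
  if (K < 1L || K > min(n, Lp))
    stop(sprintf("K must be between 1 and %d", min(n, Lp)))

  f <- spfa_fit_std(std$values, Dd, theta, K)
  ids <- rownames(std$values)
  if (!is.null(ids)) rownames(f$scores) <- ids
  colnames(f$scores) <- paste0("F", seq_len(K))
  rownames(f$loadings) <- paste0("F", seq_len(K))
  colnames(f$loadings) <- colnames(std$values)

  structure(list(scores = f$scores, loadings = f$loadings, d = f$d,
                 d_whitened = f$d_whitened, K = K, theta = theta,
                 theta_ratio = theta / Dd$mean_pairwise,
                 d_bar = Dd$mean_pairwise, metric = metric,
                 method = "spfa", standardize = std, coords = X,
                 jitter = f$jitter, n = n, L = Lp, call = cl),
            class = "spfa")
}

#' Genotype principal component analysis
#'
#' Baseline rank-`K` PCA of the standardized genotype matrix by singular
#' value decomposition, with the same scaling (scores = left singular
#' vectors times singular values), sign convention and return class as
#' [spfa()]. Equivalent to the `theta -> 0` limit of the spatial factor
#' model.
#'
#' @inheritParams spfa
#' @param coords optional; stored for plotting only.
#' @return An object of class `"spfa"` with `method = "pca"` and
#'   `theta = NULL`.
#' @examples
#' sim <- simulate_stepping_stone(n_demes_per_pop = 5, n_snps = 200, seed = 1)
#' pc <- spfa_pca(sim, K = 2)
#' @export
spfa_pca <- function(genotypes, K = 2L, coords = NULL) {
  cl <- match.call()
  if (inherits(genotypes, "spfa_sim")) {
    if (is.null(coords)) coords <- genotypes$coords
    genotypes <- genotypes$genotypes
  }
  std <- center_scale(genotypes)
  n <- nrow(std$values); Lp <- ncol(std$values)
  K <- as.integer(K)
  if (K < 1L || K > min(n, Lp))
    stop(sprintf("K must be between 1 and %d", min(n, Lp)))
  s <- svd_rank(std$values, K)
  scores <- sweep(s$u, 2L, s$d, "*")
  sg <- apply_sign_convention(scores, s$vt)
  scores <- sg$scores; loadings <- sg$loadings
  ids <- rownames(std$values)
  if (!is.null(ids)) rownames(scores) <- ids
  colnames(scores) <- paste0("F", seq_len(K))
  rownames(loadings) <- paste0("F", seq_len(K))
  colnames(loadings) <- colnames(std$values)
  Xc <- if (is.null(coords)) NULL else if (inherits(coords, "spfa_coords"))
    coords else prepare_coordinates(coords)
  structure(list(scores = scores, loadings = loadings, d = s$d,
                 d_whitened = s$d, K = K, theta = NULL, theta_ratio = NULL,
                 d_bar = NULL, metric = NULL, method = "pca",
                 standardize = std, coords = Xc, jitter = 0,
                 n = n, L = Lp, call = cl),
            class = "spfa")
}
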