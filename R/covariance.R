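#' Exponential spatial covariance
#'
#' Builds the kriging covariance matrix `Sigma[i, j] = exp(-d(i, j) / theta)`
#' that models isolation-by-distance autocorrelation among individuals.
#' Larger `theta` means longer-range correlation; as `theta -> 0` the matrix
#' tends to the identity and the downstream factor analysis reduces to plain
#' PCA.
#'
#' If the Cholesky factorization of the matrix fails numerically (which
#' happens for very smooth kernels on dense samplings), a diagonal jitter
#' `lambda * I` is added with `lambda` escalating through 1e-10, 1e-8, 1e-6;
#' each escalation is reported as a warning and failure beyond 1e-6 is an
#' error.
#'
#' @param D an [pairwise_distances()] result (or a plain symmetric distance
#'   matrix).
#' @param theta positive scale parameter, in the units of the distance
#'   metric.
#' @return A list of class `"spfa_cov"`: `values` (the covariance matrix,
#'   including any jitter on the diagonal), `theta`, `metric`, `jitter`
#'   (the lambda actually added, 0 when none), and `chol_lower` (the lower
#'   Cholesky factor `L`, `Sigma = L L'`).
#' @export
spatial_covariance <- function(D, theta) {
  if (!is.numeric(theta) || length(theta) != 1L || !is.finite(theta) ||
      theta <= 0)
    stop("theta must be a positive number")
  metric <- NULL
  if (inherits(D, "spfa_dist")) { metric <- D$metric; D <- D$values }
  D <- as.matrix(D)
  n <- nrow(D)
  S <- exp(-D / theta)
  diag(S) <- 1

  R <- NULL
  jitter <- 0
  for (lam in c(0, 1e-10, 1e-8, 1e-6)) {
    R <- tryCatch(chol(S + diag(lam, n)), error = function(e) NULL)
    if (!is.null(R)) { jitter <- lam; break }
  }
  if (is.null(R))
    stop("covariance numerically singular; increase theta or thin coordinates")
  if (jitter > 0) {
    S <- S + diag(jitter, n)
    warning(sprintf(
      "spatial covariance required diagonal jitter %.0e for factorization",
      jitter))
  }
  structure(list(values = S, theta = theta, metric = metric,
                 jitter = jitter, chol_lower = t(R)),
            class = "spfa_cov")
}

#' Whitening operator for spatially correlated residuals
#'
#' Computes the matrix `C` with `C' C = Sigma^{-1}`, so that premultiplying
#' data by `C` turns residuals with covariance `Sigma` into uncorrelated ones
#' (`C Sigma C' = I`). `C` is taken as the inverse of the lower Cholesky
#' factor `L` of `Sigma` (`Sigma = L L'`, `C = L^{-1}`), obtained by a
#' triangular solve; the dense inverse of `Sigma` is never formed.
#'
#' @param S an [spatial_covariance()] result.
#' @return A list of class `"spfa_whitener"`: `C` (lower-triangular `n x n`
#'   whitening matrix), `chol_lower` (`L`, kept for efficient back-solves),
#'   and `theta`.
#' @examples
#' D <- pairwise_distances(cbind(1:5, 0))
#' W <- whitening_transform(spatial_covariance(D, theta = 2))
#' max(abs(W$C %*% spatial_covariance(D, 2)$values %*% t(W$C) - diag(5)))
#' @export
whitening_transform <- function(S) {
  if (!inherits(S, "spfa_cov"))
    stop("S must be a spatial covariance from spatial_covariance()")
  L <- S$chol_lower
  n <- nrow(L)
  C <- forwardsolve(L, diag(n))
  structure(list(C = C, chol_lower = L, theta = S$theta),
            class = "spfa_whitener")
}
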