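#' Spatial weight matrices
#'
#' Builds the symmetric 0/1 spatial weight matrix used by [moran_I()].
#' Two schemes are provided: `knn` connects each point to its `k` nearest
#' neighbours (symmetrized by union), and `lattice_adjacency` connects
#' pairs at the minimum positive inter-point distance, which on an
#' equispaced transect or lattice yields the neighbour graph.
#'
#' @param X coordinates (`n x 2` matrix or [prepare_coordinates()] object).
#' @param scheme `"knn"` or `"lattice_adjacency"`.
#' @param k neighbour count for `knn` (`1 <= k < n`).
#' @return A list of class `"spfa_weights"`: `W` (symmetric matrix, zero
#'   diagonal) and `scheme`.
#' @examples
#' W <- build_weights(cbind(1:4, 0), scheme = "lattice_adjacency")
#' W$W
#' @export
build_weights <- function(X, scheme = c("knn", "lattice_adjacency"),
                          k = 1L) {
  scheme <- match.arg(scheme)
  if (!inherits(X, "spfa_coords")) X <- prepare_coordinates(X)
  P <- X$points
  n <- nrow(P)
  if (n < 2L) stop("need at least 2 points")
  D <- as.matrix(stats::dist(P))
  W <- matrix(0, n, n)
  if (scheme == "knn") {
    k <- as.integer(k)
    if (k < 1L || k >= n) stop("k must satisfy 1 <= k < n")
    for (i in seq_len(n)) {
      nb <- order(D[i, -i])[seq_len(k)]
      nb <- seq_len(n)[-i][nb]
      W[i, nb] <- 1
    }
    W <- pmax(W, t(W))                 # symmetrize by union
  } else {
    offd <- D[upper.tri(D)]
    dmin <- min(offd[offd > 0])
    W[D <= dmin * (1 + 1e-9) & D > 0] <- 1
  }
  diag(W) <- 0
  structure(list(W = W, scheme = scheme), class = "spfa_weights")
}

#' Moran's I spatial autocorrelation index
#'
#' Computes the standard Moran's I of a variable over a spatial weight
#' matrix,
#' `I = (n / sum(W)) * sum_ij W_ij (g_i - gbar)(g_j - gbar) / sum_i (g_i - gbar)^2`,
#' including the conventional multiplier `n`. Values near +1 indicate smooth
#' spatial gradients, values near -1 checkerboard patterns, and values near
#' `-1/(n-1)` spatial randomness. Used here as a diagnostic for residual
#' isolation-by-distance structure in factor maps.
#'
#' @param g numeric vector of length `n` (e.g. one factor's scores); must
#'   not be constant.
#' @param W an [build_weights()] object or a non-negative `n x n` matrix
#'   with zero diagonal.
#' @return Moran's I as a single number.
#' @examples
#' W <- build_weights(cbind(1:4, 0), scheme = "lattice_adjacency")
#' moran_I(c(1, -1, 1, -1), W)   # perfect alternation: -1
#' @export
moran_I <- function(g, W) {
  if (inherits(W, "spfa_weights")) W <- W$W
  W <- as.matrix(W)
  n <- length(g)
  if (!is.numeric(g) || anyNA(g)) stop("g must be numeric and complete")
  if (nrow(W) != n || ncol(W) != n) stop("dimension mismatch between g and W")
  if (any(W < 0)) stop("weights must be non-negative")
  if (any(diag(W) != 0)) stop("weight matrix must have zero diagonal")
  s0 <- sum(W)
  if (s0 <= 0) stop("weight matrix has no positive entries")
  gc <- g - mean(g)
  ss <- sum(gc^2)
  if (ss == 0) stop("zero variance")
  (n / s0) * as.numeric(gc %*% W %*% gc) / ss
}
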