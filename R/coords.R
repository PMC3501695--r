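#' Prepare geographic coordinates for spatial analysis
#'
#' Validates an `n x 2` coordinate matrix and breaks exact ties between
#' sampling locations. Tied points are perturbed by uniform noise of
#' magnitude `1e-6` times the typical pairwise distance, applied only to the
#' duplicated rows, so that the spatial covariance matrix is non-singular.
#'
#' @param X numeric `n x 2` matrix (or data frame) of coordinates; for
#'   `frame = "lonlat"` the columns are longitude and latitude in degrees.
#' @param frame `"planar"` (default) or `"lonlat"`.
#' @param jitter logical; break ties by jittering (default `TRUE`). With
#'   `jitter = FALSE` duplicated coordinates are an error naming the rows.
#' @param jitter_seed integer seed used for the tie-breaking noise so runs
#'   are reproducible; default 1.
#' @return A list of class `"spfa_coords"` with elements `points` (the `n x 2`
#'   matrix), `frame`, `jitter_applied`, and `jitter_seed` (NULL when no
#'   jitter was needed).
#' @export
prepare_coordinates <- function(X, frame = c("planar", "lonlat"),
                                jitter = TRUE, jitter_seed = 1L) {
  frame <- match.arg(frame)
  X <- as.matrix(X)
  if (ncol(X) != 2L) stop("coordinates must have exactly 2 columns")
  if (!is.numeric(X) || anyNA(X)) stop("coordinates must be numeric and complete")
  storage.mode(X) <- "double"
  if (nrow(X) < 2L) stop("need at least 2 individuals")
  if (frame == "lonlat") {
    if (any(X[, 1L] < -180 | X[, 1L] > 180))
      stop("longitude out of range [-180, 180]")
    if (any(X[, 2L] < -90 | X[, 2L] > 90))
      stop("latitude out of range [-90, 90]")
  }

  key <- paste(X[, 1L], X[, 2L], sep = "\r")
  dup <- duplicated(key) | duplicated(key, fromLast = TRUE)
  applied <- FALSE
  if (any(dup)) {
    ids <- rownames(X)
    if (is.null(ids)) ids <- as.character(which(dup))
    else ids <- ids[dup]
    if (!jitter)
      stop("duplicated coordinates for: ", paste(unique(ids), collapse = ", "))
    # typical scale from the distinct points
    Xu <- X[!duplicated(key), , drop = FALSE]
    if (nrow(Xu) >= 2L) {
      d <- as.matrix(stats::dist(Xu))
      scale0 <- mean(d[upper.tri(d)])
    } else {
      scale0 <- max(abs(X), 1)
    }
    eps <- 1e-6 * scale0
    old_seed <- get0(".Random.seed", envir = globalenv())
    set.seed(jitter_seed)
    X[dup, ] <- X[dup, , drop = FALSE] +
      matrix(stats::runif(2L * sum(dup), -eps, eps), ncol = 2L)
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
    applied <- TRUE
    warning(sprintf("jittered %d tied coordinates (magnitude %.3g, seed %d)",
                    sum(dup), eps, jitter_seed))
    key <- paste(X[, 1L], X[, 2L], sep = "\r")
    if (anyDuplicated(key))
      stop("coordinates still duplicated after jitter; thin the input")
  }
  structure(list(points = X, frame = frame, jitter_applied = applied,
                 jitter_seed = if (applied) as.integer(jitter_seed) else NULL),
            class = "spfa_coords")
}

#' Pairwise geographic distances
#'
#' Computes the `n x n` matrix of pairwise distances used by the spatial
#' covariance kernel, together with the mean pairwise distance d-bar that
#' serves as the natural unit for the scale parameter theta.
#'
#' Metrics:
#' \describe{
#'   \item{`euclidean`}{plain Euclidean distance in planar coordinates
#'     (default). With the exponential kernel this is the
#'     Ornstein-Uhlenbeck / Matern-1/2 covariance, positive definite in any
#'     dimension.}
#'   \item{`sq_euclidean`}{squared Euclidean distance, giving a Gaussian
#'     kernel.}
#'   \item{`great_circle`}{great-circle arc length on a sphere of radius
#'     `radius` for longitude/latitude coordinates in degrees (unsquared:
#'     the exponential kernel of squared great-circle distance is not
#'     guaranteed positive definite on the sphere).}
#' }
#'
#' @param X an [prepare_coordinates()] result, or a raw `n x 2` matrix
#'   (prepared automatically; the frame is inferred from the metric).
#' @param metric one of `"euclidean"`, `"sq_euclidean"`, `"great_circle"`.
#' @param radius sphere radius for `great_circle` (default 1, i.e. distances
#'   in radians).
#' @return A list of class `"spfa_dist"`: `values` (symmetric matrix, zero
#'   diagonal), `metric`, and `mean_pairwise` (mean over the off-diagonal
#'   upper triangle).
#' @examples
#' pairwise_distances(rbind(c(0, 0), c(3, 4)), metric = "sq_euclidean")$values
#' @export
pairwise_distances <- function(X,
                               metric = c("euclidean", "sq_euclidean",
                                          "great_circle"),
                               radius = 1) {
  metric <- match.arg(metric)
  if (!inherits(X, "spfa_coords")) {
    X <- prepare_coordinates(X, frame = if (metric == "great_circle")
      "lonlat" else "planar")
  }
  P <- X$points
  n <- nrow(P)
  if (metric == "great_circle") {
    if (X$frame != "lonlat")
      stop("great_circle distances require lonlat coordinates")
    lam <- P[, 1L] * pi / 180
    phi <- P[, 2L] * pi / 180
    # central angle via the haversine form (stable for small separations)
    dphi <- outer(phi, phi, "-") / 2
    dlam <- outer(lam, lam, "-") / 2
    a <- sin(dphi)^2 + (cos(phi) %o% cos(phi)) * sin(dlam)^2
    a[a > 1] <- 1; a[a < 0] <- 0
    D <- radius * 2 * asin(sqrt(a))
  } else {
    D <- as.matrix(stats::dist(P))
    if (metric == "sq_euclidean") D <- D^2
  }
  diag(D) <- 0
  offd <- D[upper.tri(D)]
  if (any(offd <= 0))
    stop("duplicate points detected; prepare coordinates with jitter first")
  structure(list(values = D, metric = metric,
                 mean_pairwise = mean(offd)),
            class = "spfa_dist")
}
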