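#' @export
print.spfa <- function(x, ...) {
  cat(sprintf("%s fit: %d individuals x %d loci, K = %d\n",
              if (x$method == "spfa") "Spatial factor analysis" else
                "Genotype PCA", x$n, x$L, x$K))
  if (x$method == "spfa")
    cat(sprintf("theta = %.4g (theta/d-bar = %.4g, metric = %s)\n",
                x$theta, x$theta_ratio, x$metric))
  cat("singular values:", paste(sprintf("%.4g", x$d), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.spfa <- function(object, ...) {
  tot <- sum(object$standardize$values^2)
  out <- list(fit = object,
              explained = object$d^2 / tot,
              n_imputed = object$standardize$n_imputed,
              kept = length(object$standardize$kept_loci))
  class(out) <- "summary.spfa"
  out
}

#' @export
print.summary.spfa <- function(x, ...) {
  print(x$fit)
  cat(sprintf("retained loci: %d; imputed genotypes: %d\n",
              x$kept, x$n_imputed))
  cat("variance explained per factor:",
      paste(sprintf("%.3f", x$explained), collapse = ", "), "\n")
  invisible(x)
}

#' Extract factor loadings
#'
#' @param object an [spfa()] or [spfa_pca()] fit.
#' @param ... unused.
#' @return the `K x L'` loading matrix with orthonormal rows.
#' @export
coef.spfa <- function(object, ...) object$loadings

#' Low-rank fitted values on the standardized scale
#'
#' @param object an `"spfa"` fit.
#' @param ... unused.
#' @return the `n x L'` matrix `U V` approximating the standardized
#'   genotypes.
#' @export
fitted.spfa <- function(object, ...) object$scores %*% object$loadings

#' @export
residuals.spfa <- function(object, ...)
  object$standardize$values - fitted(object)

#' Project new genotypes onto fitted factors
#'
#' Standardizes `newdata` with the centring and scaling of the original fit
#' (columns restricted to the retained loci) and projects onto the loading
#' rows, returning factor scores for the new individuals.
#'
#' @param object an `"spfa"` fit.
#' @param newdata matrix of genotypes with the same loci as the training
#'   data; omitted returns the fitted scores.
#' @param ... unused.
#' @return score matrix with `K` columns.
#' @export
predict.spfa <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$scores)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) < max(object$standardize$kept_loci))
    stop("newdata has fewer loci than the training data")
  Z <- newdata[, object$standardize$kept_loci, drop = FALSE]
  Z <- sweep(Z, 2L, object$standardize$center, "-")
  Z <- sweep(Z, 2L, object$standardize$scale, "/")
  Z %*% t(object$loadings)
}

#' Factor maps along geography
#'
#' Plots each factor's scores against the first coordinate axis (for
#' transect-like data) or as a coloured scatter in two dimensions.
#'
#' @param x an `"spfa"` fit carrying coordinates.
#' @param factors which factors to draw (default all).
#' @param ... passed to [graphics::plot()].
#' @export
plot.spfa <- function(x, factors = seq_len(x$K), ...) {
  if (is.null(x$coords)) stop("fit carries no coordinates")
  P <- x$coords$points
  one_d <- length(unique(P[, 2L])) == 1L
  op <- graphics::par(mfrow = c(length(factors), 1L),
                      mar = c(3.5, 3.5, 1.5, 0.5), mgp = c(2, 0.7, 0))
  on.exit(graphics::par(op))
  for (k in factors) {
    if (one_d) {
      graphics::plot(P[, 1L], x$scores[, k], xlab = "position",
                     ylab = sprintf("factor %d", k), ...)
    } else {
      cols <- grDevices::hcl.colors(64L)
      v <- x$scores[, k]
      idx <- cut(v, breaks = 64L, labels = FALSE)
      graphics::plot(P[, 1L], P[, 2L], col = cols[idx], pch = 19,
                     xlab = "x", ylab = "y",
                     main = sprintf("factor %d", k), ...)
    }
  }
  invisible(x)
}

#' @importFrom stats screeplot
#' @export
screeplot.spfa <- function(x, ...) {
  graphics::barplot(x$d, names.arg = paste0("F", seq_along(x$d)),
                    ylab = "singular value", ...)
  invisible(x)
}
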