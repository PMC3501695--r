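#' Centre and scale a genotype matrix
#'
#' Standardizes each locus (column) to mean zero and unit standard deviation,
#' the usual preprocessing for genotype PCA. Missing genotypes are imputed to
#' the column mean before scaling, and monomorphic loci (zero variance after
#' imputation) are dropped with a warning. The sample standard deviation
#' (divisor `n - 1`) is used, matching [stats::prcomp()].
#'
#' @param G numeric matrix of `n` individuals by `L` loci. Entries are
#'   typically allele counts 0/1/2 but any numeric values are accepted (the
#'   continuous Gaussian fixtures of [gaussian_fixture()] use this path).
#'   `NA` marks a missing genotype.
#' @return A list of class `"spfa_standardized"` with elements
#'   \describe{
#'     \item{values}{the `n x L'` standardized matrix (`L' <= L`),}
#'     \item{kept_loci}{integer indices of the retained columns of `G`,}
#'     \item{center, scale}{per retained column mean and standard deviation,}
#'     \item{n_imputed}{number of missing entries imputed to column means.}
#'   }
#' @examples
#' G <- cbind(a = c(0, 1, 2), b = c(2, 2, 2))
#' s <- center_scale(G)
#' s$values      # single column, (-1, 0, 1)
#' s$kept_loci   # locus "b" was monomorphic and dropped
#' @export
center_scale <- function(G) {
  G <- as.matrix(G)
  if (!is.numeric(G)) stop("genotype matrix must be numeric")
  n <- nrow(G)
  if (n < 2L) stop("need at least 2 individuals")
  storage.mode(G) <- "double"

  n_imputed <- 0L
  if (anyNA(G)) {
    mu <- colMeans(G, na.rm = TRUE)
    idx <- which(is.na(G))
    n_imputed <- length(idx)
    G[idx] <- mu[((idx - 1L) %/% n) + 1L]
    if (anyNA(G)) stop("some loci have no observed genotypes")
    warning(sprintf("imputed %d missing genotypes to column means", n_imputed))
  }

  ctr <- colMeans(G)
  Gc <- sweep(G, 2L, ctr, "-")
  sds <- sqrt(colSums(Gc^2) / (n - 1L))
  keep <- which(unname(sds) > 0)
  if (length(keep) == 0L) stop("no polymorphic loci")
  if (length(keep) < ncol(G)) {
    warning(sprintf("dropped %d monomorphic loci (indices: %s%s)",
                    ncol(G) - length(keep),
                    paste(utils::head(setdiff(seq_len(ncol(G)), keep), 5L),
                          collapse = ", "),
                    if (ncol(G) - length(keep) > 5L) ", ..." else ""))
  }
  vals <- sweep(Gc[, keep, drop = FALSE], 2L, sds[keep], "/")
  structure(list(values = vals,
                 kept_loci = keep,
                 center = ctr[keep],
                 scale = sds[keep],
                 n_imputed = n_imputed),
            class = "spfa_standardized")
}
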