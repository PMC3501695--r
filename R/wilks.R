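#' Wilks' Lambda for group separation of factor scores
#'
#' The MANOVA determinant ratio `Lambda = det(W) / det(W + B)`, where `W` is
#' the pooled within-group scatter of the score rows and `B` the
#' between-group scatter. `Lambda` lies in (0, 1]: 1 when the group means
#' coincide, near 0 when groups are well separated relative to their spread.
#' Raw sums of squares are used; the ratio is invariant to any common
#' divisor and to any nonsingular affine transform of the scores.
#'
#' @param scores `n x K` numeric matrix (rows = individuals).
#' @param groups vector of group labels of length `n`; at least 2 groups,
#'   each with at least 2 members.
#' @return Wilks' Lambda as a single number.
#' @examples
#' wilks_lambda(cbind(c(0, 2, 1, 3)), groups = c(1, 1, 2, 2))  # 0.8
#' @export
wilks_lambda <- function(scores, groups) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  if (length(groups) != n) stop("groups must have one label per score row")
  g <- as.factor(groups)
  if (nlevels(g) < 2L) stop("need at least 2 groups")
  sizes <- table(g)
  if (any(sizes < 2L))
    stop("every group needs at least 2 members: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "))
  K <- ncol(scores)
  gm <- colMeans(scores)
  Wm <- matrix(0, K, K); Bm <- matrix(0, K, K)
  for (lev in levels(g)) {
    Si <- scores[g == lev, , drop = FALSE]
    mi <- colMeans(Si)
    Wm <- Wm + crossprod(sweep(Si, 2L, mi, "-"))
    Bm <- Bm + nrow(Si) * tcrossprod(mi - gm)
  }
  dt <- det(Wm + Bm)
  if (!is.finite(dt) || dt <= 0) stop("degenerate scores")
  lam <- det(Wm) / dt
  max(lam, 0)
}
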