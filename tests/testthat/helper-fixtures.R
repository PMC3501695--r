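# Shared fixtures built in code.

# random genotype-like matrix (continuous, mean-varied columns)
rand_matrix <- function(n, L, seed) {
  set.seed(seed)
  matrix(rnorm(n * L), n, L)
}

# random 0/1/2 genotype matrix with all loci polymorphic
rand_genotypes <- function(n, L, seed) {
  set.seed(seed)
  repeat {
    G <- matrix(rbinom(n * L, 2L, runif(L, 0.2, 0.8)[rep(seq_len(L),
                                                         each = n)]),
                n, L)
    if (all(apply(G, 2L, function(col) length(unique(col)) > 1L))) return(G)
  }
}

# coordinates on a transect
line_coords <- function(n) cbind(x = seq_len(n), y = 0)

# path-graph adjacency over n nodes
path_weights <- function(n) {
  W <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) { W[i, i + 1L] <- 1; W[i + 1L, i] <- 1 }
  W
}

# brute-force Moran's I by explicit double loop
moran_brute <- function(g, W) {
  n <- length(g)
  gb <- mean(g)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    num <- num + W[i, j] * (g[i] - gb) * (g[j] - gb)
  (n / sum(W)) * num / sum((g - gb)^2)
}

# brute-force Wilks' Lambda from scatter matrices assembled row by row
wilks_brute <- function(scores, groups) {
  scores <- as.matrix(scores)
  g <- as.factor(groups)
  K <- ncol(scores)
  gm <- colMeans(scores)
  Wm <- matrix(0, K, K); Bm <- matrix(0, K, K)
  for (lev in levels(g)) {
    rows <- which(g == lev)
    mi <- colMeans(scores[rows, , drop = FALSE])
    for (i in rows)
      Wm <- Wm + tcrossprod(scores[i, ] - mi)
    Bm <- Bm + length(rows) * tcrossprod(mi - gm)
  }
  det(Wm) / det(Wm + Bm)
}

# a small in-memory VCF with one triallelic record among five
write_test_vcf <- function(path) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
           "ind_001\tind_002\tind_003"),
    "1\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "1\t200\trs2\tC\tT\t.\tPASS\t.\tGT\t0/1\t0/0\t0/0",
    "1\t300\trs3\tG\tA,T\t.\tPASS\t.\tGT\t0/1\t0/2\t1/1",
    "1\t400\trs4\tT\tC\t.\tPASS\t.\tGT\t1/1\t0/1\t./.",
    "1\t500\t.\tA\tC\t.\tPASS\t.\tGT\t0|1\t1|1\t0|0")
  writeLines(lines, path)
  path
}
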