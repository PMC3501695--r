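#' Read a genotype matrix
#'
#' Two formats are supported. `delimited`: a tab-separated table with a
#' header row of locus identifiers and a first column of individual
#' identifiers; entries must be 0, 1, 2 or the missing code `NA`. `vcf`: a
#' VCF file whose biallelic SNP records are converted to alternate-allele
#' counts; multi-allelic records are skipped with a message reporting the
#' count.
#'
#' @param path file path.
#' @param format `"delimited"` (default) or `"vcf"`.
#' @return integer matrix of individuals x loci with dimnames.
#' @export
read_genotypes <- function(path, format = c("delimited", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "vcf") return(read_genotypes_vcf(path))
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character",
                           row.names = 1L, comment.char = "")
  if (nrow(tab) == 0L || ncol(tab) == 0L) stop("empty genotype file: ", path)
  M <- as.matrix(tab)
  bad <- matrix(!(M %in% c("0", "1", "2", "NA", NA)), nrow = nrow(M))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "invalid genotype '%s' at row %d (individual %s), column %d (locus %s)",
      M[idx[1L], idx[2L]], idx[1L], rownames(M)[idx[1L]], idx[2L],
      colnames(M)[idx[2L]]))
  }
  G <- matrix(suppressWarnings(as.integer(M)), nrow = nrow(M),
              dimnames = dimnames(M))
  G
}

read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (nrow(v@fix) == 0L) stop("empty VCF: ", path)
  bi <- vcfR::is.biallelic(v)
  if (any(!bi))
    message(sprintf("skipped %d multi-allelic VCF records", sum(!bi)))
  v <- v[bi, ]
  if (nrow(v@fix) == 0L) stop("no biallelic records in VCF: ", path)
  gt <- vcfR::extract.gt(v, element = "GT")
  count_alt <- function(x) {
    if (is.na(x) || x %in% c(".", "./.", ".|.")) return(NA_integer_)
    alleles <- strsplit(x, "[/|]")[[1L]]
    if (any(alleles == ".")) return(NA_integer_)
    sum(alleles != "0")
  }
  G <- t(apply(gt, c(1L, 2L), count_alt))
  ids <- v@fix[, "ID"]
  miss <- is.na(ids) | ids == "."
  ids[miss] <- paste0(v@fix[miss, "CHROM"], ":", v@fix[miss, "POS"])
  colnames(G) <- ids
  storage.mode(G) <- "integer"
  G
}

#' Read individual coordinates
#'
#' Reads a tab-separated table with columns `id`, `x`, `y` and reorders the
#' rows to match a genotype matrix's individuals. For great-circle analyses
#' `x` is longitude and `y` latitude, in degrees.
#'
#' @param path file path.
#' @param ids individual identifiers in the target order (e.g.
#'   `rownames(G)`); if `NULL` the file order is kept.
#' @return numeric `n x 2` matrix with the ids as rownames.
#' @export
read_coordinates <- function(path, ids = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, comment.char = "")
  need <- c("id", "x", "y")
  if (!all(need %in% names(tab)))
    stop("coordinate file must have columns: id, x, y")
  if (!is.numeric(tab$x) || !is.numeric(tab$y) || anyNA(tab$x) ||
      anyNA(tab$y))
    stop("non-numeric coordinate values in ", path)
  rid <- as.character(tab$id)
  if (anyDuplicated(rid))
    stop("duplicated ids in coordinate file: ",
         paste(unique(rid[duplicated(rid)]), collapse = ", "))
  X <- cbind(x = tab$x, y = tab$y)
  rownames(X) <- rid
  if (!is.null(ids)) {
    missing_ids <- setdiff(ids, rid)
    if (length(missing_ids))
      stop("coordinates missing for: ", paste(missing_ids, collapse = ", "))
    extra <- setdiff(rid, ids)
    if (length(extra))
      stop("coordinate ids not in genotypes: ",
           paste(extra, collapse = ", "))
    X <- X[match(ids, rid), , drop = FALSE]
  }
  X
}

fmt_full <- function(x) formatC(x, format = "g", digits = 17)

#' Write a fitted factor model to disk
#'
#' Writes the scores, loadings and singular values as tab-separated tables
#' (full double precision, so read/write round-trips are lossless) plus a
#' JSON manifest recording theta, theta/d-bar, K, the metric and the package
#' version.
#'
#' @param model an [spfa()] or [spfa_pca()] fit.
#' @param outdir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_factor_model <- function(model, outdir) {
  if (!inherits(model, "spfa")) stop("model must be an spfa fit")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop("cannot create output directory: ", outdir)
  paths <- file.path(outdir, c("scores.tsv", "loadings.tsv",
                               "singular_values.tsv", "manifest.json"))
  sc <- data.frame(id = rownames(model$scores) %||%
                     sprintf("ind_%03d", seq_len(model$n)),
                   apply(model$scores, 2L, fmt_full),
                   check.names = FALSE)
  utils::write.table(sc, paths[1L], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  ld <- data.frame(id = colnames(model$loadings) %||%
                     sprintf("locus_%05d", seq_len(ncol(model$loadings))),
                   apply(t(model$loadings), 2L, fmt_full),
                   check.names = FALSE)
  names(ld) <- c("id", rownames(model$loadings))
  utils::write.table(ld, paths[2L], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(factor = paste0("F", seq_along(model$d)),
               singular_value = fmt_full(model$d)),
    paths[3L], sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(method = model$method, K = model$K,
                   theta = model$theta, theta_ratio = model$theta_ratio,
                   d_bar = model$d_bar, metric = model$metric,
                   n = model$n, L = model$L,
                   jitter = model$jitter,
                   package_version =
                     as.character(utils::packageVersion("spfa")))
  jsonlite::write_json(manifest, paths[4L], auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(paths)
}

#' Write a simulated dataset to disk
#'
#' Writes genotypes (individuals x loci, tab-separated 0/1/2), coordinates
#' and population labels, plus a JSON manifest with all simulation
#' parameters including the seed.
#'
#' @param sim a [simulate_stepping_stone()] or [gaussian_fixture()] result.
#' @param outdir output directory.
#' @return invisibly, the paths written.
#' @export
write_sim <- function(sim, outdir) {
  if (!inherits(sim, "spfa_sim")) stop("sim must be an spfa_sim object")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(outdir, c("genotypes.tsv", "coords.tsv", "labels.tsv",
                               "manifest.json"))
  G <- sim$genotypes
  gt <- data.frame(id = rownames(G),
                   if (is.double(G)) apply(G, 2L, fmt_full) else G,
                   check.names = FALSE)
  names(gt) <- c("id", colnames(G))
  utils::write.table(gt, paths[1L], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(id = rownames(sim$coords), x = sim$coords[, 1L],
               y = sim$coords[, 2L]),
    paths[2L], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(id = rownames(sim$coords), population = sim$labels),
    paths[3L], sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(sim$params, paths[4L], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
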