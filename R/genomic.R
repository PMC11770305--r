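#' Construct a genotype matrix
#'
#' Wraps an animals-by-SNPs allele-dosage matrix (entries 0/1/2, the count of
#' the counted allele; NA = missing) together with the per-SNP observed
#' allele frequencies `p`, the SNP count `N` and the VanRaden scaling
#' constant `lambda = 1 / (2 * sum p_i (1 - p_i))`.
#'
#' `p` is the observed frequency of the counted allele among the genotyped
#' animals (not folded to the minor allele): `p (1 - p)` — hence `lambda` —
#' is unaffected by the choice, while the centering of `Z` requires the
#' counted allele's frequency for internal consistency.
#'
#' @param dosages numeric matrix, animals x SNPs, entries in \{0, 1, 2, NA\}.
#' @param animal_ids,snp_ids row/column identifiers (defaults: dimnames).
#' @return object of class `geno_matrix`: list with `M`, `animal_id`,
#'   `snp_id`, `p`, `N`, `lam`.
#' @export
genotype_matrix <- function(dosages, animal_ids = rownames(dosages),
                            snp_ids = colnames(dosages)) {
  dosages <- as.matrix(dosages)
  if (is.null(animal_ids)) animal_ids <- as.character(seq_len(nrow(dosages)))
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(ncol(dosages)))
  ok <- is.na(dosages) | dosages %in% c(0, 1, 2)
  if (!all(ok)) stop("dosages must be 0, 1, 2 or NA")
  p <- colMeans(dosages, na.rm = TRUE) / 2
  het <- sum(p * (1 - p))
  structure(list(M = unname(dosages),
                 animal_id = as.character(animal_ids),
                 snp_id = as.character(snp_ids),
                 p = unname(p), N = ncol(dosages),
                 lam = if (het > 0) 1 / (2 * het) else NA_real_),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("Genotypes:", length(x$animal_id), "animals x", x$N, "SNPs\n")
  cat("  mean allele frequency:", signif(mean(x$p), 4),
      " lambda:", signif(x$lam, 6), "\n")
  invisible(x)
}

#' Minor-allele-frequency and monomorphism filter
#'
#' Drops SNPs whose minor allele frequency `min(p, 1 - p)` falls below
#' `maf_min`, and monomorphic SNPs regardless of `maf_min`; `p`, `N` and
#' `lambda` are recomputed on the retained panel.
#'
#' @param g a `geno_matrix`.
#' @param maf_min MAF threshold in `[0, 0.5)`.
#' @return filtered `geno_matrix`.
#' @export
qc_filter <- function(g, maf_min = 0.01) {
  stopifnot(inherits(g, "geno_matrix"), maf_min >= 0, maf_min < 0.5)
  maf <- pmin(g$p, 1 - g$p)
  keep <- maf >= maf_min & g$p > 0 & g$p < 1
  if (!any(keep)) stop("all SNPs removed by QC (maf_min = ", maf_min, ")")
  genotype_matrix(g$M[, keep, drop = FALSE], g$animal_id, g$snp_id[keep])
}

#' Center genotypes to the Z matrix
#'
#' Returns `Z = M - 2p` columnwise (gene content adjusted for allele
#' frequencies). Missing dosages are imputed to the column mean `2p` first,
#' so they contribute exactly zero to `Z`. When `p` is the observed
#' frequency every column of `Z` sums to zero.
#'
#' @param g a `geno_matrix`.
#' @return numeric matrix Z (animals x SNPs) with dimnames.
#' @export
center_genotypes <- function(g) {
  stopifnot(inherits(g, "geno_matrix"))
  M <- g$M
  if (anyNA(M)) {
    na <- which(is.na(M), arr.ind = TRUE)
    M[na] <- 2 * g$p[na[, 2]]
  }
  Z <- sweep(M, 2, 2 * g$p, "-")
  dimnames(Z) <- list(g$animal_id, g$snp_id)
  Z
}

#' Genomic relationship matrix (VanRaden, optionally SNP-weighted)
#'
#' `G = lambda * Z D Z'` with `D = diag(d)` the per-SNP weights and
#' `lambda = 1 / (2 sum p_i (1 - p_i))`. With `d = 1` everywhere this is the
#' unweighted VanRaden first-method G.
#'
#' @param Z centered genotype matrix from [center_genotypes()].
#' @param d per-SNP positive weights (default all 1).
#' @param lam scaling constant lambda.
#' @return symmetric PSD matrix, animals x animals.
#' @export
g_matrix <- function(Z, d = rep(1, ncol(Z)), lam) {
  stopifnot(length(d) == ncol(Z), all(d > 0), lam > 0)
  G <- lam * tcrossprod(sweep(Z, 2, sqrt(d), "*"))
  G <- (G + t(G)) / 2
  dimnames(G) <- list(rownames(Z), rownames(Z))
  G
}

#' Blend G with the pedigree block A22
#'
#' `G* = alpha G + (1 - alpha) A22` guarantees invertibility when G is
#' rank-deficient (more animals than SNPs, duplicated genotypes).
#'
#' @param G genomic relationship matrix.
#' @param A22 pedigree relationship matrix of the genotyped animals.
#' @param alpha blending weight in `(0, 1]`; default 0.95.
#' @return blended matrix `G*`.
#' @export
blend_g <- function(G, A22, alpha = 0.95) {
  stopifnot(alpha > 0, alpha <= 1)
  if (!all(dim(G) == dim(A22))) stop("G and A22 dimensions differ")
  alpha * G + (1 - alpha) * A22
}

#' Rescale G to the scale of A22
#'
#' Solves `G_adj = a + b G` so that the means of the diagonal and of the
#' off-diagonal of `G_adj` match those of `A22` (compatibility tuning of
#' genomic and pedigree base populations). Off by default in the fitting
#' routines.
#'
#' @param G genomic relationship matrix.
#' @param A22 pedigree relationship block of the same animals.
#' @return rescaled matrix.
#' @export
tune_g <- function(G, A22) {
  if (!all(dim(G) == dim(A22))) stop("G and A22 dimensions differ")
  n <- nrow(G)
  dg <- mean(diag(G)); da <- mean(diag(A22))
  og <- (sum(G) - sum(diag(G))) / (n * (n - 1))
  oa <- (sum(A22) - sum(diag(A22))) / (n * (n - 1))
  b <- (da - oa) / (dg - og)
  a <- oa - b * og
  a + b * G
}

#' Single-step H-inverse
#'
#' `H^-1 = A^-1 + scatter(G*^-1 - A22^-1)` over the genotyped block
#' (the Aguilar/Christensen single-step combination). With no genotyped
#' animals, or with `G* = A22`, the correction vanishes and `H^-1 = A^-1`.
#'
#' @param Ainv sparse A-inverse of the whole pedigree ([a_inverse()]).
#' @param A22 dense pedigree relationship matrix of the genotyped animals.
#' @param Gstar blended genomic relationship matrix (same animals, same order).
#' @param geno_idx integer positions of the genotyped animals in pedigree
#'   order.
#' @return sparse symmetric H-inverse (same dimension as `Ainv`).
#' @export
h_inverse <- function(Ainv, A22, Gstar, geno_idx) {
  n <- nrow(Ainv)
  k <- length(geno_idx)
  if (k == 0) return(Ainv)
  stopifnot(nrow(A22) == k, nrow(Gstar) == k)
  Gi <- tryCatch(chol2inv(chol(Gstar)),
                 error = function(e)
                   stop("G* is singular; blend with A22 (see blend_g)",
                        call. = FALSE))
  Ai22 <- chol2inv(chol(A22))
  C <- Gi - Ai22
  idx <- rep(geno_idx, times = k)
  jdx <- rep(geno_idx, each = k)
  Hinv <- Ainv + Matrix::sparseMatrix(i = idx, j = jdx, x = as.vector(C),
                                      dims = c(n, n))
  Hinv <- (Hinv + Matrix::t(Hinv)) / 2
  dimnames(Hinv) <- dimnames(Ainv)
  Hinv
}

#' Read a genotype file
#'
#' Two dialects are supported and auto-detected: (a) BLUPF90-style fixed
#' columns `animal_id 012012...` (whitespace-separated id and one unbroken
#' dosage string, `5` = missing), and (b) CSV with a header row of SNP ids
#' and the animal id in the first column (empty/NA = missing).
#'
#' @param path file path.
#' @param format `"auto"` (default), `"blupf90"` or `"csv"`.
#' @return a `geno_matrix`.
#' @export
read_genotypes <- function(path, format = c("auto", "blupf90", "csv")) {
  format <- match.arg(format)
  first <- readLines(path, n = 1L)
  if (format == "auto")
    format <- if (grepl(",", first, fixed = TRUE)) "csv" else "blupf90"
  if (format == "csv") {
    df <- utils::read.csv(path, check.names = FALSE,
                          colClasses = "character")
    ids <- df[[1]]
    M <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(M) <- "numeric"
    return(genotype_matrix(M, ids, colnames(df)[-1]))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- regmatches(lines, regexpr("^\\S+", lines))
  rest <- trimws(sub("^\\S+\\s+", "", lines))
  nsnp <- unique(nchar(rest))
  if (length(nsnp) != 1)
    stop("unequal genotype string lengths in ", path)
  M <- matrix(as.numeric(unlist(strsplit(rest, ""))), nrow = length(lines),
              ncol = nsnp, byrow = TRUE)
  M[M == 5] <- NA_real_
  genotype_matrix(M, parts, paste0("snp", seq_len(nsnp)))
}

#' Write a genotype file
#'
#' @param g a `geno_matrix`.
#' @param path output path.
#' @param format `"blupf90"` (id + dosage string, missing as `5`) or `"csv"`.
#' @export
write_genotypes <- function(g, path, format = c("blupf90", "csv")) {
  format <- match.arg(format)
  M <- g$M
  if (format == "blupf90") {
    M[is.na(M)] <- 5
    str <- apply(M, 1, function(r) paste(r, collapse = ""))
    writeLines(paste(g$animal_id, str), path)
  } else {
    lines <- c(paste(c("animal", g$snp_id), collapse = ","),
               paste(g$animal_id,
                     apply(M, 1, paste, collapse = ","), sep = ","))
    writeLines(lines, path)
  }
  invisible(path)
}
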