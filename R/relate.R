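#' VanRaden genomic relationship matrix
#'
#' Computes the first VanRaden genomic relationship matrix from biallelic
#' codes: alt-allele dosages `M` in \{0, 1, 2\} are centered by twice the
#' observed panel allele frequency, `Z = M - 2p`, and
#' `K = Z Z' / (2 * sum(p * (1 - p)))`. Frequencies come from the analyzed
#' panel itself; no external reference population is used.
#'
#' @param genotypes A [geno_matrix] without missing calls and with at least
#'   two polymorphic markers.
#' @return A symmetric lines-by-lines numeric matrix with line-ID dimnames.
#' @export
vanraden_kinship <- function(genotypes) {
  stopifnot(inherits(genotypes, "geno_matrix"))
  codes <- genotypes$codes
  if (anyNA(codes)) stop("missing calls: impute first", call. = FALSE)
  M <- codes + 1
  p <- colMeans(M) / 2
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) {
    stop("all markers monomorphic: VanRaden denominator is zero",
         call. = FALSE)
  }
  if (sum(p > 0 & p < 1) < 2L) {
    stop("need at least two polymorphic markers", call. = FALSE)
  }
  Z <- sweep(M, 2, 2 * p)
  K <- tcrossprod(Z) / denom
  dimnames(K) <- list(rownames(codes), rownames(codes))
  K
}

#' Identity-by-state co-ancestry distance
#'
#' Pairwise genetic distance computed directly from the SNPs as one minus the
#' mean proportion of alleles shared per marker. For codes x and y the
#' per-marker allele sharing is `1 - |x - y| / 2` (identical genotypes share
#' both alleles, opposite homozygotes none, a heterozygote shares half with
#' either homozygote), so the distance is the scaled Manhattan distance
#' `mean(|x - y|) / 2`, bounded in \[0, 1\].
#'
#' @param genotypes A [geno_matrix] without missing calls.
#' @return A symmetric lines-by-lines distance matrix with line-ID dimnames.
#' @export
coancestry_distance <- function(genotypes) {
  stopifnot(inherits(genotypes, "geno_matrix"))
  codes <- genotypes$codes
  if (anyNA(codes)) stop("missing calls: impute first", call. = FALSE)
  D <- as.matrix(stats::dist(codes, method = "manhattan")) / (2 * ncol(codes))
  dimnames(D) <- list(rownames(codes), rownames(codes))
  D
}

#' Principal component analysis of a genotype panel
#'
#' PCA of the column-centered (unscaled) genotype codes via singular value
#' decomposition, as done by `stats::prcomp`. Variance explained is each
#' squared singular value as a percentage of their total, so the full vector
#' sums to 100.
#'
#' @param genotypes A [geno_matrix] with at least 2 lines and no missing
#'   calls.
#' @param n_components Number of leading components to return.
#' @return A list of class `geno_pca` with `scores` (lines x
#'   `n_components`), `var_explained` (percent, length `n_components`) and
#'   `var_explained_all` (all components; sums to 100).
#' @export
pca_genotypes <- function(genotypes, n_components = 3) {
  stopifnot(inherits(genotypes, "geno_matrix"))
  codes <- genotypes$codes
  if (anyNA(codes)) stop("missing calls: impute first", call. = FALSE)
  if (nrow(codes) < 2L) stop("need at least 2 lines", call. = FALSE)
  max_comp <- min(nrow(codes) - 1L, ncol(codes))
  if (n_components > max_comp) {
    stop("n_components exceeds min(lines - 1, markers) = ", max_comp,
         call. = FALSE)
  }
  pc <- stats::prcomp(codes, center = TRUE, scale. = FALSE)
  ve <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = pc$x[, seq_len(n_components), drop = FALSE],
                 var_explained = ve[seq_len(n_components)],
                 var_explained_all = ve),
            class = "geno_pca")
}

#' @export
print.geno_pca <- function(x, ...) {
  cat("geno_pca:", nrow(x$scores), "lines;",
      paste0("PC", seq_along(x$var_explained), " ",
             round(x$var_explained, 1), "%", collapse = ", "), "\n")
  invisible(x)
}
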