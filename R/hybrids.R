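#' Additive and dominance design matrices for F1 hybrids
#'
#' Derives, for each hybrid in the mating design, its expected marker states
#' from the two parental genotypes. With inbred parents coded -1/+1, a
#' hybrid is homozygous (K_A = parental code, K_D = 0) where the parents
#' agree and heterozygous (K_A = 0, K_D = 1) where they carry opposite
#' homozygotes. Equivalently K_A = (female + male)/2 and
#' K_D = |female - male|/2, which is how the matrices are computed.
#'
#' A residually heterozygous parent (code 0) makes the cross outcome
#' stochastic; policy `"expected"` records the expected state (K_A may be
#' +/-0.5, K_D may be 0.5), while `"strict"` refuses such parents, which is
#' the appropriate setting for panels assumed fully inbred.
#'
#' @param genotypes Parental [geno_matrix]; must contain no missing calls
#'   (run [impute_naive()] first).
#' @param design A mating design: data frame with columns `hybrid`, `female`,
#'   `male` (and optionally `group`), parents named as in `genotypes`.
#' @param het_policy `"expected"` or `"strict"` (see Details).
#' @return A list of class `hybrid_design` with matrices `K_A` (values in
#'   \[-1, 1\]) and `K_D` (values in \[0, 1\]), rows ordered and named as the
#'   design records, columns as the genotype markers, plus the `design`.
#' @export
#' @examples
#' g <- geno_matrix(rbind(A = c(1, 1, -1), B = c(-1, 1, -1)))
#' d <- data.frame(hybrid = "AxB", female = "A", male = "B")
#' make_hybrid_design(g, d)$K_A
make_hybrid_design <- function(genotypes, design,
                               het_policy = c("expected", "strict")) {
  het_policy <- match.arg(het_policy)
  stopifnot(inherits(genotypes, "geno_matrix"))
  design <- as.data.frame(design)
  if (!all(c("hybrid", "female", "male") %in% names(design))) {
    stop("design needs columns 'hybrid', 'female', 'male'", call. = FALSE)
  }
  if (anyDuplicated(design$hybrid)) {
    stop("duplicate hybrid IDs in mating design", call. = FALSE)
  }
  codes <- genotypes$codes
  if (anyNA(codes)) {
    stop("genotypes contain missing calls; impute before building ",
         "hybrid design matrices", call. = FALSE)
  }
  unknown <- setdiff(unique(c(design$female, design$male)), rownames(codes))
  if (length(unknown) > 0L) {
    stop("parent line(s) absent from genotype matrix: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (het_policy == "strict" && any(codes[unique(c(design$female,
                                                   design$male)), ] == 0)) {
    stop("heterozygous parental call under strict policy", call. = FALSE)
  }
  fem <- codes[design$female, , drop = FALSE]
  mal <- codes[design$male, , drop = FALSE]
  K_A <- (fem + mal) / 2
  K_D <- abs(fem - mal) / 2
  # expected heterozygosity of the cross: P(het) = P(f alt)P(m ref) + v.v.
  if (het_policy == "expected" && any(fem == 0 | mal == 0)) {
    pf <- (fem + 1) / 2
    pm <- (mal + 1) / 2
    K_D <- pf * (1 - pm) + pm * (1 - pf)
  }
  dimnames(K_A) <- dimnames(K_D) <- list(design$hybrid, colnames(codes))
  structure(list(K_A = K_A, K_D = K_D, design = design),
            class = "hybrid_design")
}

#' @export
print.hybrid_design <- function(x, ...) {
  cat("hybrid_design:", nrow(x$K_A), "hybrids x", ncol(x$K_A), "markers;",
      "mean heterozygosity", round(mean(x$K_D), 3), "\n")
  invisible(x)
}

#' Summaries of a hybrid design
#'
#' @param hd A `hybrid_design` from [make_hybrid_design()].
#' @return A list with `per_hybrid` (data frame: `hybrid`, `heterozygosity` =
#'   mean K_D across markers) and `per_marker` (data frame: `marker`,
#'   `n_het` = hybrids heterozygous at the marker, `n_segregating` = hybrids
#'   not fixed for the panel-wide modal state).
#' @export
design_summary <- function(hd) {
  stopifnot(inherits(hd, "hybrid_design"))
  per_hybrid <- data.frame(hybrid = rownames(hd$K_A),
                           heterozygosity = rowMeans(hd$K_D),
                           stringsAsFactors = FALSE)
  n_het <- colSums(hd$K_D > 0)
  seg <- vapply(seq_len(ncol(hd$K_A)), function(j) {
    x <- hd$K_A[, j]
    tab <- table(x)
    sum(x != as.numeric(names(tab))[which.max(tab)])
  }, numeric(1))
  per_marker <- data.frame(marker = colnames(hd$K_A),
                           n_het = as.numeric(n_het),
                           n_segregating = seg,
                           stringsAsFactors = FALSE)
  rownames(per_hybrid) <- rownames(per_marker) <- NULL
  list(per_hybrid = per_hybrid, per_marker = per_marker)
}
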