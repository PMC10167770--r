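#' Per-marker quality-control statistics
#'
#' Computes minor-allele frequency and missing-call rate for each marker, and
#' per-chromosome marker counts. Each homozygous call (`-1` or `+1`)
#' contributes two copies of one allele to the frequency; a heterozygous call
#' (`0`) contributes one copy of each.
#'
#' @param geno A [geno_matrix].
#' @return An object of class `marker_stats`: a data frame with columns
#'   `marker`, `chrom`, `maf`, `missing` plus an attribute
#'   `chrom_counts` (named integer vector of markers per chromosome).
#' @export
#' @examples
#' g <- geno_matrix(rbind(c(1, 1), c(-1, 1), c(1, NA)))
#' compute_marker_stats(g)
compute_marker_stats <- function(geno) {
  stopifnot(inherits(geno, "geno_matrix"))
  codes <- geno$codes
  n <- nrow(codes)
  n_obs <- colSums(!is.na(codes))
  if (any(n_obs == 0L)) {
    stop("marker(s) with all calls missing: ",
         paste(colnames(codes)[n_obs == 0L], collapse = ", "), call. = FALSE)
  }
  # alt-allele copies: +1 -> 2, 0 -> 1, -1 -> 0
  alt_copies <- colSums(codes + 1, na.rm = TRUE)
  p_alt <- alt_copies / (2 * n_obs)
  maf <- pmin(p_alt, 1 - p_alt)
  missing <- 1 - n_obs / n
  chrom_counts <- table(factor(geno$map$chrom, levels = unique(geno$map$chrom)))
  out <- data.frame(marker = colnames(codes),
                    chrom = as.character(geno$map$chrom),
                    maf = as.numeric(maf),
                    missing = as.numeric(missing),
                    stringsAsFactors = FALSE)
  attr(out, "chrom_counts") <- c(chrom_counts)
  class(out) <- c("marker_stats", "data.frame")
  out
}

#' Filter markers on minor-allele frequency and missingness
#'
#' Retains markers with `maf >= maf_min` and missing rate `<= missing_max`
#' (both boundaries inclusive), preserving marker order. The thresholds
#' default to the usual GBS quality-control cut-offs for inbred panels:
#' markers with MAF below 5% or more than 20% missing calls are dropped.
#'
#' @param geno A [geno_matrix].
#' @param maf_min Minimum minor-allele frequency retained.
#' @param missing_max Maximum missing-call rate retained.
#' @return The filtered [geno_matrix] with an attribute `report`, a one-row
#'   data frame (`n_input`, `n_kept`, `n_low_maf`, `n_high_missing`).
#'   An empty result triggers a warning, not an error.
#' @export
filter_markers <- function(geno, maf_min = 0.05, missing_max = 0.20) {
  stopifnot(maf_min >= 0, maf_min <= 0.5, missing_max >= 0, missing_max <= 1)
  st <- compute_marker_stats(geno)
  keep <- st$maf >= maf_min & st$missing <= missing_max
  report <- data.frame(n_input = nrow(st),
                       n_kept = sum(keep),
                       n_low_maf = sum(st$maf < maf_min),
                       n_high_missing = sum(st$missing > missing_max))
  if (!any(keep)) warning("no markers pass the filters", call. = FALSE)
  out <- subset_markers(geno, keep)
  attr(out, "report") <- report
  out
}

#' Naive mode imputation of missing genotype calls
#'
#' Replaces each missing call by the per-marker modal code; when modes tie,
#' the per-marker mean code rounded toward zero is used (so a balanced
#' -1/+1 marker imputes to 0). This is a deliberately simple stand-in for
#' haplotype-aware imputation and is only appropriate at low missingness.
#'
#' @param geno A [geno_matrix] with no all-missing marker.
#' @return A [geno_matrix] without missing values.
#' @export
impute_naive <- function(geno) {
  stopifnot(inherits(geno, "geno_matrix"))
  codes <- geno$codes
  miss_cols <- which(colSums(is.na(codes)) > 0L)
  if (any(colSums(!is.na(codes)) == 0L)) {
    stop("cannot impute marker(s) with all calls missing", call. = FALSE)
  }
  for (j in miss_cols) {
    x <- codes[, j]
    obs <- x[!is.na(x)]
    counts <- tabulate(factor(obs, levels = c(-1, 0, 1)), nbins = 3L)
    top <- which(counts == max(counts))
    fill <- if (length(top) == 1L) c(-1, 0, 1)[top] else trunc(mean(obs))
    codes[is.na(x), j] <- fill
  }
  geno_matrix(codes, geno$map)
}

#' Per-chromosome marker density
#'
#' Summarizes how markers are spread over chromosomes: per-chromosome counts,
#' the genome-wide total, and the mean count per chromosome truncated to an
#' integer.
#'
#' @param x A `marker_stats` object from [compute_marker_stats()], or a
#'   numeric vector of per-chromosome marker counts (optionally named).
#' @return A list with `counts` (named numeric vector), `total` and
#'   `mean_density` (integer-truncated mean markers per chromosome).
#' @export
#' @examples
#' chromosome_density(c(chr1 = 3, chr2 = 4))
chromosome_density <- function(x) {
  counts <- if (inherits(x, "marker_stats")) {
    cc <- attr(x, "chrom_counts")
    if (is.null(cc)) stop("marker_stats lacks chromosome counts", call. = FALSE)
    cc
  } else {
    stopifnot(is.numeric(x), length(x) >= 1L)
    x
  }
  counts <- c(counts)
  list(counts = counts,
       total = sum(counts),
       mean_density = trunc(sum(counts) / length(counts)))
}
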