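#' Genotype matrix container
#'
#' Bundles a lines-by-markers matrix of biallelic SNP codes with its marker
#' map. Codes follow the inbred-panel convention: `-1` and `+1` are the two
#' homozygous classes, `0` is heterozygous and `NA` is a missing call.
#'
#' @param codes Numeric matrix, lines in rows and markers in columns, values
#'   in `{-1, 0, 1, NA}`. Row names are line IDs, column names marker IDs;
#'   default IDs are generated when absent.
#' @param map Data frame with one row per marker and columns `marker`,
#'   `chrom`, `pos` (base pairs), `ref`, `alt`. When `NULL`, a single-
#'   chromosome placeholder map is created.
#'
#' @return An object of class `geno_matrix`: a list with elements `codes`
#'   (numeric matrix) and `map` (data frame).
#' @export
#' @examples
#' g <- geno_matrix(rbind(L1 = c(-1, 1), L2 = c(1, 1)))
#' dim(g$codes)
geno_matrix <- function(codes, map = NULL) {
  codes <- as.matrix(codes)
  storage.mode(codes) <- "double"
  if (is.null(rownames(codes)) && nrow(codes) > 0L) {
    rownames(codes) <- paste0("L", seq_len(nrow(codes)))
  }
  if (is.null(colnames(codes)) && ncol(codes) > 0L) {
    colnames(codes) <- paste0("M", seq_len(ncol(codes)))
  }
  bad <- !(codes %in% c(-1, 0, 1) | is.na(codes))
  if (any(bad)) {
    idx <- which(bad)[1L]
    stop("invalid genotype code ", codes[idx], " at [",
         rownames(codes)[(idx - 1L) %% nrow(codes) + 1L], ", ",
         colnames(codes)[(idx - 1L) %/% nrow(codes) + 1L],
         "]: codes must be -1, 0, 1 or NA", call. = FALSE)
  }
  if (anyDuplicated(colnames(codes))) {
    stop("duplicate marker IDs in genotype matrix", call. = FALSE)
  }
  if (is.null(map)) {
    map <- data.frame(marker = colnames(codes), chrom = "1",
                      pos = seq_len(ncol(codes)), ref = "A", alt = "T",
                      stringsAsFactors = FALSE)
  }
  map <- as.data.frame(map)
  if (nrow(map) != ncol(codes)) {
    stop("marker map has ", nrow(map), " rows but genotype matrix has ",
         ncol(codes), " markers", call. = FALSE)
  }
  if (!all(c("marker", "chrom", "pos") %in% names(map))) {
    stop("marker map needs columns 'marker', 'chrom', 'pos'", call. = FALSE)
  }
  if (any(map$pos < 0)) stop("marker positions must be non-negative", call. = FALSE)
  if (!identical(as.character(map$marker),
                 as.character(colnames(codes)))) {
    stop("marker map IDs do not match genotype matrix columns", call. = FALSE)
  }
  structure(list(codes = codes, map = map), class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("geno_matrix:", nrow(x$codes), "lines x", ncol(x$codes), "markers on",
      length(unique(x$map$chrom)), "chromosome(s);",
      sum(is.na(x$codes)), "missing call(s)\n")
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$codes)

# subset markers (columns) keeping map in sync
subset_markers <- function(geno, keep) {
  geno_matrix(geno$codes[, keep, drop = FALSE],
              droplevels(geno$map[keep, , drop = FALSE]))
}
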