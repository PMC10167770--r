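# shared fixture builders; all randomness is seeded locally

# small deterministic genotype matrix with an explicit map
toy_geno <- function(codes, chrom = NULL) {
  codes <- as.matrix(codes)
  if (is.null(rownames(codes))) {
    rownames(codes) <- paste0("L", seq_len(nrow(codes)))
  }
  colnames(codes) <- paste0("M", seq_len(ncol(codes)))
  map <- data.frame(marker = colnames(codes),
                    chrom = if (is.null(chrom)) rep("1", ncol(codes))
                            else as.character(chrom),
                    pos = seq_len(ncol(codes)) * 100,
                    ref = "A", alt = "T", stringsAsFactors = FALSE)
  geno_matrix(codes, map)
}

# random fully-inbred panel (codes -1/+1)
random_inbred_geno <- function(n_lines, n_markers, seed) {
  set.seed(seed)
  toy_geno(matrix(sample(c(-1, 1), n_lines * n_markers, replace = TRUE),
                  n_lines, n_markers))
}

# scratch file path under the session temp directory
withr_local_file <- function(name) file.path(tempdir(), name)

# reorder/select markers of a geno_matrix, keeping the map aligned
subset_geno_cols <- function(geno, idx) {
  geno_matrix(geno$codes[, idx, drop = FALSE], geno$map[idx, , drop = FALSE])
}

# desk-scale simulation config kept small for test speed
test_config <- function(...) {
  args <- utils::modifyList(
    list(n_pollinators = 30, group_sizes = c(22, 18, 20),
         n_shared_pollinators = 12, n_markers = 300, n_qtl = 60),
    list(...))
  do.call(sim_config, args)
}
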