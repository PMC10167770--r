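#' Read parental genotypes from VCF or TSV
#'
#' VCF genotypes are mapped by alt-allele dosage: `0/0 -> -1`, `0/1 -> 0`,
#' `1/1 -> +1`, `./. -> NA`. Multi-allelic records are skipped with a
#' warning. The TSV dialect is a lines-by-markers matrix of codes
#' -1/0/1 (empty or NA for missing) with a marker-ID header row and line
#' IDs in the first column, as written by [write_genotypes()].
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"vcf"` or `"tsv"`.
#' @return A [geno_matrix]. For VCF input the number of skipped
#'   multi-allelic records is attached as attribute `n_skipped`.
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  }
  if (format == "vcf") {
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
    multi <- grepl(",", fix$ALT)
    if (any(multi)) {
      warning(sum(multi), " multi-allelic record(s) skipped in ", path,
              call. = FALSE)
    }
    keep <- which(!multi)
    if (length(keep) == 0L) stop("no biallelic records in ", path,
                                 call. = FALSE)
    gt <- vcfR::extract.gt(vcf, element = "GT")[keep, , drop = FALSE]
    dosage <- apply(gt, c(1, 2), function(g) {
      if (is.na(g)) return(NA_real_)
      al <- strsplit(gsub("\\|", "/", g), "/", fixed = FALSE)[[1]]
      if (any(al == ".")) return(NA_real_)
      sum(al != "0")
    })
    ids <- fix$ID[keep]
    no_id <- is.na(ids) | ids == "."
    ids[no_id] <- paste0(fix$CHROM[keep][no_id], "_", fix$POS[keep][no_id])
    map <- data.frame(marker = ids, chrom = fix$CHROM[keep],
                      pos = as.numeric(fix$POS[keep]),
                      ref = fix$REF[keep], alt = fix$ALT[keep],
                      stringsAsFactors = FALSE)
    codes <- t(dosage) - 1
    colnames(codes) <- ids
    out <- geno_matrix(codes, map)
    attr(out, "n_skipped") <- sum(multi)
    out
  } else {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             row.names = 1, check.names = FALSE)
    geno_matrix(as.matrix(tab))
  }
}

#' Write parental genotypes as TSV or VCF
#'
#' The TSV format round-trips exactly through [read_genotypes()]. VCF output
#' (plain text) encodes codes as GT `0/0`, `0/1`, `1/1` and missing as
#' `./.`, with the marker map providing CHROM/POS/REF/ALT.
#'
#' @param geno A [geno_matrix].
#' @param path Output path.
#' @param format `"tsv"` or `"vcf"`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(geno, path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  stopifnot(inherits(geno, "geno_matrix"))
  if (format == "tsv") {
    utils::write.table(geno$codes, path, sep = "\t", quote = FALSE,
                       col.names = NA)
  } else {
    gt_code <- c(`-1` = "0/0", `0` = "0/1", `1` = "1/1")
    gt <- matrix("./.", ncol(geno$codes), nrow(geno$codes))
    obs <- !is.na(t(geno$codes))
    gt[obs] <- gt_code[as.character(t(geno$codes))[obs]]
    lines <- c("##fileformat=VCFv4.2",
               paste0("##source=hybridGP"),
               paste0("##FORMAT=<ID=GT,Number=1,Type=String,",
                      "Description=\"Genotype\">"),
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", rownames(geno$codes)),
                     collapse = "\t"),
               paste(geno$map$chrom, geno$map$pos, geno$map$marker,
                     geno$map$ref, geno$map$alt, ".", "PASS", ".", "GT",
                     apply(gt, 1, paste, collapse = "\t"), sep = "\t"))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read and write phenotype and mating-design tables
#'
#' Phenotypes are CSV with columns `hybrid`, `environment`, `replicate`,
#' `trait`, `value`; mating designs are CSV with columns `hybrid`, `female`,
#' `male` and optionally `group`. Both readers validate the header and,
#' for phenotypes, key uniqueness and finite values.
#'
#' @param path File path.
#' @return `read_phenotypes()` / `read_design()` return validated data
#'   frames; the writers return `path` invisibly.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ph <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (tr in unique(ph$trait)) check_phenotypes(ph, tr)
  ph
}

#' @rdname read_phenotypes
#' @param phenotypes Long-format phenotype data frame.
#' @export
write_phenotypes <- function(phenotypes, path) {
  utils::write.csv(phenotypes, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_phenotypes
#' @export
read_design <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("hybrid", "female", "male") %in% names(d))) {
    stop(path, " needs columns hybrid, female, male", call. = FALSE)
  }
  if (anyDuplicated(d$hybrid)) {
    stop("duplicate hybrid IDs in ", path, call. = FALSE)
  }
  d
}

#' @rdname read_phenotypes
#' @param design Mating-design data frame.
#' @export
write_design <- function(design, path) {
  utils::write.csv(design, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read or write a simulation configuration as YAML
#'
#' The YAML fields mirror the arguments of [sim_config()].
#'
#' @param path YAML file path.
#' @return `read_sim_config()` returns a [sim_config];
#'   `write_sim_config()` returns `path` invisibly.
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  vals <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0L) {
    stop("unknown config field(s) in ", path, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  do.call(sim_config, vals)
}

#' @rdname read_sim_config
#' @param config A [sim_config].
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Write a run manifest
#'
#' Records package version, seed and MD5 checksums of the listed artifact
#' files, so a run can be audited and regenerated.
#'
#' @param paths Character vector of artifact paths.
#' @param path Output YAML path.
#' @param seed The run's global seed.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(paths, path, seed) {
  info <- list(
    package = "hybridGP",
    version = as.character(utils::packageVersion("hybridGP")),
    r_version = as.character(getRversion()),
    seed = as.integer(seed),
    artifacts = lapply(stats::setNames(paths, basename(paths)), function(p) {
      list(path = p, md5 = unname(tools::md5sum(p)))
    }))
  yaml::write_yaml(info, path)
  invisible(path)
}
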