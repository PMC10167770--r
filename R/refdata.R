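#' Reference tables from a public grain-sorghum hybrid prediction experiment
#'
#' Two small published summary tables from a genomic-prediction experiment
#' on grain sorghum (102 parental inbreds, 3 female testers crossed to 99
#' pollinators giving 204 F1 hybrids, 66,265 GBS SNPs), bundled as worked-
#' example inputs:
#'
#' * `sorghum_tp_accuracy()`: five-fold cross-validated prediction
#'   accuracies r(g-hat, g) for eight agronomic traits at training-population
#'   sizes 41, 82, 122 and 163, under the additive-only and the
#'   additive-plus-dominance model (long format: `trait`, `model`, `n_tp`,
#'   `accuracy`). Feeding a trait's additive series into [accuracy_gain()]
#'   reproduces the experiment's reported percent gains from enlarging the
#'   training population.
#' * `sorghum_chrom_counts()`: the SNP count retained on each of the 10
#'   sorghum chromosomes after MAF/missingness filtering (named numeric
#'   vector), summarized by [chromosome_density()].
#'
#' @return See above.
#' @export
#' @examples
#' acc <- sorghum_tp_accuracy()
#' gy <- acc[acc$trait == "grain_yield" & acc$model == "additive", ]
#' accuracy_gain(gy$accuracy[order(gy$n_tp)])  # 28
sorghum_tp_accuracy <- function() {
  utils::read.csv(system.file("extdata", "sorghum_tp_accuracy.csv",
                              package = "hybridGP", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}

#' @rdname sorghum_tp_accuracy
#' @export
#' @examples
#' chromosome_density(sorghum_chrom_counts())$total  # 66265
sorghum_chrom_counts <- function() {
  tab <- utils::read.table(system.file("extdata",
                                       "sorghum_chrom_snp_counts.tsv",
                                       package = "hybridGP",
                                       mustWork = TRUE),
                           header = TRUE, sep = "\t")
  stats::setNames(as.numeric(tab$n_markers), paste0("chr", tab$chrom))
}
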