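#' Simulation configuration for a tester-by-pollinator hybrid study
#'
#' Collects all parameters of the synthetic-data generator: the size and
#' structure of the parental panel, the mating design (testers crossed to
#' overlapping pollinator groups), the genetic architecture of the simulated
#' trait, and the multi-environment trial layout.
#'
#' Defaults are a desk-scale version of a public sorghum testcross program:
#' 60 pollinators crossed to 3 cytoplasmic-male-sterile testers in three
#' overlapping groups, 2,000 SNPs on 10 chromosomes, a trait controlled by
#' 100 QTL with mostly additive variance, and a trial with 4 environments and
#' 3 replicates. Any field can be overridden; `reference_shaped = TRUE` switches
#' the mating design to the 99-pollinator, 204-hybrid layout with groups of
#' 77/59/68 hybrids and 44 pollinators shared by all groups.
#'
#' @param n_pollinators Number of pollinator (male, R-line) parents.
#' @param n_testers Number of seed-parent testers (female, A-lines).
#' @param group_sizes Integer vector, hybrids per tester group (one group per
#'   tester, each pollinator in a group contributing one hybrid).
#' @param n_shared_pollinators Pollinators present in every group.
#' @param n_markers,n_chromosomes Markers simulated, spread contiguously and
#'   evenly over chromosomes.
#' @param n_qtl Markers carrying nonzero trait effects.
#' @param var_additive,var_dominance Target in-sample variances (trait
#'   units squared) of the hybrids' additive and dominance genetic values.
#' @param var_gxe,var_residual Genotype-by-environment and plot-residual
#'   variances of the trial model.
#' @param n_environments,n_replicates Trial layout (replicates nested in
#'   environments).
#' @param n_subpopulations Subpopulations in the parental panel; each gets
#'   its own allele-frequency vector, creating PCA-visible structure.
#' @param allele_freq_range Interval in (0, 1) from which subpopulation
#'   allele frequencies are drawn.
#' @param mu Grand mean of the simulated trait.
#' @param env_effect_sd,rep_effect_sd Spread of the fixed environment and
#'   replicate-within-environment shifts (trait units); set to 0 for a
#'   noise-free trial in combination with zero `var_gxe`/`var_residual`.
#' @param seed Integer seed controlling every downstream draw.
#' @param reference_shaped If `TRUE`, override the mating-design fields with the
#'   204-hybrid layout (99 pollinators, groups 77/59/68, 44 shared).
#'
#' @return A list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(seed = 7)
#' cfg$n_markers
#' sum(sim_config(reference_shaped = TRUE)$group_sizes)  # 204 hybrids
sim_config <- function(n_pollinators = 60,
                       n_testers = 3,
                       group_sizes = c(45, 35, 40),
                       n_shared_pollinators = 25,
                       n_markers = 2000,
                       n_chromosomes = 10,
                       n_qtl = 100,
                       var_additive = 10,
                       var_dominance = 2,
                       var_gxe = 4,
                       var_residual = 7,
                       n_environments = 4,
                       n_replicates = 3,
                       n_subpopulations = 3,
                       allele_freq_range = c(0.1, 0.9),
                       mu = 50,
                       env_effect_sd = 5,
                       rep_effect_sd = 1,
                       seed = 1,
                       reference_shaped = FALSE) {
  if (reference_shaped) {
    n_pollinators <- 99
    n_testers <- 3
    group_sizes <- c(77, 59, 68)
    n_shared_pollinators <- 44
  }
  cfg <- list(n_pollinators = as.integer(n_pollinators),
              n_testers = as.integer(n_testers),
              group_sizes = as.integer(group_sizes),
              n_shared_pollinators = as.integer(n_shared_pollinators),
              n_markers = as.integer(n_markers),
              n_chromosomes = as.integer(n_chromosomes),
              n_qtl = as.integer(n_qtl),
              var_additive = var_additive,
              var_dominance = var_dominance,
              var_gxe = var_gxe,
              var_residual = var_residual,
              n_environments = as.integer(n_environments),
              n_replicates = as.integer(n_replicates),
              n_subpopulations = as.integer(n_subpopulations),
              allele_freq_range = as.numeric(allele_freq_range),
              mu = mu,
              env_effect_sd = env_effect_sd,
              rep_effect_sd = rep_effect_sd,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  counts <- c("n_pollinators", "n_testers", "n_markers", "n_chromosomes",
              "n_qtl", "n_environments", "n_replicates", "n_subpopulations")
  for (f in counts) {
    if (length(cfg[[f]]) != 1L || is.na(cfg[[f]]) || cfg[[f]] < 1L) {
      stop("'", f, "' must be a positive count", call. = FALSE)
    }
  }
  if (length(cfg$group_sizes) != cfg$n_testers) {
    stop("need one group size per tester", call. = FALSE)
  }
  if (any(cfg$group_sizes < 1L) || any(cfg$group_sizes > cfg$n_pollinators)) {
    stop("each group size must be in [1, n_pollinators]", call. = FALSE)
  }
  if (cfg$n_shared_pollinators < 0L ||
      cfg$n_shared_pollinators > min(cfg$group_sizes)) {
    stop("n_shared_pollinators must not exceed the smallest group",
         call. = FALSE)
  }
  if (cfg$n_qtl > cfg$n_markers) stop("n_qtl exceeds n_markers", call. = FALSE)
  vars <- c("var_additive", "var_dominance", "var_gxe", "var_residual",
            "env_effect_sd", "rep_effect_sd")
  if (any(unlist(cfg[vars]) < 0)) {
    stop("variances and effect scales must be >= 0", call. = FALSE)
  }
  r <- cfg$allele_freq_range
  if (length(r) != 2L || r[1] > r[2] || r[1] <= 0 || r[2] > 1) {
    stop("allele_freq_range must be an interval within (0, 1]", call. = FALSE)
  }
  invisible(cfg)
}

# evaluate `expr` under a private RNG stream, restoring the caller's state
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# derive a sub-seed for a named stage from the global seed (kept < 2^31)
stage_seed <- function(seed, stage) {
  offsets <- c(parents = 11, design = 23, effects = 37, phenos = 53,
               cv = 71)
  as.integer((as.numeric(seed) * 1009 + offsets[[stage]]) %% 2147483629)
}

#' Simulate a structured panel of homozygous parental lines
#'
#' Draws fully homozygous inbred genotypes (codes -1/+1, no residual
#' heterozygosity) for all testers and pollinators. The panel is split into
#' `n_subpopulations` contiguous blocks of lines; each subpopulation gets its
#' own per-marker allele frequency drawn uniformly from
#' `allele_freq_range`, which induces the kind of structure that shows up in
#' the leading principal components of real breeding panels. Markers are
#' assigned to chromosomes contiguously and as evenly as possible.
#'
#' @param config A [sim_config].
#' @return A [geno_matrix] with `n_testers + n_pollinators` rows (line IDs
#'   `T1..` for testers, `P1..` for pollinators) and an attribute
#'   `subpop` (named vector of subpopulation labels).
#' @export
simulate_parents <- function(config) {
  validate_sim_config(config)
  n_lines <- config$n_testers + config$n_pollinators
  if (config$n_subpopulations > n_lines) {
    stop("more subpopulations than lines", call. = FALSE)
  }
  m <- config$n_markers
  ids <- c(paste0("T", seq_len(config$n_testers)),
           paste0("P", seq_len(config$n_pollinators)))
  with_seed(stage_seed(config$seed, "parents"), {
    # contiguous subpopulation blocks of near-equal size
    subpop <- sort(rep_len(seq_len(config$n_subpopulations), n_lines))
    freq <- matrix(stats::runif(config$n_subpopulations * m,
                                config$allele_freq_range[1],
                                config$allele_freq_range[2]),
                   nrow = config$n_subpopulations)
    codes <- matrix(0, n_lines, m, dimnames = list(ids, NULL))
    for (s in seq_len(config$n_subpopulations)) {
      rows <- which(subpop == s)
      draws <- matrix(stats::rbinom(length(rows) * m, 1L,
                                    rep(freq[s, ], each = length(rows))),
                      nrow = length(rows))
      codes[rows, ] <- 2 * draws - 1
    }
    chrom <- rep(seq_len(config$n_chromosomes),
                 times = diff(round(seq(0, m, length.out =
                                          config$n_chromosomes + 1L))))
    pos <- unlist(lapply(split(seq_len(m), chrom), function(ix) {
      sort(sample.int(1e8, length(ix)))
    }), use.names = FALSE)
    map <- data.frame(marker = paste0("S", chrom, "_", seq_len(m)),
                      chrom = as.character(chrom), pos = pos,
                      ref = "A", alt = "T", stringsAsFactors = FALSE)
    colnames(codes) <- map$marker
    out <- geno_matrix(codes, map)
    attr(out, "subpop") <- stats::setNames(paste0("G", subpop), ids)
    out
  })
}

#' Build an overlapping tester-by-pollinator mating design
#'
#' Assigns pollinators to each tester's crossing group. The first
#' `n_shared_pollinators` pollinators enter every group; remaining slots are
#' filled from the rest of the pollinator pool, cycling so that every
#' pollinator is used before any non-shared pollinator appears in a second
#' group. Each (tester, pollinator) pair yields one F1 hybrid, so the hybrid
#' count equals `sum(group_sizes)`.
#'
#' @param config A [sim_config].
#' @return A data frame of class `mating_design` with columns `hybrid`,
#'   `female`, `male`, `group`.
#' @export
#' @examples
#' md <- make_mating_design(sim_config(reference_shaped = TRUE))
#' nrow(md)  # 204
make_mating_design <- function(config) {
  validate_sim_config(config)
  k <- config$n_shared_pollinators
  extra_slots <- config$group_sizes - k
  pool <- setdiff(seq_len(config$n_pollinators), seq_len(k))
  if (max(extra_slots) > length(pool)) {
    stop("group size exceeds available non-shared pollinators", call. = FALSE)
  }
  if (sum(extra_slots) > length(pool) * max(1L, config$n_testers - 1L)) {
    stop("infeasible overlap: not enough pollinators to fill the groups ",
         "without making extra pollinators shared by all testers",
         call. = FALSE)
  }
  groups <- with_seed(stage_seed(config$seed, "design"), {
    pool <- sample(pool)  # deterministic shuffle
    membership <- vector("list", config$n_testers)
    # pass 1: give each pollinator one group; pass 2: a second group, etc.
    remaining <- extra_slots
    used <- integer(0)
    while (sum(remaining) > 0L) {
      for (p in pool) {
        open <- which(remaining > 0L &
                        !vapply(membership, function(g) p %in% g, logical(1)))
        if (length(open) == 0L) next
        g <- open[which.max(remaining[open])]
        membership[[g]] <- c(membership[[g]], p)
        remaining[g] <- remaining[g] - 1L
        if (sum(remaining) == 0L) break
      }
    }
    lapply(membership, function(extra) c(seq_len(k), sort(extra)))
  })
  recs <- do.call(rbind, lapply(seq_len(config$n_testers), function(t) {
    males <- groups[[t]]
    data.frame(female = paste0("T", t), male = paste0("P", males),
               group = paste0("G", t), stringsAsFactors = FALSE)
  }))
  recs <- data.frame(hybrid = paste0("H", seq_len(nrow(recs))), recs,
                     stringsAsFactors = FALSE)
  class(recs) <- c("mating_design", "data.frame")
  recs
}

#' Simulate QTL effects and true genetic values of the hybrids
#'
#' Samples `n_qtl` QTL positions without replacement, draws additive and
#' dominance allele-substitution effects from mean-zero Gaussians, and then
#' rescales each effect vector so that the in-sample variance of the hybrids'
#' additive (and dominance) genetic values hits `var_additive`
#' (`var_dominance`) exactly. Non-QTL markers carry exactly zero effect.
#'
#' @param config A [sim_config].
#' @param genotypes Parental [geno_matrix] from [simulate_parents()].
#' @param design Mating design from [make_mating_design()]; needed because
#'   the variance targets are defined over the simulated hybrids.
#' @return A list of class `true_values` with per-marker effect vectors `a`
#'   and `d`, the QTL marker IDs, and per-hybrid values `g_additive`,
#'   `g_dominance` and their sum `g_total`.
#' @export
simulate_effects <- function(config, genotypes, design) {
  validate_sim_config(config)
  stopifnot(inherits(genotypes, "geno_matrix"), inherits(design, "data.frame"))
  m <- ncol(genotypes$codes)
  if (config$n_qtl > m) stop("n_qtl exceeds marker count", call. = FALSE)
  hd <- make_hybrid_design(genotypes, design)
  with_seed(stage_seed(config$seed, "effects"), {
    qtl <- sort(sample.int(m, config$n_qtl))
    a <- numeric(m)
    d <- numeric(m)
    if (config$var_additive > 0) {
      a[qtl] <- stats::rnorm(config$n_qtl)
      g_a <- drop(hd$K_A %*% a)
      if (stats::var(g_a) == 0) {
        stop("all QTL are non-segregating among the hybrids; ",
             "cannot realize additive variance", call. = FALSE)
      }
      a <- a * sqrt(config$var_additive / stats::var(g_a))
    }
    if (config$var_dominance > 0) {
      d[qtl] <- stats::rnorm(config$n_qtl)
      g_d <- drop(hd$K_D %*% d)
      if (stats::var(g_d) == 0) {
        stop("no heterozygous QTL among the hybrids; ",
             "cannot realize dominance variance", call. = FALSE)
      }
      d <- d * sqrt(config$var_dominance / stats::var(g_d))
    }
    g_additive <- drop(hd$K_A %*% a)
    g_dominance <- drop(hd$K_D %*% d)
    structure(list(a = stats::setNames(a, colnames(genotypes$codes)),
                   d = stats::setNames(d, colnames(genotypes$codes)),
                   qtl = colnames(genotypes$codes)[qtl],
                   g_additive = stats::setNames(g_additive, design$hybrid),
                   g_dominance = stats::setNames(g_dominance, design$hybrid),
                   g_total = stats::setNames(g_additive + g_dominance,
                                             design$hybrid)),
              class = "true_values")
  })
}

#' Simulate a balanced multi-environment hybrid trial
#'
#' Generates one phenotypic record per hybrid x environment x replicate from
#' the trial model `y = mu + g + env + rep(env) + gxe + error`: the hybrid's
#' total genetic value plus a fixed environment shift, a fixed
#' replicate-within-environment shift, an independent mean-zero
#' genotype-by-environment deviate (variance `var_gxe`) and a residual
#' (variance `var_residual`).
#'
#' @param design Mating design from [make_mating_design()].
#' @param values `true_values` from [simulate_effects()].
#' @param config A [sim_config].
#' @param trait Trait name written into the table.
#' @return A long-format data frame with columns `hybrid`, `environment`,
#'   `replicate`, `trait`, `value`.
#' @export
simulate_phenotypes <- function(design, values, config, trait = "trait1") {
  validate_sim_config(config)
  stopifnot(inherits(values, "true_values"))
  if (!all(design$hybrid %in% names(values$g_total))) {
    stop("genetic values missing for hybrid(s): ",
         paste(setdiff(design$hybrid, names(values$g_total)), collapse = ", "),
         call. = FALSE)
  }
  n_h <- nrow(design)
  e <- config$n_environments
  r <- config$n_replicates
  with_seed(stage_seed(config$seed, "phenos"), {
    env_eff <- stats::rnorm(e, 0, config$env_effect_sd)   # fixed env shifts
    rep_eff <- matrix(stats::rnorm(e * r, 0, config$rep_effect_sd), e, r)
    gxe <- matrix(stats::rnorm(n_h * e, 0, sqrt(config$var_gxe)), n_h, e)
    tab <- expand.grid(replicate = paste0("R", seq_len(r)),
                       environment = paste0("E", seq_len(e)),
                       hybrid = design$hybrid,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    hi <- match(tab$hybrid, design$hybrid)
    ei <- as.integer(sub("E", "", tab$environment))
    ri <- as.integer(sub("R", "", tab$replicate))
    tab$trait <- trait
    tab$value <- config$mu + values$g_total[hi] + env_eff[ei] +
      rep_eff[cbind(ei, ri)] + gxe[cbind(hi, ei)] +
      stats::rnorm(nrow(tab), 0, sqrt(config$var_residual))
    rownames(tab) <- NULL
    tab[, c("hybrid", "environment", "replicate", "trait", "value")]
  })
}

#' Simulate a complete hybrid genomic-prediction dataset
#'
#' Convenience wrapper chaining [simulate_parents()], [make_mating_design()],
#' [simulate_effects()] and [simulate_phenotypes()].
#'
#' @param config A [sim_config].
#' @param trait Trait name for the phenotype table.
#' @return A list with `genotypes`, `design`, `values`, `phenotypes` and the
#'   `config` used.
#' @export
#' @examples
#' sim <- simulate_dataset(sim_config(n_markers = 200, seed = 3))
#' head(sim$phenotypes)
simulate_dataset <- function(config = sim_config(), trait = "trait1") {
  genotypes <- simulate_parents(config)
  design <- make_mating_design(config)
  values <- simulate_effects(config, genotypes, design)
  phenotypes <- simulate_phenotypes(design, values, config, trait = trait)
  list(genotypes = genotypes, design = design, values = values,
       phenotypes = phenotypes, config = config)
}
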