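test_that("parental lines are homozygous and reproducible from the seed", {
  cfg <- test_config(seed = 7)
  g1 <- simulate_parents(cfg)
  g2 <- simulate_parents(cfg)
  expect_identical(g1$codes, g2$codes)
  expect_true(all(g1$codes %in% c(-1, 1)))
  expect_equal(nrow(g1$codes), cfg$n_testers + cfg$n_pollinators)
  expect_equal(length(unique(g1$map$chrom)), cfg$n_chromosomes)
  # contiguous chromosome blocks
  expect_false(is.unsorted(as.integer(g1$map$chrom)))
  # a different seed gives different genotypes
  expect_false(identical(g1$codes,
                         simulate_parents(test_config(seed = 8))$codes))
})

test_that("degenerate allele frequency fixes the whole panel", {
  cfg <- test_config(n_subpopulations = 1,
                     allele_freq_range = c(1, 1), seed = 3)
  g <- simulate_parents(cfg)
  expect_true(all(g$codes == 1))
})

test_that("subpopulation structure is visible on the first PC", {
  cfg <- sim_config(n_pollinators = 47, n_testers = 3,
                    group_sizes = c(10, 10, 10), n_shared_pollinators = 5,
                    n_markers = 500, n_subpopulations = 2, seed = 21)
  g <- simulate_parents(cfg)
  grp <- attr(g, "subpop")
  # independent oracle: PCA straight from the raw code matrix
  pc1 <- prcomp(g$codes, center = TRUE)$x[, 1]
  # silhouette of the PC1 grouping, computed from first principles
  sil <- vapply(seq_along(pc1), function(i) {
    d <- abs(pc1 - pc1[i])
    a <- mean(d[setdiff(which(grp == grp[i]), i)])
    b <- mean(d[grp != grp[i]])
    (b - a) / max(a, b)
  }, numeric(1))
  expect_gt(mean(sil), 0)
  # and the package's own PCA agrees with the oracle up to sign
  scores <- pca_genotypes(g, 2)$scores[, 1]
  expect_equal(abs(cor(scores, pc1)), 1, tolerance = 1e-8)
})

test_that("mating design honors group sizes and pollinator sharing", {
  md <- make_mating_design(sim_config(reference_shaped = TRUE))
  expect_equal(nrow(md), 204)
  expect_equal(as.vector(table(md$group)), c(77, 59, 68))
  groups_per_male <- tapply(md$group, md$male, function(g) length(unique(g)))
  expect_equal(sum(groups_per_male == 3), 44)
  expect_equal(length(unique(md$male)), 99)
  expect_false(anyDuplicated(md$hybrid) > 0)
  # deterministic under the seed
  expect_identical(md, make_mating_design(sim_config(reference_shaped = TRUE)))

  # disjoint two-group design: sizes add, no male crosses groups
  md2 <- make_mating_design(sim_config(n_pollinators = 6, n_testers = 2,
                                       group_sizes = c(2, 3),
                                       n_shared_pollinators = 0))
  expect_equal(nrow(md2), 5)
  expect_true(all(tapply(md2$group, md2$male,
                         function(g) length(unique(g))) == 1))

  expect_error(sim_config(n_pollinators = 10, n_testers = 2,
                          group_sizes = c(3, 5), n_shared_pollinators = 4),
               "smallest group")
})

test_that("QTL effects hit the target variances and respect sparsity", {
  cfg <- test_config(seed = 5)
  g <- simulate_parents(cfg)
  md <- make_mating_design(cfg)
  tv <- simulate_effects(cfg, g, md)
  expect_equal(sum(tv$a != 0), cfg$n_qtl)
  expect_true(all(names(tv$a)[tv$a != 0] %in% tv$qtl))
  # rescaling makes the in-sample variances exact
  expect_equal(var(tv$g_additive), cfg$var_additive, tolerance = 1e-10)
  expect_equal(var(tv$g_dominance), cfg$var_dominance, tolerance = 1e-10)

  # zero dominance variance means identically zero dominance effects
  cfg0 <- test_config(var_dominance = 0, seed = 5)
  tv0 <- simulate_effects(cfg0, g, md)
  expect_true(all(tv0$d == 0))

  # dense architecture: every marker carries an effect
  cfgd <- test_config(n_qtl = 300, seed = 9)
  tvd <- simulate_effects(cfgd, g, md)
  expect_true(all(tvd$a != 0))

  # a single additive QTL yields at most three genetic-value levels
  cfg1 <- test_config(n_qtl = 1, var_dominance = 0, seed = 13)
  tv1 <- simulate_effects(cfg1, g, md)
  expect_lte(length(unique(round(tv1$g_total, 10))), 3L)
})

test_that("phenotypes are balanced and collapse to mu + g without noise", {
  cfg <- test_config(n_environments = 2, n_replicates = 3,
                     var_gxe = 0, var_residual = 0,
                     env_effect_sd = 0, rep_effect_sd = 0, seed = 17)
  sim <- simulate_dataset(cfg)
  ph <- sim$phenotypes
  expect_equal(nrow(ph), nrow(sim$design) * 2 * 3)
  # every hybrid exactly once per environment x replicate cell
  expect_true(all(table(ph$hybrid, ph$environment, ph$replicate) == 1))
  expect_equal(ph$value,
               cfg$mu + unname(sim$values$g_total[ph$hybrid]),
               tolerance = 1e-12)
  # same seed, same table
  expect_identical(ph, simulate_phenotypes(sim$design, sim$values, cfg))
  # unknown hybrids are rejected
  bad <- sim$design
  bad$hybrid[1] <- "HX"
  expect_error(simulate_phenotypes(bad, sim$values, cfg), "HX")
})

test_that("realized heritability of entry means matches the variance targets", {
  cfg <- sim_config(n_pollinators = 180, n_testers = 3,
                    group_sizes = c(170, 165, 165),
                    n_shared_pollinators = 160, n_markers = 400,
                    n_qtl = 100, seed = 29)
  sim <- simulate_dataset(cfg)
  vc <- estimate_components(sim$phenotypes)
  s2g <- var(sim$values$g_total)
  target_H <- s2g / (s2g + cfg$var_gxe / cfg$n_environments +
                       cfg$var_residual /
                       (cfg$n_environments * cfg$n_replicates))
  expect_lt(abs(vc$H - target_H), 0.05)
})
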