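test_that("fold partitions are balanced, disjoint, covering and seeded", {
  ids204 <- paste0("H", 1:204)
  folds <- make_folds(ids204, 5, seed = 1)
  expect_equal(sort(lengths(folds), decreasing = TRUE),
               c(41, 41, 41, 41, 40))
  expect_setequal(unlist(folds), ids204)
  expect_equal(length(unlist(folds)), 204)

  f10 <- make_folds(paste0("H", 1:10), 5, seed = 2)
  expect_true(all(lengths(f10) == 2))
  expect_equal(anyDuplicated(unlist(f10)), 0)

  expect_identical(make_folds(ids204, 5, seed = 9),
                   make_folds(ids204, 5, seed = 9))
  expect_false(identical(make_folds(ids204, 5, seed = 9),
                         make_folds(ids204, 5, seed = 10)))
  expect_error(make_folds(paste0("H", 1:3), 5, seed = 1), "folds")
})

test_that("standardized accuracy divides the correlation by sqrt(H)", {
  obs <- c(1, 2, 3, 5)
  pred <- c(1.2, 1.9, 3.4, 4.6)
  res <- standardized_accuracy(obs, pred, H = 0.49)
  # brute-force Pearson correlation from first principles
  r_oracle <- sum((obs - mean(obs)) * (pred - mean(pred))) /
    sqrt(sum((obs - mean(obs))^2) * sum((pred - mean(pred))^2))
  expect_equal(res$raw_r, r_oracle, tolerance = 1e-12)
  expect_equal(res$accuracy, r_oracle / 0.7, tolerance = 1e-12)

  expect_equal(standardized_accuracy(obs, obs, H = 1)$accuracy, 1)
  # r = 0.5 with H = 0.25 standardizes to 1
  set.seed(5)
  expect_error(standardized_accuracy(obs, rep(1, 4), H = 0.5), "variance")
  expect_error(standardized_accuracy(obs, pred, H = 0), "H")
  expect_error(standardized_accuracy(obs[1:2], pred[1:2], H = 1), "pairs")
})

test_that("cross-validation is reproducible and reports exact means", {
  cfg <- test_config(seed = 4)
  sim <- simulate_dataset(cfg)
  sc <- cv_scheme("fivefold", iterations = 2, seed = 11)
  r1 <- run_cv(sim$phenotypes, sim$genotypes, sim$design, sc)
  r2 <- run_cv(sim$phenotypes, sim$genotypes, sim$design, sc)
  expect_identical(r1$replicates, r2$replicates)
  expect_equal(r1$mean_accuracy, mean(r1$replicates$accuracy))
  expect_equal(nrow(r1$replicates), 2 * 5)
  # a different scheme seed re-randomizes
  r3 <- run_cv(sim$phenotypes, sim$genotypes, sim$design,
               cv_scheme("fivefold", iterations = 2, seed = 12))
  expect_false(identical(r1$replicates$raw_r, r3$replicates$raw_r))
})

test_that("tp_size draws the requested training size", {
  cfg <- test_config(seed = 6)
  sim <- simulate_dataset(cfg)
  sc <- cv_scheme("tp_size", n_tp = 24, iterations = 3, seed = 2)
  res <- run_cv(sim$phenotypes, sim$genotypes, sim$design, sc)
  expect_true(all(res$replicates$n_tp == 24))
  expect_equal(nrow(res$replicates), 3)
  expect_error(run_cv(sim$phenotypes, sim$genotypes, sim$design,
                      cv_scheme("tp_size", n_tp = 60, iterations = 1)),
               "smaller")
})

test_that("a trait without genetic signal has accuracy near zero", {
  cfg <- test_config(var_additive = 0, var_dominance = 0, n_qtl = 20,
                     seed = 10)
  sim <- simulate_dataset(cfg)
  res <- run_cv(sim$phenotypes, sim$genotypes, sim$design,
                cv_scheme("fivefold", iterations = 10, seed = 3),
                H = 1)
  expect_lt(abs(res$mean_accuracy), 0.1)
})

test_that("relatedness splits reproduce tester-group arithmetic", {
  md <- make_mating_design(sim_config(reference_shaped = TRUE))
  sp <- relatedness_split(md, "common_male")
  sizes <- sapply(sp, function(s) c(length(s$tp), length(s$vp)))
  expect_true(all(colSums(sizes) == 204))
  expect_true(any(sizes[1, ] == 136 & sizes[2, ] == 68))
  # held-out tester's hybrids share males but never the female
  for (s in sp) {
    vp_rows <- md[md$hybrid %in% s$vp, ]
    tp_rows <- md[md$hybrid %in% s$tp, ]
    expect_length(intersect(unique(vp_rows$female),
                            unique(tp_rows$female)), 0)
    expect_gt(length(intersect(unique(vp_rows$male),
                               unique(tp_rows$male))), 0)
  }

  spf <- relatedness_split(md, "common_female")
  expect_equal(length(spf[[1]]$tp), 77)
  expect_equal(length(spf[[1]]$vp), 127)
  tp_rows <- md[md$hybrid %in% spf[[1]]$tp, ]
  vp_rows <- md[md$hybrid %in% spf[[1]]$vp, ]
  # sides share female testers but never a male
  expect_length(intersect(unique(tp_rows$male), unique(vp_rows$male)), 0)
  expect_gt(length(intersect(unique(tp_rows$female),
                             unique(vp_rows$female))), 0)

  # disjoint single-cross groups admit no common-male scheme
  md2 <- make_mating_design(sim_config(n_pollinators = 6, n_testers = 2,
                                       group_sizes = c(2, 3),
                                       n_shared_pollinators = 0))
  expect_error(relatedness_split(md2, "common_male"), "impossible")
})

test_that("relatedness CV runs end to end on a small design", {
  cfg <- test_config(seed = 14)
  sim <- simulate_dataset(cfg)
  res <- relatedness_cv(sim$phenotypes, sim$genotypes, sim$design,
                        kind = "common_male")
  expect_equal(nrow(res$replicates), 3)
  expect_equal(res$replicates$n_tp + res$replicates$n_vp,
               rep(nrow(sim$design), 3))
  resf <- relatedness_cv(sim$phenotypes, sim$genotypes, sim$design,
                         kind = "common_female")
  expect_equal(resf$replicates$n_tp, max(table(sim$design$female)))
})

test_that("percent gains follow the half-away-from-zero rounding", {
  expect_equal(accuracy_gain(c(0.25, 0.30)), 20)
  expect_equal(accuracy_gain(c(0.46, 0.59)), 28)
  expect_equal(accuracy_gain(c(0.4, 0.4)), 0)
  expect_equal(accuracy_gain(c(0.09, 0.23)), 156)   # 155.6 rounds up
  expect_equal(accuracy_gain(c(0.18, 0.34)), 89)    # 88.9 rounds up
  expect_equal(accuracy_gain(c(0.4, 0.2)), -50)
  expect_error(accuracy_gain(c(0, 0.2)), "zero")
  expect_error(accuracy_gain(0.3), "2")
})
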