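# shared small instance: 20 hybrids x 50 markers from random inbred parents
rr_instance <- function(seed, n = 20, m = 50) {
  g <- random_inbred_geno(12, m, seed = seed)
  set.seed(seed + 500)
  des <- data.frame(hybrid = paste0("H", seq_len(n)),
                    female = sample(rownames(g$codes), n, replace = TRUE),
                    male = sample(rownames(g$codes), n, replace = TRUE))
  hd <- make_hybrid_design(g, des)
  y <- drop(hd$K_A %*% rnorm(m, 0, 0.3)) + rnorm(n)
  names(y) <- des$hybrid
  list(hd = hd, y = y)
}

test_that("fixed-lambda solution equals the normal-equations ridge oracle", {
  for (seed in 1:5) {
    inst <- rr_instance(seed)
    lambda <- exp(runif(1, -1, 3))
    fit <- fit_partial(inst$y, inst$hd$K_A, lambda = lambda)
    # dense oracle: a = (K'K + lambda I)^-1 K'(y - mu)
    K <- inst$hd$K_A
    a_oracle <- solve(crossprod(K) + lambda * diag(ncol(K)),
                      crossprod(K, inst$y - fit$mu))
    expect_equal(unname(fit$a), unname(drop(a_oracle)), tolerance = 1e-8)
  }
})

test_that("marker-effect RR-BLUP and kernel GBLUP predictions coincide", {
  for (seed in 1:5) {
    inst <- rr_instance(seed + 10)
    fit <- fit_partial(inst$y, inst$hd$K_A)
    K <- inst$hd$K_A
    G <- tcrossprod(K)
    # kernel-form fitted values at the same variance ratio
    gbv <- drop(G %*% solve(G + fit$lambda * diag(nrow(G)),
                            inst$y - fit$mu))
    expect_equal(unname(fit$fitted), unname(fit$mu + gbv), tolerance = 1e-8)
    # and for out-of-sample rows: K_new a == G_new (G + lambda I)^-1 r
    newg <- random_inbred_geno(4, 50, seed = seed + 200)
    K_new <- newg$codes
    pred <- predict(fit, K_new)
    gbv_new <- drop(tcrossprod(K_new, K) %*%
                      solve(G + fit$lambda * diag(nrow(G)),
                            inst$y - fit$mu))
    expect_equal(pred$value, unname(gbv_new), tolerance = 1e-8)
  }
})

test_that("extreme shrinkage collapses predictions to the mean", {
  inst <- rr_instance(99)
  y <- inst$y * 0 + 5 + rnorm(length(inst$y), 0, 1e-6)
  names(y) <- names(inst$y)
  fit <- fit_partial(y, inst$hd$K_A, lambda = 1e10)
  expect_lt(max(abs(fit$a)), 1e-8)
  expect_equal(unname(fit$fitted), rep(mean(y), length(y)),
               tolerance = 1e-4)
})

test_that("effect norms shrink monotonically in lambda", {
  inst <- rr_instance(7)
  norms <- sapply(10^seq(-2, 4, by = 1), function(l) {
    sqrt(sum(fit_partial(inst$y, inst$hd$K_A, lambda = l)$a^2))
  })
  expect_true(all(diff(norms) < 0))
})

test_that("permuting hybrids permutes predictions identically", {
  inst <- rr_instance(15)
  fit <- fit_partial(inst$y, inst$hd$K_A)
  set.seed(1)
  perm <- sample(length(inst$y))
  fitp <- fit_partial(inst$y[perm], inst$hd$K_A[perm, ])
  expect_equal(fitp$fitted, fit$fitted[perm], tolerance = 1e-6)
  expect_equal(fitp$mu, fit$mu, tolerance = 1e-6)
})

test_that("noise-free additive data is predicted almost perfectly", {
  cfg <- sim_config(n_pollinators = 40, group_sizes = c(35, 30, 35),
                    n_shared_pollinators = 20, n_markers = 300, n_qtl = 40,
                    var_dominance = 0, var_gxe = 0, var_residual = 0,
                    env_effect_sd = 0, rep_effect_sd = 0, seed = 61)
  sim <- simulate_dataset(cfg)
  hd <- make_hybrid_design(sim$genotypes, sim$design)
  y <- hybrid_means(sim$phenotypes)[rownames(hd$K_A)]
  tp <- sim$design$hybrid[1:80]
  vp <- setdiff(sim$design$hybrid, tp)
  fit <- fit_partial(y[tp], hd$K_A[tp, ])
  pred <- predict(fit, hd$K_A[vp, ])
  expect_gt(cor(pred$value, sim$values$g_total[vp]), 0.99)
})

test_that("full model degenerates gracefully and honors its contracts", {
  inst <- rr_instance(3)
  K_D0 <- inst$hd$K_D * 0
  expect_warning(fit0 <- fit_full(inst$y, inst$hd$K_A, K_D0),
                 "identically zero")
  ref <- fit_partial(inst$y, inst$hd$K_A)
  expect_equal(fit0$fitted, ref$fitted, tolerance = 1e-10)
  expect_equal(fit0$model, "full")
  expect_true(all(fit0$d == 0))

  # misalignment errors
  expect_error(fit_full(inst$y, inst$hd$K_A, inst$hd$K_D[, -1]), "shape")
  expect_error(fit_partial(inst$y[-1], inst$hd$K_A), "rows|entries")
  expect_error(fit_partial(rep(1, 20), matrix(rnorm(20 * 5), 20)),
               "constant")
})

test_that("full-model fits recover dominance signal when present", {
  cfg <- sim_config(n_pollinators = 35, group_sizes = c(30, 28, 30),
                    n_shared_pollinators = 20, n_markers = 250, n_qtl = 50,
                    var_additive = 8, var_dominance = 8, var_gxe = 1,
                    var_residual = 2, seed = 71)
  sim <- simulate_dataset(cfg)
  hd <- make_hybrid_design(sim$genotypes, sim$design)
  y <- hybrid_means(sim$phenotypes)[rownames(hd$K_A)]
  fit <- fit_full(y, hd$K_A, hd$K_D)
  # the dominance kernel must carry a non-trivial share of the variance
  gd <- drop(hd$K_D %*% fit$d)
  expect_gt(var(gd), 0.05 * var(y))
  expect_gt(cor(fit$fitted, sim$values$g_total), 0.9)
})

test_that("prediction applies stored effects as plain linear algebra", {
  inst <- rr_instance(21)
  fit <- fit_partial(inst$y, inst$hd$K_A)
  # training rows reproduce the in-sample fitted values
  pr <- predict(fit, inst$hd$K_A)
  expect_equal(pr$predicted, unname(fit$fitted), tolerance = 1e-10)
  # all-zero design rows predict the intercept
  z <- matrix(0, 2, ncol(inst$hd$K_A))
  expect_equal(predict(fit, z)$predicted, rep(fit$mu, 2))
  # random new rows: brute-force matrix-vector product
  newK <- matrix(sample(c(-1, 0, 1), 3 * ncol(inst$hd$K_A), replace = TRUE),
                 nrow = 3)
  expect_equal(predict(fit, newK)$value, drop(newK %*% fit$a),
               tolerance = 1e-12)
  # a full fit refuses to predict without dominance rows
  instf <- rr_instance(22)
  ff <- fit_full(instf$y, instf$hd$K_A, instf$hd$K_D)
  expect_error(predict(ff, instf$hd$K_A), "K_D_new")
})
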