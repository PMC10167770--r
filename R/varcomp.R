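#' Variance components of a multi-environment hybrid trial
#'
#' Estimates the genetic, genotype-by-environment and residual variance of a
#' replicated multi-environment trial under the model
#' `y = mu + g + env + rep(env) + gxe + error`, with environment and
#' replicate-within-environment fixed and genotype and G-by-E random, and
#' returns them together with the broad-sense heritability of entry means.
#'
#' For balanced data (every hybrid observed once in every environment x
#' replicate cell) the default `"anova"` method solves the expected mean
#' squares in closed form: with g hybrids, e environments and r replicates,
#' `sigma2_e = MS_res`, `sigma2_ge = (MS_GxE - MS_res) / r` and
#' `sigma2_g = (MS_G - MS_GxE) / (e * r)`, negative solutions truncated to
#' zero. The `"reml"` method fits the same model by restricted maximum
#' likelihood through `lme4::lmer` and also accepts unbalanced tables;
#' residual variance is assumed homogeneous across environments.
#'
#' @param phenotypes Long-format data frame with columns `hybrid`,
#'   `environment`, `replicate`, `trait`, `value`.
#' @param trait Trait to analyze (default: the only trait present).
#' @param method `"anova"` (balanced closed form) or `"reml"`.
#' @return A list of class `variance_components`: `sigma2_g`, `sigma2_ge`,
#'   `sigma2_e`, `r`, `e`, `n_hybrids`, `H` (see
#'   [broad_sense_heritability()]), `trait` and `method`.
#' @export
#' @examples
#' sim <- simulate_dataset(sim_config(n_markers = 200, seed = 2))
#' estimate_components(sim$phenotypes)
estimate_components <- function(phenotypes, trait = NULL,
                                method = c("anova", "reml")) {
  method <- match.arg(method)
  ph <- check_phenotypes(phenotypes, trait)
  g <- length(unique(ph$hybrid))
  e <- length(unique(ph$environment))
  r <- length(unique(ph$replicate))
  if (g < 2L || e < 2L || r < 2L) {
    stop("need at least 2 hybrids, 2 environments and 2 replicates",
         call. = FALSE)
  }
  balanced <- all(table(ph$hybrid, ph$environment, ph$replicate) == 1L)
  if (method == "anova") {
    if (!balanced) {
      stop("unbalanced phenotype table: the closed-form ANOVA path needs ",
           "every hybrid x environment x replicate cell filled exactly ",
           "once; use method = \"reml\"", call. = FALSE)
    }
    # closed-form sums of squares for the balanced orthogonal layout
    y <- ph$value
    gbar <- mean(y)
    m_g <- tapply(y, ph$hybrid, mean)                      # hybrid means
    m_e <- tapply(y, ph$environment, mean)                 # env means
    m_ge <- tapply(y, list(ph$hybrid, ph$environment), mean)
    m_er <- tapply(y, list(ph$environment, ph$replicate), mean)
    ms_g <- e * r * sum((m_g - gbar)^2) / (g - 1)
    ge_dev <- sweep(sweep(m_ge, 1, m_g), 2, m_e) + gbar
    ms_ge <- r * sum(ge_dev^2) / ((g - 1) * (e - 1))
    resid <- y - m_ge[cbind(ph$hybrid, ph$environment)] -
      m_er[cbind(ph$environment, ph$replicate)] +
      m_e[ph$environment]
    ms_res <- sum(resid^2) / (e * (g - 1) * (r - 1))
    sigma2_e <- ms_res
    sigma2_ge <- max(0, (ms_ge - ms_res) / r)
    sigma2_g <- max(0, (ms_g - ms_ge) / (e * r))
  } else {
    fit <- lme4::lmer(value ~ environment + environment:replicate +
                        (1 | hybrid) + (1 | hybrid:environment),
                      data = ph, REML = TRUE,
                      control = lme4::lmerControl(check.conv.singular =
                                                    "ignore"))
    vc <- as.data.frame(lme4::VarCorr(fit))
    pick <- function(grp) {
      v <- vc$vcov[vc$grp == grp]
      if (length(v) != 1L) stop("degenerate strata in REML fit", call. = FALSE)
      v
    }
    sigma2_g <- pick("hybrid")
    sigma2_ge <- pick("hybrid:environment")
    sigma2_e <- pick("Residual")
  }
  out <- structure(list(sigma2_g = unname(sigma2_g),
                        sigma2_ge = unname(sigma2_ge),
                        sigma2_e = unname(sigma2_e),
                        r = r, e = e, n_hybrids = g,
                        trait = ph$trait[1], method = method),
                   class = "variance_components")
  out$H <- broad_sense_heritability(out)
  out
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf(paste0("variance components for '%s' (%s): sigma2_g = %.4g, ",
                     "sigma2_ge = %.4g, sigma2_e = %.4g (e = %d, r = %d), ",
                     "H = %.3f\n"),
              x$trait, x$method, x$sigma2_g, x$sigma2_ge, x$sigma2_e,
              x$e, x$r, x$H))
  invisible(x)
}

#' Broad-sense heritability of entry means
#'
#' `H = sigma2_g / (sigma2_g + sigma2_ge / e + sigma2_e / (e * r))`: the
#' share of the variance of across-environment hybrid means attributable to
#' genetic differences, for a trial with `e` environments and `r` replicates
#' per environment. The result is clipped to \[0, 1\].
#'
#' @param vc A `variance_components` object, or a list with fields
#'   `sigma2_g`, `sigma2_ge`, `sigma2_e`, `e`, `r`.
#' @return Heritability in \[0, 1\].
#' @export
#' @examples
#' broad_sense_heritability(list(sigma2_g = 10.2, sigma2_ge = 3.93,
#'                               sigma2_e = 6.8, e = 4, r = 3))
broad_sense_heritability <- function(vc) {
  v <- unlist(vc[c("sigma2_g", "sigma2_ge", "sigma2_e")])
  if (any(v < 0)) stop("variance components must be >= 0", call. = FALSE)
  if (vc$e < 1 || vc$r < 1) stop("e and r must be >= 1", call. = FALSE)
  denom <- vc$sigma2_g + vc$sigma2_ge / vc$e + vc$sigma2_e / (vc$e * vc$r)
  if (denom <= 0) stop("all variance components are zero", call. = FALSE)
  min(1, max(0, vc$sigma2_g / denom))
}

#' Across-environment hybrid means
#'
#' Arithmetic mean of each hybrid's observations over all environments and
#' replicates, the phenotype that the genomic prediction models are fitted
#' to.
#'
#' @inheritParams estimate_components
#' @param hybrids Optional hybrid IDs that must all be present (error if
#'   any is unobserved).
#' @return Named numeric vector of per-hybrid means.
#' @export
hybrid_means <- function(phenotypes, trait = NULL, hybrids = NULL) {
  ph <- check_phenotypes(phenotypes, trait)
  m <- c(tapply(ph$value, ph$hybrid, mean))
  if (!is.null(hybrids)) {
    absent <- setdiff(hybrids, names(m))
    if (length(absent) > 0L) {
      stop("no phenotypic records for hybrid(s): ",
           paste(absent, collapse = ", "), call. = FALSE)
    }
    m <- m[hybrids]
  }
  m
}

# validate the long phenotype table and slice out one trait
check_phenotypes <- function(phenotypes, trait = NULL) {
  ph <- as.data.frame(phenotypes)
  need <- c("hybrid", "environment", "replicate", "trait", "value")
  if (!all(need %in% names(ph))) {
    stop("phenotype table needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(trait)) {
    trait <- unique(ph$trait)
    if (length(trait) > 1L) {
      stop("several traits present; pick one with 'trait ='", call. = FALSE)
    }
  }
  ph <- ph[ph$trait == trait, , drop = FALSE]
  if (nrow(ph) == 0L) stop("no records for trait '", trait, "'", call. = FALSE)
  if (!all(is.finite(ph$value))) {
    stop("non-finite phenotype value(s)", call. = FALSE)
  }
  key <- paste(ph$hybrid, ph$environment, ph$replicate, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (hybrid, environment, replicate) record(s)",
         call. = FALSE)
  }
  ph
}
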