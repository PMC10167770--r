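#' Fit the additive-only (partial) RR-BLUP model
#'
#' Fits `y = 1 mu + K_A a + e` with marker effects
#' `a ~ N(0, sigma2_a I)` and residuals `e ~ N(0, sigma2_e I)`: every marker
#' effect is shrunk under a common-variance Gaussian prior. The variance
#' ratio is estimated by restricted maximum likelihood through a spectral
#' decomposition of the additive kernel `G = K_A K_A'`, after which the
#' intercept is the generalized-least-squares mean and the effects are the
#' BLUP back-solution `a = K_A' (G + lambda I)^-1 (y - mu)` with
#' `lambda = sigma2_e / sigma2_a`.
#'
#' @param y Named numeric vector of per-hybrid phenotypes (typically
#'   across-environment means from [hybrid_means()]).
#' @param K_A Additive design matrix (hybrids x markers), rows aligned with
#'   `y`.
#' @param lambda Optional fixed ridge parameter; when supplied, REML is
#'   skipped and the ridge solution at this `lambda` is returned.
#' @return An object of class `gp_fit`: `mu`, `a` (named effect vector),
#'   `sigma2_a`, `sigma2_e`, `lambda`, `fitted` (in-sample `mu + K_A a`),
#'   `model = "partial"`.
#' @export
#' @examples
#' sim <- simulate_dataset(sim_config(n_markers = 300, seed = 5))
#' hd <- make_hybrid_design(sim$genotypes, sim$design)
#' y <- hybrid_means(sim$phenotypes)[rownames(hd$K_A)]
#' fit <- fit_partial(y, hd$K_A)
#' fit$sigma2_a / fit$sigma2_e
fit_partial <- function(y, K_A, lambda = NULL) {
  y <- check_y(y, K_A, "K_A")
  n <- length(y)
  if (n < 3L) stop("need at least 3 observations", call. = FALSE)
  G <- tcrossprod(K_A)
  if (is.null(lambda)) {
    vc <- reml_single_kernel(y, G)
  } else {
    stopifnot(is.numeric(lambda), lambda > 0)
    # treat lambda as known: only mu and the effect scale remain
    vc <- list(delta = lambda, sigma2_u = NA_real_, sigma2_e = NA_real_)
  }
  Vinv_r <- solve(G + vc$delta * diag(n))
  one <- rep(1, n)
  mu <- drop(crossprod(one, Vinv_r %*% y) / crossprod(one, Vinv_r %*% one))
  a <- drop(crossprod(K_A, Vinv_r %*% (y - mu)))
  fitted <- drop(mu + K_A %*% a)
  structure(list(mu = mu,
                 a = stats::setNames(a, colnames(K_A)),
                 d = NULL,
                 sigma2_a = vc$sigma2_u, sigma2_d = 0,
                 sigma2_e = vc$sigma2_e,
                 lambda = vc$delta,
                 fitted = stats::setNames(fitted, names(y)),
                 model = "partial"),
            class = "gp_fit")
}

#' Fit the additive-plus-dominance (full) RR-BLUP model
#'
#' Fits `y = 1 mu + K_A a + K_D d + e` with independent Gaussian priors
#' `a ~ N(0, sigma2_a I)` and `d ~ N(0, sigma2_d I)`. The two variance
#' ratios `lambda_a = sigma2_a / sigma2_e` and `lambda_d = sigma2_d /
#' sigma2_e` are found by a derivative-free Nelder-Mead search on the
#' restricted log-likelihood over their logarithms (start: both kernels
#' explaining half the phenotypic variance; relative convergence tolerance
#' 1e-6), with the residual variance and intercept profiled out. Effects are
#' recovered by BLUP back-solving against the combined covariance.
#'
#' @param y Named numeric vector of per-hybrid phenotypes.
#' @param K_A Additive design matrix (hybrids x markers).
#' @param K_D Dominance design matrix, same shape, rows aligned with `K_A`.
#' @return A `gp_fit` with `model = "full"` and both effect vectors `a` and
#'   `d`. If `K_D` is identically zero the partial model is returned with a
#'   warning.
#' @export
fit_full <- function(y, K_A, K_D) {
  y <- check_y(y, K_A, "K_A")
  if (!all(dim(K_D) == dim(K_A))) {
    stop("K_D must have the same shape as K_A", call. = FALSE)
  }
  if (all(K_D == 0)) {
    warning("K_D is identically zero; falling back to the partial model",
            call. = FALSE)
    fit <- fit_partial(y, K_A)
    fit$d <- stats::setNames(numeric(ncol(K_D)), colnames(K_D))
    fit$model <- "full"
    return(fit)
  }
  n <- length(y)
  if (n < 3L) stop("need at least 3 observations", call. = FALSE)
  if (stats::var(y) == 0) stop("phenotype is constant", call. = FALSE)
  G_a <- tcrossprod(K_A)
  G_d <- tcrossprod(K_D)
  one <- rep(1, n)
  I_n <- diag(n)
  # profiled REML log-likelihood at variance ratios (lambda_a, lambda_d)
  nll <- function(log_lam) {
    lam <- exp(log_lam)
    V0 <- lam[1] * G_a + lam[2] * G_d + I_n
    R <- tryCatch(chol(V0), error = function(e) NULL)
    if (is.null(R)) return(1e10)
    ldet <- 2 * sum(log(diag(R)))
    Vi_y <- backsolve(R, forwardsolve(t(R), y))
    Vi_1 <- backsolve(R, forwardsolve(t(R), one))
    xvx <- drop(crossprod(one, Vi_1))
    mu <- drop(crossprod(one, Vi_y)) / xvx
    r <- y - mu * one
    Vi_r <- Vi_y - mu * Vi_1
    s2 <- drop(crossprod(r, Vi_r)) / (n - 1)
    if (s2 <= 0) return(1e10)
    0.5 * ((n - 1) * log(s2) + ldet + log(xvx))
  }
  # start: each kernel at the scale that alone would explain half of var(y)
  start <- log(c(0.5 * stats::var(y) / mean(diag(G_a)),
                 0.5 * stats::var(y) / mean(diag(G_d))))
  opt <- stats::optim(start, nll, method = "Nelder-Mead",
                      control = list(reltol = 1e-6, maxit = 500))
  lam <- exp(opt$par)
  V0 <- lam[1] * G_a + lam[2] * G_d + I_n
  Vinv <- solve(V0)
  mu <- drop(crossprod(one, Vinv %*% y) / crossprod(one, Vinv %*% one))
  resid <- y - mu
  Vi_r <- Vinv %*% resid
  sigma2_e <- max(drop(crossprod(resid, Vi_r)) / (n - 1),
                  1e-9 * stats::var(y))
  a <- lam[1] * drop(crossprod(K_A, Vi_r))
  d <- lam[2] * drop(crossprod(K_D, Vi_r))
  fitted <- drop(mu + K_A %*% a + K_D %*% d)
  floor_v <- 1e-9 * stats::var(y)
  structure(list(mu = mu,
                 a = stats::setNames(a, colnames(K_A)),
                 d = stats::setNames(d, colnames(K_D)),
                 sigma2_a = max(lam[1] * sigma2_e, floor_v),
                 sigma2_d = max(lam[2] * sigma2_e, 0),
                 sigma2_e = sigma2_e,
                 lambda = 1 / lam[1],
                 fitted = stats::setNames(fitted, names(y)),
                 model = "full"),
            class = "gp_fit")
}

#' Predict genomic estimated breeding values for new hybrids
#'
#' Applies the stored marker effects to new hybrid design rows:
#' `value = K_A_new a` (plus `K_D_new d` for full fits), and
#' `predicted = mu + value`.
#'
#' @param object A `gp_fit` from [fit_partial()] or [fit_full()].
#' @param K_A_new Additive design rows of the hybrids to predict; columns
#'   must match the markers of the fit.
#' @param K_D_new Dominance design rows; required for full fits.
#' @param ... Unused.
#' @return A data frame with columns `hybrid`, `value` (genetic value) and
#'   `predicted` (`mu` + value).
#' @export
predict.gp_fit <- function(object, K_A_new, K_D_new = NULL, ...) {
  K_A_new <- as.matrix(K_A_new)
  if (ncol(K_A_new) != length(object$a)) {
    stop("K_A_new has ", ncol(K_A_new), " markers but the fit has ",
         length(object$a), call. = FALSE)
  }
  value <- drop(K_A_new %*% object$a)
  if (object$model == "full") {
    if (is.null(K_D_new)) {
      stop("full-model prediction needs K_D_new", call. = FALSE)
    }
    K_D_new <- as.matrix(K_D_new)
    if (!all(dim(K_D_new) == dim(K_A_new))) {
      stop("K_D_new must match K_A_new in shape", call. = FALSE)
    }
    value <- value + drop(K_D_new %*% object$d)
  }
  ids <- rownames(K_A_new)
  if (is.null(ids)) ids <- paste0("hybrid", seq_len(nrow(K_A_new)))
  data.frame(hybrid = ids, value = unname(value),
             predicted = unname(object$mu + value),
             stringsAsFactors = FALSE)
}

#' @export
print.gp_fit <- function(x, ...) {
  cat(sprintf(paste0("gp_fit (%s model): %d markers, mu = %.4g, ",
                     "sigma2_a = %.4g, sigma2_d = %.4g, sigma2_e = %.4g\n"),
              x$model, length(x$a), x$mu, x$sigma2_a, x$sigma2_d, x$sigma2_e))
  invisible(x)
}

# single-kernel REML via spectral decomposition (EMMA-style):
# y = 1 mu + u + e, u ~ N(0, sigma2_u G), minimized over delta = s2e/s2u
reml_single_kernel <- function(y, G) {
  n <- length(y)
  if (stats::var(y) == 0) {
    stop("phenotype is constant: genetic variance is not identifiable",
         call. = FALSE)
  }
  S <- diag(n) - matrix(1 / n, n, n)
  # offset separates the intercept null direction from genetic null
  # directions when G is rank-deficient (hybrids sharing parents)
  offset <- mean(diag(G)) + 1
  eig <- eigen(S %*% (G + offset * diag(n)) %*% S, symmetric = TRUE)
  theta <- pmax(eig$values[seq_len(n - 1L)] - offset, 0)
  U <- eig$vectors[, seq_len(n - 1L), drop = FALSE]
  eta2 <- drop(crossprod(U, y))^2
  obj <- function(log_delta) {
    delta <- exp(log_delta)
    (n - 1) * log(sum(eta2 / (theta + delta))) + sum(log(theta + delta))
  }
  opt <- stats::optimize(obj, interval = c(-25, 25), tol = 1e-8)
  delta <- exp(opt$minimum)
  sigma2_u <- sum(eta2 / (theta + delta)) / (n - 1)
  floor_v <- 1e-9 * stats::var(y)
  sigma2_u <- max(sigma2_u, floor_v)
  list(delta = delta, sigma2_u = sigma2_u, sigma2_e = delta * sigma2_u)
}

check_y <- function(y, K, Kname) {
  if (!is.numeric(y)) stop("y must be numeric", call. = FALSE)
  if (nrow(K) != length(y)) {
    stop("y has ", length(y), " entries but ", Kname, " has ", nrow(K),
         " rows", call. = FALSE)
  }
  if (!is.null(names(y)) && !is.null(rownames(K)) &&
      !identical(names(y), rownames(K))) {
    stop("names of y do not match rows of ", Kname, call. = FALSE)
  }
  if (anyNA(y)) stop("y contains missing values", call. = FALSE)
  y
}
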