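#' Cross-validation scheme descriptor
#'
#' @param kind One of `"fivefold"` (random k-fold, each fold serving once as
#'   validation population per iteration), `"tp_size"` (random training
#'   populations of a fixed size, remainder validated), `"common_male"`
#'   (validation = all hybrids of one held-out female tester, training = the
#'   other testers' hybrids, so training and validation share male parents
#'   only), or `"common_female"` (hybrids split by a partition of the male
#'   parents, so the two sides share female testers only).
#' @param folds Folds for `"fivefold"`.
#' @param iterations Random re-partitions / re-draws.
#' @param n_tp Training-population size: hybrids drawn for `"tp_size"`, or
#'   the target training size for `"common_female"` (default for the latter:
#'   the largest tester group's size).
#' @param holdout For `"common_male"`: female tester(s) to hold out in turn
#'   (default: each tester once).
#' @param seed Integer seed for the scheme's random stream.
#' @return A list of class `cv_scheme`.
#' @export
cv_scheme <- function(kind = c("fivefold", "tp_size", "common_male",
                               "common_female"),
                      folds = 5, iterations = 100, n_tp = NULL,
                      holdout = NULL, seed = 1) {
  kind <- match.arg(kind)
  if (folds < 2L) stop("folds must be >= 2", call. = FALSE)
  if (iterations < 1L) stop("iterations must be >= 1", call. = FALSE)
  if (kind == "tp_size" && (is.null(n_tp) || n_tp < 3L)) {
    stop("tp_size scheme needs n_tp >= 3", call. = FALSE)
  }
  structure(list(kind = kind, folds = as.integer(folds),
                 iterations = as.integer(iterations),
                 n_tp = if (!is.null(n_tp)) as.integer(n_tp),
                 holdout = holdout, seed = as.integer(seed)),
            class = "cv_scheme")
}

#' Random k-fold partition of hybrids
#'
#' Simple random partition without replacement into `folds` subsets whose
#' sizes differ by at most one; deterministic under `seed`.
#'
#' @param ids Character vector of hybrid IDs.
#' @param folds Number of folds.
#' @param seed Integer seed.
#' @return List of `folds` character vectors, disjoint and covering `ids`.
#' @export
#' @examples
#' lengths(make_folds(paste0("H", 1:204), 5, seed = 1))  # 41 41 41 41 40
make_folds <- function(ids, folds, seed) {
  n <- length(ids)
  if (folds > n) stop("more folds than hybrids", call. = FALSE)
  with_seed(seed, {
    shuffled <- sample(ids)
    sizes <- tabulate(rep_len(seq_len(folds), n), folds)  # differ by <= 1
    unname(split(shuffled, rep(seq_len(folds), times = sizes)))
  })
}

#' Heritability-standardized prediction accuracy
#'
#' The accuracy r(g-hat, g): Pearson correlation between observed and
#' predicted values, divided by the square root of the trait's broad-sense
#' heritability to express it on the scale of true genetic values.
#'
#' @param observed,predicted Numeric vectors of equal length (>= 3).
#' @param H Broad-sense heritability in (0, 1].
#' @return List with `raw_r` and `accuracy = raw_r / sqrt(H)`.
#' @export
#' @examples
#' standardized_accuracy(c(1, 2, 3, 5), c(1.1, 1.9, 3.2, 4.8), H = 0.64)
standardized_accuracy <- function(observed, predicted, H) {
  if (length(observed) != length(predicted) || length(observed) < 3L) {
    stop("need >= 3 aligned observed/predicted pairs", call. = FALSE)
  }
  if (!is.numeric(H) || H <= 0 || H > 1) {
    stop("H must be in (0, 1]", call. = FALSE)
  }
  if (stats::sd(observed) == 0 || stats::sd(predicted) == 0) {
    stop("zero variance in observed or predicted values", call. = FALSE)
  }
  raw_r <- stats::cor(observed, predicted)
  list(raw_r = raw_r, accuracy = raw_r / sqrt(H))
}

#' Cross-validated genomic prediction accuracy
#'
#' Runs the requested cross-validation scheme for one trait: hybrid means
#' and broad-sense heritability are computed once from the full phenotype
#' table, the hybrid design matrices are built once, and then each replicate
#' fits the chosen RR-BLUP model on the training hybrids and predicts the
#' validation hybrids. Accuracy is the validation-set correlation divided by
#' `sqrt(H)`, computed per fold (or per draw) and then averaged.
#'
#' @param phenotypes Long-format phenotype table.
#' @param genotypes Parental [geno_matrix] (QC'd, no missing calls).
#' @param design Mating design (`hybrid`, `female`, `male`, `group`).
#' @param scheme A [cv_scheme] of kind `"fivefold"` or `"tp_size"`.
#' @param model `"partial"` or `"full"`.
#' @param trait Trait to analyze (default: the only one present).
#' @param H Heritability used for standardization; estimated from the
#'   phenotypes via [estimate_components()] when `NULL`.
#' @return A list of class `cv_result`: `replicates` (data frame with one
#'   row per fold/draw: `trait`, `scheme`, `model`, `n_tp`, `iteration`,
#'   `fold`, `raw_r`, `accuracy`), `mean_accuracy`, `mean_raw_r`, `H`,
#'   `scheme`, `model`, `trait`.
#' @export
run_cv <- function(phenotypes, genotypes, design, scheme, model = "partial",
                   trait = NULL, H = NULL) {
  stopifnot(inherits(scheme, "cv_scheme"))
  model <- match.arg(model, c("partial", "full"))
  if (!scheme$kind %in% c("fivefold", "tp_size")) {
    stop("run_cv handles fivefold/tp_size; use relatedness_cv for ",
         "common_male/common_female", call. = FALSE)
  }
  prep <- cv_prepare(phenotypes, genotypes, design, trait, H)
  ids <- rownames(prep$hd$K_A)
  n <- length(ids)
  if (!is.null(scheme$n_tp) && scheme$n_tp >= n) {
    stop("n_tp must be smaller than the hybrid count", call. = FALSE)
  }
  rows <- list()
  with_seed(stage_seed(scheme$seed, "cv"), {
    for (it in seq_len(scheme$iterations)) {
      if (scheme$kind == "fivefold") {
        part <- unname(split(sample(ids), rep_len(seq_len(scheme$folds), n)))
        for (f in seq_along(part)) {
          vp <- part[[f]]
          tp <- setdiff(ids, vp)
          acc <- cv_fit_once(prep, tp, vp, model)
          rows[[length(rows) + 1L]] <-
            data.frame(iteration = it, fold = f, n_tp = length(tp),
                       raw_r = acc$raw_r, accuracy = acc$accuracy)
        }
      } else {
        tp <- sample(ids, scheme$n_tp)
        vp <- setdiff(ids, tp)
        acc <- cv_fit_once(prep, tp, vp, model)
        rows[[length(rows) + 1L]] <-
          data.frame(iteration = it, fold = 1L, n_tp = length(tp),
                     raw_r = acc$raw_r, accuracy = acc$accuracy)
      }
    }
  })
  cv_collect(rows, prep, scheme, model)
}

#' Parent-relatedness cross-validation
#'
#' Validation schemes that control how training and validation hybrids are
#' related through their parents, for testcross designs where a few female
#' testers are each crossed to an overlapping set of male pollinators:
#'
#' * `common_male`: the validation population is every hybrid of one
#'   held-out female tester and the training population is all other
#'   hybrids, so the two sides share male parents (the pollinators crossed
#'   to several testers) but no female parent. Each tester in `holdout`
#'   (default: all, in turn) yields one split.
#' * `common_female`: the male pollinators are partitioned into a training
#'   and a validation set and every hybrid follows its male parent, so the
#'   two sides share the female testers but no male. Males are accumulated
#'   in seed-shuffled order until the training side holds `n_tp` hybrids
#'   (default target: the largest tester group's size), swapping in a
#'   smaller male where needed to hit the target exactly.
#'
#' @inheritParams run_cv
#' @param kind `"common_male"` or `"common_female"`.
#' @return A `cv_result` (see [run_cv()]); its `replicates` carry one row
#'   per split with the realized `n_tp` and `n_vp`.
#' @export
relatedness_cv <- function(phenotypes, genotypes, design, kind = "common_male",
                           model = "partial", trait = NULL, H = NULL,
                           scheme = NULL) {
  kind <- match.arg(kind, c("common_male", "common_female"))
  if (is.null(scheme)) scheme <- cv_scheme(kind, iterations = 1)
  prep <- cv_prepare(phenotypes, genotypes, design, trait, H)
  splits <- relatedness_split(prep$design, kind, n_tp = scheme$n_tp,
                              holdout = scheme$holdout, seed = scheme$seed)
  rows <- list()
  for (s in seq_along(splits)) {
    sp <- splits[[s]]
    acc <- cv_fit_once(prep, sp$tp, sp$vp, model)
    rows[[length(rows) + 1L]] <-
      data.frame(iteration = s, fold = 1L, n_tp = length(sp$tp),
                 n_vp = length(sp$vp), label = sp$label,
                 raw_r = acc$raw_r, accuracy = acc$accuracy)
  }
  cv_collect(rows, prep, scheme, model)
}

#' Training/validation splits defined by parent relatedness
#'
#' The split constructions behind [relatedness_cv()], exposed so that split
#' sizes can be inspected without fitting models.
#'
#' @param design Mating design data frame (`hybrid`, `female`, `male`, and
#'   `group` if present).
#' @param kind `"common_male"` or `"common_female"`.
#' @param n_tp Target training size for `"common_female"`; default is the
#'   largest tester group's hybrid count.
#' @param holdout Tester(s) to hold out for `"common_male"`; default all.
#' @param seed Seed for the male-partition shuffle.
#' @return A list of splits, each a list with `tp`, `vp` (hybrid IDs) and a
#'   `label` describing the split.
#' @export
#' @examples
#' md <- make_mating_design(sim_config(reference_shaped = TRUE))
#' sp <- relatedness_split(md, "common_male")
#' sapply(sp, function(s) c(tp = length(s$tp), vp = length(s$vp)))
relatedness_split <- function(design, kind = c("common_male", "common_female"),
                              n_tp = NULL, holdout = NULL, seed = 1) {
  kind <- match.arg(kind)
  design <- as.data.frame(design)
  females <- unique(design$female)
  if (length(females) < 2L) {
    stop("relatedness schemes need at least 2 tester groups", call. = FALSE)
  }
  if (kind == "common_male") {
    # feasible only if held-out testers' males also occur elsewhere
    shared <- vapply(females, function(f) {
      any(design$male[design$female == f] %in%
            design$male[design$female != f])
    }, logical(1))
    if (!any(shared)) {
      stop("no male parent occurs under more than one tester; ",
           "a common-male split is impossible", call. = FALSE)
    }
    if (is.null(holdout)) holdout <- females[shared]
    lapply(holdout, function(f) {
      vp <- design$hybrid[design$female == f]
      tp <- design$hybrid[design$female != f]
      if (length(vp) == 0L || length(tp) == 0L) {
        stop("common_male split for tester ", f, " leaves a side empty",
             call. = FALSE)
      }
      list(tp = tp, vp = vp, label = paste0("holdout_", f))
    })
  } else {
    hybrids_per_male <- table(design$male)
    if (is.null(n_tp)) {
      n_tp <- max(table(design$female))
    }
    if (n_tp < 1L || n_tp >= nrow(design)) {
      stop("common_female target n_tp must be in [1, hybrids)", call. = FALSE)
    }
    tp_males <- with_seed(seed, {
      res <- NULL
      for (attempt in seq_len(200L)) {
        males <- sample(names(hybrids_per_male))
        sel <- character(0)
        total <- 0L
        for (m in males) {
          cnt <- hybrids_per_male[[m]]
          if (total + cnt <= n_tp) {
            sel <- c(sel, m)
            total <- total + cnt
          }
          if (total == n_tp) break
        }
        if (total == n_tp) {
          res <- sel
          break
        }
      }
      res
    })
    if (is.null(tp_males)) {
      stop("cannot partition male parents into a training side of exactly ",
           n_tp, " hybrids", call. = FALSE)
    }
    tp <- design$hybrid[design$male %in% tp_males]
    vp <- design$hybrid[!design$male %in% tp_males]
    if (length(vp) == 0L) stop("common_female split leaves no validation ",
                               "hybrids", call. = FALSE)
    list(list(tp = tp, vp = vp, label = paste0("tp_males_",
                                               length(tp_males))))
  }
}

#' Percent accuracy gain across a training-population-size series
#'
#' `100 * (last - first) / first`, rounded half-away-from-zero to the
#' nearest integer percent.
#'
#' @param accuracies Numeric vector of mean accuracies ordered by increasing
#'   training-population size (length >= 2, first entry nonzero).
#' @return Integer percent change from the first to the last entry.
#' @export
#' @examples
#' accuracy_gain(c(0.25, 0.28, 0.28, 0.30))  # 20
accuracy_gain <- function(accuracies) {
  accuracies <- as.numeric(accuracies)
  if (length(accuracies) < 2L) stop("need >= 2 accuracies", call. = FALSE)
  if (accuracies[1] == 0) {
    stop("first accuracy is zero; percent gain undefined", call. = FALSE)
  }
  x <- 100 * (accuracies[length(accuracies)] - accuracies[1]) / accuracies[1]
  sign(x) * floor(abs(x) + 0.5)
}

# ---- internal CV machinery ----

cv_prepare <- function(phenotypes, genotypes, design, trait, H) {
  design <- as.data.frame(design)
  hd <- make_hybrid_design(genotypes, design)
  y <- hybrid_means(phenotypes, trait, hybrids = design$hybrid)
  if (is.null(H)) {
    H <- estimate_components(phenotypes, trait)$H
  }
  if (H <= 0) stop("H must be positive for standardization", call. = FALSE)
  tr <- if (is.null(trait)) unique(as.data.frame(phenotypes)$trait)[1] else trait
  list(hd = hd, design = design, y = y, H = H, trait = tr)
}

cv_fit_once <- function(prep, tp, vp, model) {
  if (length(tp) < 3L) stop("training population smaller than 3", call. = FALSE)
  K_A <- prep$hd$K_A
  K_D <- prep$hd$K_D
  fit <- if (model == "partial") {
    fit_partial(prep$y[tp], K_A[tp, , drop = FALSE])
  } else {
    fit_full(prep$y[tp], K_A[tp, , drop = FALSE], K_D[tp, , drop = FALSE])
  }
  pred <- predict(fit, K_A[vp, , drop = FALSE],
                  if (model == "full") K_D[vp, , drop = FALSE])
  standardized_accuracy(prep$y[vp], pred$predicted, prep$H)
}

cv_collect <- function(rows, prep, scheme, model) {
  reps <- do.call(rbind, rows)
  reps <- data.frame(trait = prep$trait, scheme = scheme$kind, model = model,
                     reps, stringsAsFactors = FALSE)
  structure(list(replicates = reps,
                 mean_accuracy = mean(reps$accuracy),
                 mean_raw_r = mean(reps$raw_r),
                 H = prep$H, scheme = scheme, model = model,
                 trait = prep$trait),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(paste0("cv_result: %s scheme, %s model, trait '%s': mean ",
                     "accuracy %.3f (raw r %.3f, H = %.3f, %d replicate(s))\n"),
              x$scheme$kind, x$model, x$trait, x$mean_accuracy,
              x$mean_raw_r, x$H, nrow(x$replicates)))
  invisible(x)
}
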