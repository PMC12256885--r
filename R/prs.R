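## Elastic-net genetic risk scores on significant-hit dosages, scoring,
## evaluation (AUROC / AUPRC / prevalence by percentile) and paired
## bootstrap model comparison.

#' Fit an elastic-net risk score
#'
#' Elastic-net linear model (glmnet) of the phenotype on hit dosages,
#' with the mixing parameter searched over the fixed grid
#' `[0.1, 0.5, 0.7, 0.9, 0.95, 0.99, 1.0]` and the regularization
#' strength chosen internally by k-fold cross-validation along glmnet's
#' path.  Binary phenotypes are fitted as a linear model on the 0/1
#' outcome by default; `family = "binomial"` switches to logistic.
#' Features are standardized inside glmnet; reported weights are on the
#' original dosage scale.
#'
#' @param dosages n x p dosage matrix at the hit variants (p >= 2),
#'   training split only.
#' @param phenotype Numeric (or 0/1) outcome of length n.
#' @param l1_grid Grid of elastic-net mixing values.
#' @param folds Number of CV folds (default 5).
#' @param seed Integer seed controlling fold assignment.
#' @param family `"gaussian"` (default) or `"binomial"`.
#' @return List of class `prs_model`: `variants`, `weights`, `intercept`,
#'   `l1_ratio`, `lambda`, `cv` (per-grid mean CV loss),
#'   `train_means` (per-variant mean dose, for imputation).
#' @export
fit_prs <- function(dosages, phenotype,
                    l1_grid = c(0.1, 0.5, 0.7, 0.9, 0.95, 0.99, 1.0),
                    folds = 5, seed = 1, family = c("gaussian", "binomial")) {
  family <- match.arg(family)
  dosages <- as.matrix(dosages)
  if (ncol(dosages) < 2) mr_stop("need at least 2 variants to fit a PRS")
  if (family == "binomial" && length(unique(phenotype)) < 2)
    mr_stop("single-class binary phenotype")
  if (length(unique(phenotype)) < 2) mr_stop("constant phenotype")
  n <- nrow(dosages)
  with_seed(seed, {
    foldid <- sample(rep_len(seq_len(folds), n))
    fits <- lapply(l1_grid, function(a)
      glmnet::cv.glmnet(dosages, phenotype, alpha = a, foldid = foldid,
                        family = family, standardize = TRUE))
    cvmin <- vapply(fits, function(f) min(f$cvm), numeric(1))
    best <- which.min(cvmin)
    fit <- fits[[best]]
    co <- as.numeric(stats::coef(fit, s = "lambda.min"))
    structure(list(variants = colnames(dosages),
                   weights = stats::setNames(co[-1], colnames(dosages)),
                   intercept = co[1],
                   l1_ratio = l1_grid[best],
                   lambda = fit$lambda.min,
                   cv = stats::setNames(cvmin, l1_grid),
                   family = family,
                   train_means = colMeans(dosages)),
              class = "prs_model")
  })
}

#' Score individuals with a fitted risk score
#'
#' Linear score `intercept + sum(w * dose)`.  Variants absent from the
#' supplied dosages are mean-imputed from the training means with a
#' warning.
#'
#' @param model A `prs_model`.
#' @param dosages Dosage matrix containing (some of) the model variants.
#' @return Numeric score per sample.
#' @export
score_prs <- function(model, dosages) {
  dosages <- as.matrix(dosages)
  missing <- setdiff(model$variants, colnames(dosages))
  if (length(missing)) {
    warning(sprintf("%d model variant(s) missing; mean-dose imputed",
                    length(missing)))
    fill <- matrix(rep(model$train_means[missing], each = nrow(dosages)),
                   nrow(dosages), length(missing),
                   dimnames = list(rownames(dosages), missing))
    dosages <- cbind(dosages, fill)
  }
  drop(model$intercept +
         dosages[, model$variants, drop = FALSE] %*% model$weights)
}

#' Area under the ROC curve (rank statistic, ties averaged)
#' @param scores Numeric scores.
#' @param labels 0/1 labels.
#' @return AUROC in \[0, 1\]; NA when only one class is present.
#' @export
auroc <- function(scores, labels) {
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve (step integral)
#' @param scores Numeric scores.
#' @param labels 0/1 labels.
#' @return AUPRC in \[0, 1\]; NA when no positives.
#' @export
auprc <- function(scores, labels) {
  n1 <- sum(labels == 1)
  if (n1 == 0 || n1 == length(labels)) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  tp <- cumsum(lab == 1)
  prec <- tp / seq_along(lab)
  rec <- tp / n1
  ## step integral over distinct recall increments
  drec <- diff(c(0, rec))
  sum(prec * drec)
}

#' Evaluate risk scores
#'
#' AUROC, AUPRC and case prevalence per score-percentile bin, with
#' nonparametric bootstrap mean and standard error over `n_boot`
#' resamples (default 100) of the target set.
#'
#' @param scores Numeric scores.
#' @param labels 0/1 labels (continuous outcomes: only the percentile
#'   table of means is returned).
#' @param percentile_bins Number of equal-count score bins (default 10).
#' @param n_boot Bootstrap replicates (default 100; requires n >= 30).
#' @param seed Integer seed for the resampling.
#' @return List of class `eval_report` with `auroc`, `auprc`,
#'   `prevalence` (bin table) and `bootstrap` (mean and se per metric).
#' @export
evaluate_scores <- function(scores, labels, percentile_bins = 10,
                            n_boot = 100, seed = 1) {
  n <- length(scores)
  stopifnot(length(labels) == n)
  binary <- all(labels %in% c(0, 1))
  a_roc <- if (binary) auroc(scores, labels) else NA_real_
  a_prc <- if (binary) auprc(scores, labels) else NA_real_
  grid <- seq(0, 1, length.out = percentile_bins + 1)
  qs <- pctl(scores, grid)
  qs[1] <- -Inf; qs[length(qs)] <- Inf
  ## tied scores can duplicate breaks; collapse to unique intervals
  keep <- !duplicated(qs)
  qs_u <- qs[keep]
  grid_u <- grid[keep]
  n_bins <- length(qs_u) - 1L
  bin <- cut(scores, qs_u, labels = FALSE, include.lowest = TRUE)
  prev <- data.frame(bin = seq_len(n_bins),
                     lo_pct = 100 * grid_u[-length(grid_u)],
                     hi_pct = 100 * grid_u[-1],
                     n = tabulate(bin, n_bins),
                     case_fraction = vapply(seq_len(n_bins),
                                            function(b) mean(labels[bin == b]),
                                            numeric(1)))
  boot <- NULL
  if (n >= 30 && binary) {
    reps <- with_seed(seed, replicate(n_boot, {
      i <- sample.int(n, replace = TRUE)
      c(auroc(scores[i], labels[i]), auprc(scores[i], labels[i]))
    }))
    boot <- data.frame(metric = c("auroc", "auprc"),
                       mean = rowMeans(reps, na.rm = TRUE),
                       se = apply(reps, 1, stats::sd, na.rm = TRUE))
  }
  structure(list(auroc = a_roc, auprc = a_prc, prevalence = prev,
                 bootstrap = boot, n = n),
            class = "eval_report")
}

#' Paired bootstrap comparison of two score sets
#'
#' Resamples indices once per replicate and applies them to both models,
#' computing the metric difference A - B each time.  The difference is
#' significant iff the (2.5%, 97.5%) percentile interval of the
#' replicate differences excludes zero.
#'
#' @param metric_fn Function(scores, labels) -> scalar metric (e.g.
#'   [auroc()]).
#' @param scores_a,scores_b Scores of the two models on identical
#'   samples.
#' @param labels Shared labels.
#' @param reps Bootstrap replicates (default 100).
#' @param seed Integer seed.
#' @return List with `mean_diff`, `ci` (2.5/97.5 percentiles),
#'   `significant`, `sign`, and the replicate differences.
#' @export
paired_bootstrap_compare <- function(metric_fn, scores_a, scores_b, labels,
                                     reps = 100, seed = 1) {
  n <- length(labels)
  if (length(scores_a) != n || length(scores_b) != n)
    mr_stop("score/label lengths differ")
  diffs <- with_seed(seed, vapply(seq_len(reps), function(r) {
    i <- sample.int(n, replace = TRUE)
    metric_fn(scores_a[i], labels[i]) - metric_fn(scores_b[i], labels[i])
  }, numeric(1)))
  ci <- pctl(diffs, c(0.025, 0.975))
  sig <- ci[1] > 0 || ci[2] < 0
  list(mean_diff = mean(diffs), ci = ci, significant = sig,
       sign = sign(mean(diffs)), diffs = diffs)
}
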