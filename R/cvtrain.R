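#' Configure nested cross-validation
#'
#' @param outer_folds,inner_folds Fold counts (default fivefold at both
#'   levels).
#' @param repeats Number of repeats with distinct random states.
#' @param n_hyperparameter_draws Number of log-uniform draws of the ridge
#'   penalty per (repeat, outer fold).
#' @param penalty_range Interval for the L2 penalty `lambda` (log-uniform).
#' @param base_seed Repeat `r` uses seed `base_seed + r - 1`.
#' @param class_weighting `"balanced"` (loss weights `n / (2 n_c)`) or
#'   `"none"`.
#' @return A list of class `cv_config`.
#' @export
cv_config <- function(outer_folds = 5L, inner_folds = 5L, repeats = 5L,
                      n_hyperparameter_draws = 25L,
                      penalty_range = c(1e-4, 1e4), base_seed = 1L,
                      class_weighting = c("balanced", "none")) {
  class_weighting <- match.arg(class_weighting)
  if (outer_folds < 2 || inner_folds < 2) stop_data("folds must be >= 2")
  if (repeats < 1) stop_data("repeats must be >= 1")
  if (any(penalty_range <= 0) || penalty_range[1] > penalty_range[2])
    stop_data("penalty_range endpoints must be positive and ordered")
  structure(list(outer_folds = as.integer(outer_folds),
                 inner_folds = as.integer(inner_folds),
                 repeats = as.integer(repeats),
                 n_hyperparameter_draws = as.integer(n_hyperparameter_draws),
                 penalty_range = penalty_range,
                 base_seed = as.integer(base_seed),
                 class_weighting = class_weighting),
            class = "cv_config")
}

#' Balanced class weights
#'
#' @param y Binary labels.
#' @return Per-subject weights `n / (2 n_c)`, equalizing the total loss
#'   contribution of the two classes.
#' @export
balanced_weights <- function(y) {
  check_two_classes(y)
  n <- length(y)
  w1 <- n / (2 * sum(y == 1)); w0 <- n / (2 * sum(y == 0))
  ifelse(y == 1, w1, w0)
}

# Stratified fold assignment using the current RNG state.
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    if (length(idx) < k)
      stop_data("class ", cls, " has fewer members (", length(idx),
                ") than folds (", k, "); stratification impossible")
    fold[idx[sample.int(length(idx))]] <-
      rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Area under the ROC curve
#'
#' Probability that a randomly chosen case outscores a randomly chosen
#' control, with ties counted one half (rank / Wilcoxon formulation).
#'
#' @param scores Numeric decision scores or probabilities.
#' @param labels Binary labels with both classes present.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  check_two_classes(labels)
  if (length(scores) != length(labels))
    stop_data("scores and labels lengths differ")
  r <- rank(scores)
  n1 <- as.numeric(sum(labels == 1)); n0 <- as.numeric(sum(labels == 0))
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Ridge logistic fit across a lambda grid; returns a glmnet fit.
ridge_path <- function(X, y, weights, lambdas) {
  fit <- glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                        lambda = sort(lambdas, decreasing = TRUE),
                        weights = weights, standardize = FALSE,
                        thresh = 1e-8, maxit = 1e6)
  if (fit$jerr != 0)
    stop_data("ridge logistic solver failed to converge (code ", fit$jerr, ")")
  fit
}

#' Repeated nested cross-validated ridge logistic classification
#'
#' For each repeat (seeded `base_seed + r - 1`) the cohort is split into
#' stratified outer folds. Within each outer-training partition, an inner
#' stratified CV selects the L2 penalty from `n_hyperparameter_draws`
#' log-uniform samples by maximizing inner validation AUC; the residualizer
#' (deconfounding + standardization) is refit on each training partition only
#' and applied to the corresponding validation rows, so no validation
#' statistics leak into preprocessing. The final model is refit on the full
#' outer-training partition at the selected penalty with balanced class
#' weights, and out-of-fold decision scores are recorded.
#'
#' @param X Feature matrix (raw scale; deconfounding happens inside).
#' @param y Binary labels.
#' @param C Confounder matrix.
#' @param config A [cv_config()].
#' @return An object of class `model_bundle`: per-(repeat, fold) records with
#'   weights, intercept, chosen penalty, residualizer, train/validation
#'   indices, out-of-fold link scores and probabilities, plus the
#'   `repeats * outer_folds` validation AUC vector.
#' @export
nested_cv_train <- function(X, y, C, config = cv_config()) {
  stopifnot(inherits(config, "cv_config"))
  X <- as.matrix(X); C <- as.matrix(C)
  check_two_classes(y)
  if (nrow(X) != length(y) || nrow(C) != length(y))
    stop_data("X, y and C must be row-aligned")
  folds_out <- list()
  auc_vals <- c()
  for (r in seq_len(config$repeats)) {
    rec <- withr::with_seed(config$base_seed + r - 1L, {
      fold_id <- stratified_folds(y, config$outer_folds)
      lapply(seq_len(config$outer_folds), function(f) {
        tr <- which(fold_id != f); va <- which(fold_id == f)
        lambdas <- exp(runif(config$n_hyperparameter_draws,
                             log(config$penalty_range[1]),
                             log(config$penalty_range[2])))
        lam_sorted <- sort(lambdas, decreasing = TRUE)
        inner_id <- stratified_folds(y[tr], config$inner_folds)
        inner_auc <- matrix(NA_real_, config$inner_folds, length(lam_sorted))
        for (g in seq_len(config$inner_folds)) {
          itr <- tr[inner_id != g]; iva <- tr[inner_id == g]
          rz_i <- fit_residualizer(X[itr, , drop = FALSE],
                                   C[itr, , drop = FALSE])
          Xi <- apply_residualizer(rz_i, X[itr, , drop = FALSE],
                                   C[itr, , drop = FALSE])
          Xv <- apply_residualizer(rz_i, X[iva, , drop = FALSE],
                                   C[iva, , drop = FALSE])
          w <- if (config$class_weighting == "balanced")
            balanced_weights(y[itr]) else rep(1, length(itr))
          fit <- ridge_path(Xi, y[itr], w, lam_sorted)
          sc <- predict(fit, Xv, s = lam_sorted, type = "link")
          inner_auc[g, ] <- apply(sc, 2, auc, labels = y[iva])
        }
        mean_auc <- colMeans(inner_auc)
        # ties broken toward the larger (more regularized) penalty
        best <- which(mean_auc == max(mean_auc))[1]
        lam_star <- lam_sorted[best]
        rz <- fit_residualizer(X[tr, , drop = FALSE], C[tr, , drop = FALSE],
                               fitted_on = sprintf("repeat%d_fold%d", r, f))
        Xt <- apply_residualizer(rz, X[tr, , drop = FALSE],
                                 C[tr, , drop = FALSE])
        Xv <- apply_residualizer(rz, X[va, , drop = FALSE],
                                 C[va, , drop = FALSE])
        w <- if (config$class_weighting == "balanced")
          balanced_weights(y[tr]) else rep(1, length(tr))
        fit <- ridge_path(Xt, y[tr], w, lam_sorted)
        beta <- drop(coef(fit, s = lam_star))
        scores <- drop(predict(fit, Xv, s = lam_star, type = "link"))
        list(repeat_id = r, fold = f, beta = beta[-1],
             intercept = beta[1], lambda = lam_star,
             residualizer = rz, train_idx = tr, val_idx = va,
             val_scores = scores, val_probs = plogis(scores),
             val_auc = auc(scores, y[va]))
      })
    })
    folds_out <- c(folds_out, rec)
    auc_vals <- c(auc_vals, vapply(rec, `[[`, 0, "val_auc"))
  }
  structure(list(folds = folds_out, auc = auc_vals, config = config,
                 feature_names = colnames(X), n = nrow(X), y = y),
            class = "model_bundle")
}

#' Out-of-fold probabilities per repeat
#'
#' Assembles, for each repeat, the out-of-fold predicted probability of every
#' subject, then averages across repeats.
#'
#' @param bundle A `model_bundle`.
#' @return Numeric vector, one pooled out-of-fold probability per subject.
#' @export
oof_probabilities <- function(bundle) {
  stopifnot(inherits(bundle, "model_bundle"))
  reps <- unique(vapply(bundle$folds, `[[`, 0L, "repeat_id"))
  acc <- matrix(NA_real_, bundle$n, length(reps))
  for (fold in bundle$folds) {
    acc[fold$val_idx, fold$repeat_id] <- fold$val_probs
  }
  rowMeans(acc)
}

#' Percentile bootstrap summary of a metric list
#'
#' @param values Numeric vector of per-fold metric values (length >= 2).
#' @param n_bootstrap Number of seeded bootstrap resamples.
#' @param seed Integer seed.
#' @return A list with `mean`, `ci` (percentile 95% interval of resampled
#'   means), `values` and `n_bootstrap`.
#' @export
bootstrap_summary <- function(values, n_bootstrap = 1000L, seed = 1L) {
  if (length(values) < 2) stop_data("need at least 2 metric values")
  means <- withr::with_seed(seed, {
    m <- matrix(sample(values, length(values) * n_bootstrap, replace = TRUE),
                nrow = length(values))
    colMeans(m)
  })
  ci <- unname(quantile(means, c(0.025, 0.975)))
  list(mean = mean(values), ci = ci, values = values,
       n_bootstrap = as.integer(n_bootstrap))
}

#' Z-score an AUC matrix across subcategories
#'
#' Normalizes each row (diagnosis) across columns (modality subcategories),
#' or each column across rows, to mean 0 and sample SD 1. Entries with
#' z-scores at or below zero are flagged for display suppression.
#'
#' @param m Numeric matrix of AUC values.
#' @param axis `"row"` (default: within each diagnosis across subcategories)
#'   or `"column"`.
#' @return A list with the z-scored matrix `z` and a logical `display` mask
#'   (`z > 0`).
#' @export
zscore_auc_matrix <- function(m, axis = c("row", "column")) {
  axis <- match.arg(axis)
  m <- as.matrix(m)
  if (axis == "column") m <- t(m)
  if (ncol(m) < 2) stop_data("need >= 2 entries per normalization axis")
  mu <- rowMeans(m); s <- apply(m, 1, sd)
  if (any(!is.finite(s) | s == 0))
    stop_data("zero-variance normalization axis at row(s) ",
              paste(which(s == 0), collapse = ", "))
  z <- sweep(sweep(m, 1, mu, `-`), 1, s, `/`)
  if (axis == "column") z <- t(z)
  list(z = z, display = z > 0)
}

#' Apply a trained bundle to a new cohort (cross-prediction)
#'
#' Applies each fold's residualizer and weights to cohort B and reports the
#' fold-averaged AUC plus sensitivity and specificity at a probability
#' threshold of 0.5.
#'
#' @param bundle A `model_bundle` trained on matching feature columns.
#' @param X,y,C Cohort B features, binary labels and confounders.
#' @param threshold Probability threshold for sensitivity/specificity.
#' @return List with `auc` (mean), `auc_folds`, `sensitivity`, `specificity`
#'   and the subjects x folds probability matrix `prob`.
#' @export
cross_predict <- function(bundle, X, y, C, threshold = 0.5) {
  stopifnot(inherits(bundle, "model_bundle"))
  X <- as.matrix(X); C <- as.matrix(C)
  check_two_classes(y)
  if (!is.null(bundle$feature_names) &&
      !identical(colnames(X), bundle$feature_names))
    stop_data("feature columns do not match the training modality")
  nf <- length(bundle$folds)
  prob <- matrix(NA_real_, nrow(X), nf)
  aucs <- sens <- spec <- numeric(nf)
  for (i in seq_len(nf)) {
    fold <- bundle$folds[[i]]
    Xt <- apply_residualizer(fold$residualizer, X, C)
    sc <- drop(Xt %*% fold$beta) + fold$intercept
    p <- plogis(sc)
    prob[, i] <- p
    aucs[i] <- auc(p, y)
    pred <- as.integer(p >= threshold)
    sens[i] <- sum(pred == 1 & y == 1) / sum(y == 1)
    spec[i] <- sum(pred == 0 & y == 0) / sum(y == 0)
  }
  list(auc = mean(aucs), auc_folds = aucs, sensitivity = mean(sens),
       specificity = mean(spec), prob = prob)
}
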