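#' Structure-coefficient encoding map of a trained model
#'
#' For every (repeat, fold) model in the bundle, computes the Pearson
#' correlation between each deconfounded-standardized feature and the model's
#' linear decision score over the training partition, then averages across
#' folds and repeats. This is the standard encoding ("activation-pattern")
#' view of a linear classifier: it reports how strongly each feature tracks
#' the model output, on a common `[-1, 1]` scale, rather than the weights
#' themselves.
#'
#' @param bundle A `model_bundle` from [nested_cv_train()].
#' @param X,C The feature and confounder matrices the bundle was trained on.
#' @return An object of class `encoding_map`: data frame columns `feature`
#'   and `coef`, with provenance attributes. Zero-variance features get
#'   coefficient 0 and are flagged in the `flagged` attribute.
#' @export
structure_coefficients <- function(bundle, X, C) {
  stopifnot(inherits(bundle, "model_bundle"))
  X <- as.matrix(X); C <- as.matrix(C)
  p <- ncol(X)
  acc <- matrix(0, p, length(bundle$folds))
  for (i in seq_along(bundle$folds)) {
    fold <- bundle$folds[[i]]
    Xt <- apply_residualizer(fold$residualizer,
                             X[fold$train_idx, , drop = FALSE],
                             C[fold$train_idx, , drop = FALSE])
    s <- drop(Xt %*% fold$beta)
    if (sd(s) == 0) stop_data("degenerate decision score (all-zero weights)")
    sds <- apply(Xt, 2, sd)
    r <- rep(0, p)
    ok <- sds > 0
    r[ok] <- suppressWarnings(cor(Xt[, ok, drop = FALSE], s))
    acc[, i] <- r
  }
  co <- rowMeans(acc)
  flagged <- apply(acc == 0, 1, all)
  structure(data.frame(feature = bundle$feature_names, coef = co,
                       stringsAsFactors = FALSE),
            class = c("encoding_map", "data.frame"),
            flagged = flagged,
            n_models = length(bundle$folds))
}

#' Average encoding maps into a composite signature
#'
#' Element-wise unweighted mean of the structure coefficients across disease
#' models, with the per-feature SD across models recorded. Coefficients are
#' averaged raw: correlations already share the `[-1, 1]` scale.
#'
#' @param maps List of `encoding_map` objects with identical features.
#' @return An object of class `composite_signature`: columns `feature`,
#'   `coef`, `coef_sd`; attributes `n_models` and `density`.
#' @export
composite_signature <- function(maps) {
  if (!length(maps)) stop_data("empty map list")
  feats <- maps[[1]]$feature
  for (m in maps) {
    if (!identical(m$feature, feats))
      stop_data("encoding maps disagree on feature names/order")
  }
  M <- vapply(maps, `[[`, numeric(length(feats)), "coef")
  M <- matrix(M, nrow = length(feats))
  structure(data.frame(feature = feats, coef = rowMeans(M),
                       coef_sd = apply(M, 1, sd),
                       stringsAsFactors = FALSE),
            class = c("composite_signature", "data.frame"),
            n_models = length(maps), density = 1)
}

as_signature <- function(x) {
  # accept an encoding_map or a (feature, coef) data frame
  if (inherits(x, "composite_signature")) return(x)
  stopifnot(is.data.frame(x), all(c("feature", "coef") %in% names(x)))
  structure(data.frame(feature = x$feature, coef = x$coef,
                       coef_sd = if ("coef_sd" %in% names(x)) x$coef_sd else 0,
                       stringsAsFactors = FALSE),
            class = c("composite_signature", "data.frame"),
            n_models = attr(x, "n_models") %||% 1L, density = 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Keep only the k largest-magnitude features of a signature
#'
#' Retained coefficient values are unchanged; all others are zeroed. Ties at
#' the rank boundary are broken by feature order (earlier feature kept).
#'
#' @param sig A `composite_signature` (or `encoding_map`).
#' @param k Number of features to retain.
#' @return A `composite_signature` with exactly `k` nonzero entries (fewer if
#'   the signature has fewer nonzeros).
#' @export
simplify_signature <- function(sig, k) {
  sig <- as_signature(sig)
  if (k <= 0) stop_data("k must be positive")
  if (k > nrow(sig)) stop_data("k exceeds the number of features")
  ord <- order(-abs(sig$coef), seq_len(nrow(sig)))
  drop_idx <- ord[-seq_len(k)]
  out <- sig
  out$coef[drop_idx] <- 0
  attr(out, "density") <- k / nrow(sig)
  out
}

#' Threshold a signature to a target density
#'
#' Keeps the top `ceiling(density * n_features)` features by absolute
#' coefficient (ties to the earlier feature), zeroing the rest.
#'
#' @param sig A `composite_signature`.
#' @param density Fraction of features retained, in (0, 1].
#' @return Thresholded `composite_signature` with the density recorded.
#' @export
threshold_signature <- function(sig, density) {
  sig <- as_signature(sig)
  if (!is.finite(density) || density <= 0 || density > 1)
    stop_data("density must be in (0, 1]")
  k <- ceiling(density * nrow(sig))
  out <- simplify_signature(sig, k)
  attr(out, "density") <- density
  out
}

#' Score subjects with a signature
#'
#' Dot product of the signature coefficients with each subject's
#' deconfounded, standardized feature profile.
#'
#' @param sig A `composite_signature`.
#' @param X,C Raw features and confounders.
#' @param residualizer A fitted [fit_residualizer()] supplying the
#'   deconfounding and standardization.
#' @return Numeric per-subject score vector.
#' @export
score_subjects <- function(sig, X, C, residualizer) {
  sig <- as_signature(sig)
  Xt <- apply_residualizer(residualizer, as.matrix(X), as.matrix(C))
  if (!is.null(colnames(Xt)) && !identical(colnames(Xt), sig$feature))
    stop_data("signature features do not match the feature matrix")
  drop(Xt %*% sig$coef)
}

#' Similarity between two encoding maps with a permutation test
#'
#' Pearson correlation between the coefficient vectors; the two-sided p-value
#' is the proportion of feature-index permutations whose absolute correlation
#' reaches the observed one. Random permutations use the `(count + 1) /
#' (n + 1)` convention; `exact = TRUE` enumerates all permutations (small
#' vectors only) and reports the exact proportion.
#'
#' @param map_a,map_b `encoding_map`/`composite_signature` objects or bare
#'   numeric vectors over aligned features.
#' @param n_permutations Number of random permutations.
#' @param seed Integer seed.
#' @param exact Enumerate all permutations instead of sampling.
#' @return List with `r`, `p`, and `n_permutations`.
#' @export
encoding_similarity <- function(map_a, map_b, n_permutations = 1000L,
                                seed = 1L, exact = FALSE) {
  a <- if (is.numeric(map_a)) map_a else as_signature(map_a)$coef
  b <- if (is.numeric(map_b)) map_b else as_signature(map_b)$coef
  if (length(a) != length(b)) stop_data("maps have different lengths")
  if (length(a) < 3) stop_data("need at least 3 features")
  if (sd(a) == 0 || sd(b) == 0) stop_data("zero-variance coefficient vector")
  r <- cor(a, b)
  if (exact) {
    if (length(a) > 8) stop_data("exact enumeration limited to 8 features")
    perms <- all_permutations(length(a))
    rp <- apply(perms, 1, function(ix) cor(a, b[ix]))
    p <- mean(abs(rp) >= abs(r) - 1e-12)
    return(list(r = r, p = p, n_permutations = nrow(perms)))
  }
  count <- withr::with_seed(seed, {
    sum(vapply(seq_len(n_permutations), function(i)
      abs(cor(a, b[sample.int(length(b))])) >= abs(r) - 1e-12, NA))
  })
  list(r = r, p = (count + 1) / (n_permutations + 1),
       n_permutations = as.integer(n_permutations))
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

#' Permutation-null evaluation of a signature's discrimination
#'
#' Scores subjects with the signature, computes the observed AUC against the
#' labels, and builds a null AUC distribution by permuting the labels.
#'
#' @param sig A `composite_signature`.
#' @param X,y,C Features, binary labels, confounders.
#' @param residualizer Fitted residualizer for scoring.
#' @param n_permutations Number of label permutations.
#' @param seed Integer seed.
#' @return List with `observed`, `null` (vector), `null_mean`, `null_sd`,
#'   `z` and one-sided empirical `p` (`(count + 1) / (n + 1)`).
#' @export
permutation_null_auc <- function(sig, X, y, C, residualizer,
                                 n_permutations = 1000L, seed = 1L) {
  check_two_classes(y)
  s <- score_subjects(sig, X, C, residualizer)
  observed <- auc(s, y)
  null <- withr::with_seed(seed, {
    vapply(seq_len(n_permutations), function(i)
      auc(s, y[sample.int(length(y))]), 0)
  })
  m <- mean(null); sdev <- sd(null)
  list(observed = observed, null = null, null_mean = m, null_sd = sdev,
       z = (observed - m) / sdev,
       p = (sum(null >= observed) + 1) / (n_permutations + 1))
}

#' Read/write signatures as two-column delimited tables
#'
#' @param sig A `composite_signature`.
#' @param path File path.
#' @return `write_signature` returns `path`; `read_signature` returns a
#'   `composite_signature`.
#' @export
write_signature <- function(sig, path) {
  sig <- as_signature(sig)
  write_table(sig[, c("feature", "coef")], path)
}

#' @rdname write_signature
#' @export
read_signature <- function(path) {
  as_signature(read_table(path, required_cols = c("feature", "coef"),
                          id_col = NULL))
}
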