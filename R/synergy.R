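#' Pool model probabilities into a per-subject risk score
#'
#' The risk score is the mean natural-log predicted probability across the
#' contributing diagnosis models, with probabilities clipped to
#' `[1e-6, 1 - 1e-6]` so no single model dominates the pooled mean.
#'
#' @param prob_matrix Subjects x models probability matrix (or vector for a
#'   single model).
#' @param source Optional source label (for example `"blood"` or
#'   `"psychosocial"`).
#' @return Numeric per-subject score with attributes `source` and `n_models`.
#' @export
pooled_risk_scores <- function(prob_matrix, source = NA_character_) {
  P <- as.matrix(prob_matrix)
  if (ncol(P) == 0) stop_data("empty model set")
  if (anyNA(P)) stop_data("missing probabilities")
  s <- rowMeans(log(clip_prob(P)))
  attr(s, "source") <- source
  attr(s, "n_models") <- ncol(P)
  s
}

#' Assign risk quintiles
#'
#' Rank-based split at the empirical 20/40/60/80 percentiles. Tied scores
#' share a label, ties at a cut go to the lower bin, and labels are invariant
#' to subject-order permutation of tied values.
#'
#' @param scores Numeric risk scores (length >= 5).
#' @return Ordered factor with levels `low`, `reduced`, `neutral`,
#'   `elevated`, `high`.
#' @export
assign_quintiles <- function(scores) {
  if (length(scores) < 5) stop_data("need at least 5 subjects")
  if (length(unique(scores)) < 5)
    warning("fewer than 5 distinct scores; quintile bins are degenerate")
  cuts <- unname(quantile(scores, c(0.2, 0.4, 0.6, 0.8), type = 1))
  lab <- 1L + vapply(scores, function(s) sum(cuts < s), 0L)
  factor(c("low", "reduced", "neutral", "elevated", "high")[lab],
         levels = c("low", "reduced", "neutral", "elevated", "high"),
         ordered = TRUE)
}

#' Unconditional maximum-likelihood odds ratio from a 2x2 table
#'
#' `OR = (a d) / (b c)` with the Haldane-Anscombe +0.5 correction applied to
#' every cell when any cell is zero, and a Wald 95% CI
#' `exp(log OR +/- 1.96 sqrt(sum 1/cell))`.
#'
#' @param a,b,c,d Exposed cases, exposed controls, unexposed cases, unexposed
#'   controls.
#' @return List with `or`, `log_or`, `ci` (length 2), `corrected` flag and
#'   the (possibly corrected) `cells`.
#' @export
odds_ratio <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0) || any(!is.finite(cells)))
    stop_data("counts must be non-negative and finite")
  if (sum(cells) == 0) stop_data("all-zero 2x2 table")
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  log_or <- log(cells["a"]) + log(cells["d"]) -
    log(cells["b"]) - log(cells["c"])
  se <- sqrt(sum(1 / cells))
  list(or = unname(exp(log_or)), log_or = unname(log_or),
       ci = unname(exp(log_or + c(-1.96, 1.96) * se)),
       se = unname(se), corrected = corrected, cells = cells)
}

#' Odds-ratio grid over biological x psychosocial risk quintiles
#'
#' For each of the 25 quintile combinations (and each marginal quintile per
#' source), builds the 2x2 table of (in group vs all others) x (case vs
#' control) and applies [odds_ratio()].
#'
#' @param bio_quintiles,psy_quintiles Quintile labels from
#'   [assign_quintiles()] (aligned with `labels`).
#' @param labels Binary diagnosis labels.
#' @return A list of class `or_grid`: `log_or` and `or` 5x5 matrices (rows =
#'   biological quintile, columns = psychosocial), `se`, `counts` (per-cell
#'   exposed cases/controls), `sparse` (cells with an empty exposure group or
#'   a zero cell), and `marginal_bio` / `marginal_psy` per-quintile results.
#' @export
quintile_or_grid <- function(bio_quintiles, psy_quintiles, labels) {
  check_two_classes(labels)
  bq <- as.factor(bio_quintiles); pq <- as.factor(psy_quintiles)
  if (length(bq) != length(labels) || length(pq) != length(labels))
    stop_data("vectors not aligned")
  lv <- levels(bq)
  n_cases <- sum(labels == 1); n_ctrl <- sum(labels == 0)
  cell_or <- function(in_group) {
    a <- sum(in_group & labels == 1); b <- sum(in_group & labels == 0)
    odds_ratio(a, b, n_cases - a, n_ctrl - b)
  }
  log_or <- or <- se <- matrix(NA_real_, 5, 5, dimnames = list(lv, lv))
  sparse <- matrix(FALSE, 5, 5, dimnames = list(lv, lv))
  counts <- array(0, c(5, 5, 2), dimnames = list(lv, lv, c("cases", "controls")))
  for (i in seq_along(lv)) for (j in seq_along(lv)) {
    ing <- bq == lv[i] & pq == lv[j]
    res <- cell_or(ing)
    log_or[i, j] <- res$log_or; or[i, j] <- res$or; se[i, j] <- res$se
    sparse[i, j] <- res$corrected
    counts[i, j, ] <- c(sum(ing & labels == 1), sum(ing & labels == 0))
  }
  marg <- function(q) lapply(setNames(nm = lv), function(l) cell_or(q == l))
  structure(list(log_or = log_or, or = or, se = se, counts = counts,
                 sparse = sparse, marginal_bio = marg(bq),
                 marginal_psy = marg(pq),
                 n_cases = n_cases, n_controls = n_ctrl),
            class = "or_grid")
}

#' Cohen's d with a percentile bootstrap CI
#'
#' `d = (mean_a - mean_b) / s_pooled` with the pooled SD using `n - 1`
#' weighting; the CI resamples within each group.
#'
#' @param group_a,group_b Numeric vectors (each length >= 2).
#' @param n_bootstrap Bootstrap iterations.
#' @param seed Integer seed.
#' @return List with `d` and `ci`.
#' @export
cohens_d <- function(group_a, group_b, n_bootstrap = 1000L, seed = 1L) {
  na <- length(group_a); nb <- length(group_b)
  if (na < 2 || nb < 2) stop_data("each group needs >= 2 values")
  pooled <- function(a, b) {
    sp <- sqrt(((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
                 (length(a) + length(b) - 2))
    if (sp == 0) stop_data("zero pooled SD")
    (mean(a) - mean(b)) / sp
  }
  d <- pooled(group_a, group_b)
  boot <- withr::with_seed(seed, {
    vapply(seq_len(n_bootstrap), function(i)
      pooled(group_a[sample.int(na, replace = TRUE)],
             group_b[sample.int(nb, replace = TRUE)]), 0)
  })
  list(d = d, ci = unname(quantile(boot, c(0.025, 0.975))), boot = boot)
}

#' Spearman association between a risk score and pain spread
#'
#' @param score Numeric risk scores.
#' @param spread_category Ordinal pain-spread category (1, 2, 3, 4+ coded
#'   numerically), average ranks for ties.
#' @return List with `rho` and `r2 = rho^2`.
#' @export
spearman_assoc <- function(score, spread_category) {
  if (length(score) < 3) stop_data("need >= 3 subjects")
  if (sd(score) == 0 || sd(as.numeric(spread_category)) == 0)
    stop_data("constant input")
  rho <- cor(score, as.numeric(spread_category), method = "spearman")
  list(rho = rho, r2 = rho^2)
}
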