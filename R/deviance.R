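#' Fraction of deviance explained (D2) by probability predictors
#'
#' Refits a logistic regression of the labels on the logit-transformed
#' predictor(s) (probabilities clipped to `[1e-6, 1 - 1e-6]` first) and
#' reports `D2 = 1 - deviance(model) / deviance(intercept-only)`.
#'
#' @param y Binary labels.
#' @param predictors One or two probability vectors (vector, list, or
#'   n x 1/2 matrix).
#' @return D2 fraction in `[0, 1)`.
#' @export
d2 <- function(y, predictors) {
  check_two_classes(y)
  P <- if (is.list(predictors) && !is.data.frame(predictors))
    do.call(cbind, predictors) else as.matrix(predictors)
  if (nrow(P) != length(y)) stop_data("predictors not aligned with labels")
  if (ncol(P) > 2) stop_data("at most two prediction sources supported")
  L <- qlogis(clip_prob(P))
  # drop constant or duplicated (perfectly collinear) predictors
  keep <- apply(L, 2, sd) > 0
  if (ncol(L) == 2 && all(keep) &&
      abs(cor(L[, 1], L[, 2])) > 1 - 1e-12) {
    warning("perfectly collinear predictors; dropping the second")
    keep[2] <- FALSE
  }
  if (!any(keep)) return(0)
  fit <- glm(y ~ L[, keep, drop = FALSE], family = binomial())
  if (!fit$converged || any(abs(coef(fit)[-1]) > 1e3))
    stop_data("separation or non-convergence in the deviance refit")
  unname(1 - fit$deviance / fit$null.deviance)
}

#' Partition deviance explained between two prediction sources
#'
#' Computes single-source and combined D2 and the decomposition
#' `unique_bio = D2_combined - D2_psy`, `unique_psy = D2_combined - D2_bio`,
#' `shared = D2_bio + D2_psy - D2_combined`. The identity
#' `unique_bio + unique_psy + shared = D2_combined` holds exactly by
#' construction; negative shared deviance (suppression) is reported as
#' computed, not truncated.
#'
#' @param y Binary labels.
#' @param p_bio,p_psy Probability vectors from the biological and
#'   psychosocial prediction sources.
#' @return A list of class `deviance_partition` with `d2_bio`, `d2_psy`,
#'   `d2_combined`, `unique_bio`, `unique_psy`, `shared`.
#' @export
partition_deviance <- function(y, p_bio, p_psy) {
  if (length(p_bio) != length(y) || length(p_psy) != length(y))
    stop_data("predictors not aligned with labels")
  d2_bio <- d2(y, p_bio)
  d2_psy <- d2(y, p_psy)
  d2_combined <- d2(y, cbind(bio = p_bio, psy = p_psy))
  structure(list(d2_bio = d2_bio, d2_psy = d2_psy,
                 d2_combined = d2_combined,
                 unique_bio = d2_combined - d2_psy,
                 unique_psy = d2_combined - d2_bio,
                 shared = d2_bio + d2_psy - d2_combined),
            class = "deviance_partition")
}
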