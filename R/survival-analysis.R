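#' Kaplan-Meier survival curve and cumulative incidence
#'
#' Product-limit estimator; at tied times, events are handled before
#' censorings.
#'
#' @param time Positive event/censoring times (years).
#' @param event 1 = event (diagnosis onset), 0 = censored.
#' @return Data frame with `time`, `n_risk`, `n_event`, `n_censor`, `surv`
#'   and `cuminc = 1 - surv`, one row per distinct observed time.
#' @export
km_curve <- function(time, event) {
  if (!length(time)) stop_data("need at least one record")
  if (any(time <= 0) || any(!is.finite(time)))
    stop_data("times must be positive and finite")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             n_censor = fit$n.censor, surv = fit$surv,
             cuminc = 1 - fit$surv)
}

#' Two-sided log-rank test across risk groups
#'
#' @param time,event Survival records.
#' @param group Group labels (>= 2 non-empty groups).
#' @return List with `chisq`, `df` and `p`.
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(group)
  if (any(table(group) == 0) || nlevels(group) < 2)
    stop_data("need >= 2 non-empty groups")
  if (any(time <= 0)) stop_data("times must be positive")
  fit <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- length(fit$n) - 1
  list(chisq = fit$chisq, df = df,
       p = pchisq(fit$chisq, df, lower.tail = FALSE))
}

#' Cox proportional-hazards ratios for risk groups
#'
#' Partial-likelihood maximization with Breslow tie handling and Wald CIs.
#' In `"vs_rest"` mode (the default), each group's HR is estimated against
#' the complement of that group from a separate single-indicator fit; in
#' `"reference"` mode a single factor model is fit against the first level.
#' A numeric matrix of covariates is also accepted.
#'
#' @param time,event Survival records.
#' @param group Group labels, or a numeric covariate matrix.
#' @param mode `"vs_rest"` or `"reference"` (ignored for numeric covariates).
#' @return Data frame with one row per group/covariate: `hr`, `ci_low`,
#'   `ci_high`, `beta`, `se`.
#' @export
cox_hr <- function(time, event, group, mode = c("vs_rest", "reference")) {
  mode <- match.arg(mode)
  if (sum(event) < 1) stop_data("no events")
  if (any(time <= 0)) stop_data("times must be positive")
  S <- survival::Surv(time, event)
  one_fit <- function(x, nm) {
    fit <- survival::coxph(S ~ x, ties = "breslow")
    if (any(!is.finite(coef(fit))) || any(abs(coef(fit)) > 50))
      stop_data("monotone partial likelihood (separation) for ", nm)
    sm <- summary(fit)
    data.frame(term = if (is.matrix(x)) colnames(x) else nm,
               hr = unname(sm$conf.int[, "exp(coef)"]),
               ci_low = unname(sm$conf.int[, "lower .95"]),
               ci_high = unname(sm$conf.int[, "upper .95"]),
               beta = unname(coef(fit)),
               se = unname(sm$coefficients[, "se(coef)"]))
  }
  if (is.numeric(group) && (is.matrix(group) || is.null(levels(group)))) {
    x <- as.matrix(group)
    if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
    return(one_fit(x, colnames(x)))
  }
  group <- as.factor(group)
  if (mode == "reference") {
    x <- stats::model.matrix(~group)[, -1, drop = FALSE]
    colnames(x) <- levels(group)[-1]
    return(one_fit(x, colnames(x)))
  }
  do.call(rbind, lapply(levels(group), function(l)
    one_fit(as.numeric(group == l), l)))
}

#' Prognostic contrast of baseline scores against later onset
#'
#' Compares baseline signature scores between subjects whose diagnosis onset
#' occurs by follow-up time `horizon` and subjects who remain diagnosis-free
#' through `horizon`, via Cohen's d (bootstrap CI) and AUC.
#'
#' @param baseline_scores Numeric baseline signature scores.
#' @param onset_time,onset_event Onset records (administratively censored).
#' @param horizon Follow-up time T.
#' @param n_bootstrap,seed Bootstrap settings for the Cohen's d CI.
#' @return List with `d`, `d_ci`, `auc`, `n_onset`, `n_control`.
#' @export
prognostic_contrast <- function(baseline_scores, onset_time, onset_event,
                                horizon, n_bootstrap = 1000L, seed = 1L) {
  onset <- onset_event == 1 & onset_time <= horizon
  control <- !onset & onset_time >= horizon
  if (!sum(onset)) stop_data("empty onset group at horizon ", horizon)
  if (!sum(control)) stop_data("empty control group at horizon ", horizon)
  cd <- cohens_d(baseline_scores[onset], baseline_scores[control],
                 n_bootstrap = n_bootstrap, seed = seed)
  y <- c(rep(1, sum(onset)), rep(0, sum(control)))
  a <- auc(c(baseline_scores[onset], baseline_scores[control]), y)
  list(d = cd$d, d_ci = cd$ci, auc = a,
       n_onset = sum(onset), n_control = sum(control))
}
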