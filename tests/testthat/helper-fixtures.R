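# Shared fixtures and independent oracles used across the suite.

small_modalities <- function(p_bio = 20, p_psy = 15) {
  list(modality_spec("blood", p_bio, n_latent = 4),
       modality_spec("psychosocial", p_psy, n_latent = 3))
}

small_config <- function(n = 2000, seed = 1, interaction = 0,
                         effect_scale = 1, p_bio = 20, p_psy = 15, ...) {
  mods <- list(modality_spec("blood", p_bio, n_latent = 4,
                             effect_scale = effect_scale),
               modality_spec("psychosocial", p_psy, n_latent = 3,
                             effect_scale = effect_scale))
  cohort_config(n, modalities = mods,
                diagnoses = default_diagnoses(mods, n = 2,
                                              interaction_strength = interaction),
                seed = seed, ...)
}

fast_cv <- function(seed = 1, repeats = 1L, outer = 3L, inner = 3L,
                    draws = 6L) {
  cv_config(outer_folds = outer, inner_folds = inner, repeats = repeats,
            n_hyperparameter_draws = draws, base_seed = seed)
}

# Brute-force AUC: exhaustive pairwise concordance with ties counted 1/2.
auc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (s1 in pos) for (s0 in neg)
    tot <- tot + (s1 > s0) + 0.5 * (s1 == s0)
  tot / (length(pos) * length(neg))
}

# Independent IRLS logistic oracle (unpenalized) returning the deviance.
irls_logistic <- function(X, y, tol = 1e-12, maxit = 200) {
  X <- cbind(1, X)
  beta <- rep(0, ncol(X))
  for (i in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    z <- eta + (y - mu) / w
    beta_new <- solve(crossprod(X, X * w), crossprod(X, w * z))
    if (max(abs(beta_new - beta)) < tol) { beta <- beta_new; break }
    beta <- beta_new
  }
  eta <- drop(X %*% beta)
  mu <- clip_prob_oracle(plogis(eta))
  dev <- -2 * sum(y * log(mu) + (1 - y) * log(1 - mu))
  list(beta = drop(beta), deviance = dev)
}

clip_prob_oracle <- function(p) pmin(pmax(p, 1e-12), 1 - 1e-12)

irls_d2 <- function(y, L) {
  fit <- irls_logistic(as.matrix(L), y)
  null <- irls_logistic(matrix(0, length(y), 0), y)
  1 - fit$deviance / null$deviance
}

# Hand product-limit table for a KM oracle.
km_hand <- function(time, event) {
  ut <- sort(unique(time[event == 1]))
  s <- 1
  out <- data.frame(time = ut, surv = NA_real_)
  for (k in seq_along(ut)) {
    at_risk <- sum(time >= ut[k])
    d <- sum(time == ut[k] & event == 1)
    s <- s * (1 - d / at_risk)
    out$surv[k] <- s
  }
  out
}

# Grid-search maximizer of the Breslow partial likelihood for one binary
# covariate.
cox_grid_oracle <- function(time, event, x, lo = -4, hi = 4, step = 1e-4) {
  logpl <- function(b) {
    ll <- 0
    for (t in sort(unique(time[event == 1]))) {
      d_idx <- which(time == t & event == 1)
      r_idx <- which(time >= t)
      ll <- ll + b * sum(x[d_idx]) -
        length(d_idx) * log(sum(exp(b * x[r_idx])))
    }
    ll
  }
  grid <- seq(lo, hi, by = step)
  grid[which.max(vapply(grid, logpl, 0))]
}
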