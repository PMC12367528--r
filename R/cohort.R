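#' Specify a feature modality for the cohort generator
#'
#' A modality is a block of exchangeable continuous features (for example 52
#' blood assays or a set of psychosocial scales) driven by a small number of
#' latent factors. Feature `j` loads on latent block `((j - 1) mod n_latent) + 1`
#' with loading `sqrt(rho)`, receives confounder leakage, and gets independent
#' Gaussian noise with variance `1 - rho`, so the within-block correlation is
#' `rho` before leakage.
#'
#' @param name Modality name. The modality named `"psychosocial"` (or, absent
#'   that, the last modality in the config) supplies the psychosocial latent;
#'   the first remaining modality supplies the biological latent.
#' @param n_features Number of features (columns).
#' @param n_latent Number of latent factors (correlation blocks).
#' @param feature_block_correlation Within-block correlation `rho` in `[0, 1)`.
#' @param effect_sparsity Fraction of features with nonzero planted
#'   coefficients.
#' @param effect_scale Standard deviation, in log-odds units, of the planted
#'   per-modality linear predictor `X %*% beta`.
#' @param effect_latent_loading Fraction `a` in `[0, 1)` of the planted
#'   effect aligned with the modality's first latent factor: the coefficient
#'   vector is `sqrt(1 - a^2)` times a sparse random direction plus `a` times
#'   a uniform loading on the block-1 features. This gives disease effects a
#'   shared general-factor axis, so pooled model risk scores track the latent
#'   that also drives pain spread; set to 0 for fully exchangeable random
#'   effect directions.
#' @return A list of class `modality_spec`.
#' @export
modality_spec <- function(name, n_features, n_latent = 4,
                          feature_block_correlation = 0.3,
                          effect_sparsity = 0.5, effect_scale = 1.0,
                          effect_latent_loading = 0.6) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.finite(n_features) || n_features < 1 || !is.finite(n_latent) ||
      n_latent < 1 || n_features < n_latent)
    stop_data("modality '", name, "': need n_features >= n_latent >= 1")
  if (!is.finite(feature_block_correlation) ||
      feature_block_correlation < 0 || feature_block_correlation >= 1)
    stop_data("feature_block_correlation must be in [0, 1)")
  if (!is.finite(effect_sparsity) || effect_sparsity <= 0 ||
      effect_sparsity > 1)
    stop_data("effect_sparsity must be in (0, 1]")
  if (!is.finite(effect_scale) || effect_scale < 0)
    stop_data("effect_scale must be finite and >= 0")
  if (!is.finite(effect_latent_loading) || effect_latent_loading < 0 ||
      effect_latent_loading >= 1)
    stop_data("effect_latent_loading must be in [0, 1)")
  structure(list(name = name, n_features = as.integer(n_features),
                 n_latent = as.integer(n_latent),
                 feature_block_correlation = feature_block_correlation,
                 effect_sparsity = effect_sparsity,
                 effect_scale = effect_scale,
                 effect_latent_loading = effect_latent_loading),
            class = "modality_spec")
}

#' Specify a confounder
#'
#' @param name Confounder name.
#' @param kind `"continuous"` (standard normal) or `"binary"` (Bernoulli 0.5).
#' @param leakage_strength Loading of the confounder onto the features that
#'   are assigned to it (round-robin assignment across features).
#' @return A list of class `confounder_spec`.
#' @export
confounder_spec <- function(name, kind = c("continuous", "binary"),
                            leakage_strength = 0.3) {
  kind <- match.arg(kind)
  if (!is.finite(leakage_strength))
    stop_data("leakage_strength must be finite")
  structure(list(name = name, kind = kind,
                 leakage_strength = leakage_strength),
            class = "confounder_spec")
}

#' Specify a diagnosis outcome
#'
#' Diagnosis labels are drawn as
#' `Bernoulli(plogis(c + sum_m w_m * (X_m beta_m) + gamma * z_bio * z_psy))`,
#' with the intercept `c` calibrated so the empirical prevalence matches
#' `base_rate`.
#'
#' @param name Diagnosis name.
#' @param base_rate Target prevalence in (0, 1).
#' @param modality_weights Named numeric vector of weights `w_m`; modalities
#'   not named get weight 0.
#' @param interaction_strength Log-odds coefficient `gamma` of the product of
#'   the biological and psychosocial latents.
#' @return A list of class `diagnosis_spec`.
#' @export
diagnosis_spec <- function(name, base_rate = 0.1, modality_weights,
                           interaction_strength = 0) {
  if (!is.finite(base_rate) || base_rate <= 0 || base_rate >= 1)
    stop_data("base_rate must be in (0, 1)")
  if (is.null(names(modality_weights)) || any(!is.finite(modality_weights)))
    stop_data("modality_weights must be a finite named vector")
  if (!is.finite(interaction_strength))
    stop_data("interaction_strength must be finite")
  structure(list(name = name, base_rate = base_rate,
                 modality_weights = modality_weights,
                 interaction_strength = interaction_strength),
            class = "diagnosis_spec")
}

#' Configure the synthetic cohort generator
#'
#' Defaults emulate a biobank-style cross-sectional cohort: a 52-feature
#' blood-assay modality and an 81-feature psychosocial modality with
#' moderate block correlation, age/sex confounding that leaks into the
#' features, diagnoses at roughly 10% prevalence driven by sparse linear
#' effects in both modalities plus a biological-by-psychosocial latent
#' interaction, seven body-site pain indicators whose spread loads mainly on
#' the psychosocial latent, administrative follow-up at 4/9/15 years, and 11
#' opaque medication-family flags.
#'
#' @param n_subjects Cohort size.
#' @param modalities List of [modality_spec()] objects.
#' @param confounders List of [confounder_spec()] objects.
#' @param diagnoses List of [diagnosis_spec()] objects.
#' @param pain List with `n_sites`, `psychosocial_weight`, `biological_weight`
#'   (log-odds units on the cumulative-logit pain-spread model).
#' @param followup List with `visit_offsets_years` (administrative censoring
#'   occurs at the last offset) and `hazard_scale` (baseline events per year).
#' @param medication_families Number of opaque medication-family flags.
#' @param med_rates List with per-family Bernoulli rates `base` (no diagnosis)
#'   and `with_diagnosis`.
#' @param share_modality_beta If `TRUE`, all diagnoses share one planted
#'   coefficient vector per modality (the composite-signature ground truth).
#' @param missing_rate Optional MCAR missingness rate applied to features.
#' @param seed Integer seed; identical config + seed gives identical cohorts.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects,
                          modalities = list(
                            modality_spec("blood", 52),
                            modality_spec("psychosocial", 81)),
                          confounders = list(
                            confounder_spec("age", "continuous", 0.3),
                            confounder_spec("sex", "binary", 0.2)),
                          diagnoses = default_diagnoses(modalities),
                          pain = list(n_sites = 7L, psychosocial_weight = 1.2,
                                      biological_weight = 0.4),
                          followup = list(visit_offsets_years = c(4, 9, 15),
                                          hazard_scale = 0.02),
                          medication_families = 11L,
                          med_rates = list(base = 0.05, with_diagnosis = 0.25),
                          share_modality_beta = FALSE,
                          missing_rate = 0,
                          seed = 1L) {
  if (!is.finite(n_subjects) || n_subjects < 1)
    stop_data("n_subjects must be a positive count")
  stopifnot(length(modalities) >= 1, length(diagnoses) >= 1)
  for (m in modalities) stopifnot(inherits(m, "modality_spec"))
  for (cf in confounders) stopifnot(inherits(cf, "confounder_spec"))
  for (d in diagnoses) {
    stopifnot(inherits(d, "diagnosis_spec"))
    if (d$base_rate * n_subjects < 1)
      stop_data("diagnosis '", d$name, "': base_rate * n_subjects < 1, ",
                "no cases possible")
    unknown <- setdiff(names(d$modality_weights),
                       vapply(modalities, `[[`, "", "name"))
    if (length(unknown))
      stop_data("diagnosis '", d$name, "': unknown modalities ",
                paste(unknown, collapse = ", "))
  }
  if (!is.finite(pain$n_sites) || pain$n_sites < 1)
    stop_data("pain$n_sites must be a positive count")
  if (any(!is.finite(followup$visit_offsets_years)) ||
      any(followup$visit_offsets_years <= 0) ||
      !is.finite(followup$hazard_scale) || followup$hazard_scale <= 0)
    stop_data("followup offsets and hazard_scale must be positive")
  if (missing_rate < 0 || missing_rate >= 1)
    stop_data("missing_rate must be in [0, 1)")
  mod_names <- vapply(modalities, `[[`, "", "name")
  if (anyDuplicated(mod_names)) stop_data("duplicate modality names")
  structure(list(n_subjects = as.integer(n_subjects), modalities = modalities,
                 confounders = confounders, diagnoses = diagnoses,
                 pain = pain, followup = followup,
                 medication_families = as.integer(medication_families),
                 med_rates = med_rates,
                 share_modality_beta = isTRUE(share_modality_beta),
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "cohort_config")
}

#' @rdname cohort_config
#' @export
default_diagnoses <- function(modalities, n = 3L, base_rate = 0.1,
                              interaction_strength = 0.5) {
  mod_names <- vapply(modalities, `[[`, "", "name")
  w <- setNames(rep(1, length(mod_names)), mod_names)
  lapply(seq_len(n), function(i)
    diagnosis_spec(paste0("dx", i), base_rate = base_rate,
                   modality_weights = w,
                   interaction_strength = interaction_strength))
}

# Body sites queried in biobank-style pain questionnaires.
pain_site_names <- function(n_sites) {
  std <- c("headache", "facial", "neck_shoulder", "stomach_abdominal",
           "back", "hip", "knee")
  if (n_sites <= length(std)) std[seq_len(n_sites)]
  else c(std, paste0("site", seq_len(n_sites - length(std))))
}

# Round-robin assignment of features to latent blocks / confounders.
round_robin <- function(p, k) ((seq_len(p) - 1L) %% k) + 1L

# Scale a sparse coefficient vector so that Var(X beta) = effect_scale^2
# under the generative covariance of the modality (blocks + leakage + noise).
scale_planted_beta <- function(beta, mod, confounders) {
  p <- mod$n_features
  rho <- mod$feature_block_correlation
  block <- round_robin(p, mod$n_latent)
  v <- rho * sum(tapply(beta, block, sum)^2) + (1 - rho) * sum(beta^2)
  if (length(confounders)) {
    cidx <- round_robin(p, length(confounders))
    for (ci in seq_along(confounders)) {
      cf <- confounders[[ci]]
      vc <- if (cf$kind == "binary") 0.25 else 1
      v <- v + vc * (cf$leakage_strength * sum(beta[cidx == ci]))^2
    }
  }
  if (v <= 0) stop_data("degenerate planted coefficient vector")
  beta * mod$effect_scale / sqrt(v)
}

# Draw one planted coefficient vector: a sparse random direction blended
# with a uniform loading on the block-1 features (the modality's shared
# general-factor axis), rescaled so sd(X beta) = effect_scale.
draw_planted_beta <- function(m, confounders) {
  p <- m$n_features
  n_nz <- max(1L, ceiling(m$effect_sparsity * p))
  b <- numeric(p)
  b[sample.int(p, n_nz)] <- rnorm(n_nz)
  if (m$effect_scale == 0) return(numeric(p))
  a <- m$effect_latent_loading
  if (a > 0) {
    unit <- m; unit$effect_scale <- 1
    u <- as.numeric(round_robin(p, m$n_latent) == 1L)
    b <- sqrt(1 - a^2) * scale_planted_beta(b, unit, confounders) +
      a * scale_planted_beta(u, unit, confounders)
  }
  scale_planted_beta(b, m, confounders)
}

# Simulate draws of the diagnosis linear predictor directly from the model
# (without forming feature matrices), for intercept calibration.
simulate_eta <- function(config, d, betas, n_draws) {
  n_conf <- length(config$confounders)
  Csim <- if (n_conf) {
    vapply(config$confounders, function(cf) {
      if (cf$kind == "binary") rbinom(n_draws, 1, 0.5) else rnorm(n_draws)
    }, numeric(n_draws))
  } else NULL
  eta <- numeric(n_draws)
  roles <- latent_roles(config)
  z_bio <- z_psy <- NULL
  for (m in config$modalities) {
    w <- d$modality_weights[m$name]
    w <- if (is.na(w)) 0 else unname(w)
    beta <- betas[[m$name]]
    rho <- m$feature_block_correlation
    block <- round_robin(m$n_features, m$n_latent)
    S <- tapply(beta, block, sum)
    Z <- matrix(rnorm(n_draws * m$n_latent), n_draws, m$n_latent)
    lp <- sqrt(rho) * drop(Z %*% S) +
      rnorm(n_draws, sd = sqrt((1 - rho) * sum(beta^2)))
    if (n_conf) {
      cidx <- round_robin(m$n_features, n_conf)
      Tc <- vapply(seq_len(n_conf), function(ci)
        config$confounders[[ci]]$leakage_strength * sum(beta[cidx == ci]),
        0)
      lp <- lp + drop(Csim %*% Tc)
    }
    eta <- eta + w * lp
    if (identical(m$name, roles$bio)) z_bio <- Z[, 1]
    if (identical(m$name, roles$psy)) z_psy <- Z[, 1]
  }
  if (d$interaction_strength != 0 && !is.null(z_bio) && !is.null(z_psy))
    eta <- eta + d$interaction_strength * z_bio * z_psy
  eta
}

# Which modality supplies the psychosocial / biological latent.
latent_roles <- function(config) {
  mod_names <- vapply(config$modalities, `[[`, "", "name")
  psy <- if ("psychosocial" %in% mod_names) "psychosocial"
         else mod_names[length(mod_names)]
  bio <- setdiff(mod_names, psy)[1]
  if (is.na(bio)) bio <- psy
  list(bio = bio, psy = psy)
}

# Bisection for the intercept that hits the target prevalence on a simulated
# linear predictor sample.
calibrate_intercept <- function(eta, base_rate) {
  f <- function(c0) mean(plogis(c0 + eta)) - base_rate
  lo <- -30; hi <- 30
  for (i in 1:80) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' Generate a synthetic cohort with planted ground truth
#'
#' Draws confounders, latent factors, feature matrices with confounder
#' leakage, diagnosis labels from sparse per-modality logistic models plus a
#' biological-by-psychosocial interaction, pain-site indicators from a
#' cumulative-logit spread model, exponential onset times with administrative
#' censoring at the last follow-up offset, and medication-family flags. The
#' `truth` element records every planted quantity.
#'
#' @param config A [cohort_config()].
#' @return A list of class `cohort` with elements `subject_id`, `X` (named
#'   list of feature matrices), `C` (confounder matrix), `y` (subjects x
#'   diagnoses 0/1 matrix), `onset_time`, `onset_event`, `pain` (list with
#'   `chronic`, `acute`, `pain_all_over`, `chronic_count`), `med`, `config`
#'   and `truth`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  withr::with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(config) {
  n <- config$n_subjects
  n_conf <- length(config$confounders)
  conf_names <- vapply(config$confounders, `[[`, "", "name")
  roles <- latent_roles(config)

  C <- matrix(0, n, n_conf, dimnames = list(NULL, conf_names))
  for (ci in seq_len(n_conf)) {
    cf <- config$confounders[[ci]]
    C[, ci] <- if (cf$kind == "binary") rbinom(n, 1, 0.5) else rnorm(n)
  }

  X <- list(); Zs <- list()
  for (m in config$modalities) {
    p <- m$n_features; k <- m$n_latent
    rho <- m$feature_block_correlation
    Z <- matrix(rnorm(n * k), n, k)
    block <- round_robin(p, k)
    Xm <- sqrt(rho) * Z[, block, drop = FALSE] +
      sqrt(1 - rho) * matrix(rnorm(n * p), n, p)
    if (n_conf) {
      cidx <- round_robin(p, n_conf)
      leak <- vapply(config$confounders, `[[`, 0, "leakage_strength")
      Xm <- Xm + sweep(C[, cidx, drop = FALSE], 2, leak[cidx], `*`)
    }
    colnames(Xm) <- sprintf("%s_f%03d", m$name, seq_len(p))
    X[[m$name]] <- Xm
    Zs[[m$name]] <- Z
  }
  z_bio <- Zs[[roles$bio]][, 1]
  z_psy <- Zs[[roles$psy]][, 1]

  # Planted coefficients: one draw per (modality, diagnosis), or one per
  # modality shared across diagnoses when share_modality_beta is set.
  n_dx <- length(config$diagnoses)
  dx_names <- vapply(config$diagnoses, `[[`, "", "name")
  betas <- list()
  shared <- list()
  for (m in config$modalities) {
    p <- m$n_features
    B <- matrix(0, p, n_dx, dimnames = list(colnames(X[[m$name]]), dx_names))
    if (config$share_modality_beta)
      shared[[m$name]] <- draw_planted_beta(m, config$confounders)
    for (j in seq_len(n_dx)) {
      B[, j] <- if (config$share_modality_beta) shared[[m$name]]
                else draw_planted_beta(m, config$confounders)
    }
    betas[[m$name]] <- B
  }

  # Diagnosis labels with calibrated intercepts.
  eta <- matrix(0, n, n_dx, dimnames = list(NULL, dx_names))
  modality_lp <- lapply(setNames(nm = names(X)), function(nm)
    matrix(0, n, n_dx, dimnames = list(NULL, dx_names)))
  intercepts <- setNames(numeric(n_dx), dx_names)
  for (j in seq_len(n_dx)) {
    d <- config$diagnoses[[j]]
    for (m in config$modalities) {
      w <- d$modality_weights[m$name]
      w <- if (is.na(w)) 0 else unname(w)
      lp <- drop(X[[m$name]] %*% betas[[m$name]][, j])
      modality_lp[[m$name]][, j] <- lp
      eta[, j] <- eta[, j] + w * lp
    }
    if (d$interaction_strength != 0)
      eta[, j] <- eta[, j] + d$interaction_strength * z_bio * z_psy
    bj <- lapply(betas, function(B) B[, j])
    eta_sim <- simulate_eta(config, d, bj, 100000L)
    intercepts[j] <- calibrate_intercept(eta_sim, d$base_rate)
  }
  prob <- plogis(sweep(eta, 2, intercepts, `+`))
  y <- matrix(rbinom(n * n_dx, 1, prob), n, n_dx,
              dimnames = list(NULL, dx_names))
  for (j in seq_len(n_dx)) {
    d <- config$diagnoses[[j]]
    if (d$base_rate * n >= 10 && length(unique(y[, j])) < 2L)
      stop_data("diagnosis '", d$name, "': degenerate labels despite ",
                "expected count >= 10")
  }

  # Pain spread: cumulative-logit over 0..n_sites chronic sites plus a top
  # pain-all-over category, driven mostly by the psychosocial latent.
  n_sites <- config$pain$n_sites
  u <- config$pain$psychosocial_weight * z_psy +
    config$pain$biological_weight * z_bio
  cuts <- 1.1 + 0.8 * (0:n_sites)   # n_sites + 1 cutpoints, equally spaced
  t_lat <- u + rlogis(n)
  count_raw <- findInterval(t_lat, cuts)
  pao <- count_raw == n_sites + 1L
  chronic_count <- ifelse(pao, 0L, count_raw)
  site_names <- pain_site_names(n_sites)
  chronic <- matrix(0L, n, n_sites, dimnames = list(NULL, site_names))
  for (i in which(chronic_count > 0)) {
    chronic[i, sample.int(n_sites, chronic_count[i])] <- 1L
  }
  acute <- matrix(0L, n, n_sites, dimnames = list(NULL, site_names))
  p_acute <- plogis(-3 + 0.3 * u)
  for (s in seq_len(n_sites)) {
    free <- chronic[, s] == 0L & !pao
    acute[free, s] <- rbinom(sum(free), 1, p_acute[free])
  }

  # Onset times: exponential hazard proportional to exp(eta), administrative
  # censoring at the last follow-up offset.
  cens <- max(config$followup$visit_offsets_years)
  rate <- config$followup$hazard_scale * exp(eta)
  raw_t <- matrix(rexp(n * n_dx), n, n_dx) / rate
  onset_event <- matrix(as.integer(raw_t <= cens), n, n_dx,
                        dimnames = list(NULL, dx_names))
  onset_time <- pmin(raw_t, cens)
  dimnames(onset_time) <- list(NULL, dx_names)

  any_dx <- rowSums(y) > 0
  p_med <- ifelse(any_dx, config$med_rates$with_diagnosis,
                  config$med_rates$base)
  med <- matrix(rbinom(n * config$medication_families, 1, p_med),
                n, config$medication_families,
                dimnames = list(NULL, paste0("med", seq_len(config$medication_families))))

  if (config$missing_rate > 0) {
    for (nm in names(X)) {
      mask <- matrix(runif(length(X[[nm]])) < config$missing_rate,
                     nrow(X[[nm]]))
      X[[nm]][mask] <- NA_real_
    }
  }

  structure(list(
    subject_id = seq_len(n),
    X = X, C = C, y = y,
    onset_time = onset_time, onset_event = onset_event,
    pain = list(chronic = chronic, acute = acute, pain_all_over = pao,
                chronic_count = chronic_count),
    med = med,
    config = config,
    truth = list(beta = betas, intercepts = intercepts, eta = eta,
                 prob = prob, modality_lp = modality_lp,
                 latents = Zs, z_bio = z_bio, z_psy = z_psy,
                 pain_lp = u, roles = roles)
  ), class = "cohort")
}

#' Per-modality ground-truth risk probabilities
#'
#' Probability-scale version of the planted per-modality linear predictors,
#' `plogis(intercept_d + w_md * X_m beta_md)`, used to exercise risk-score
#' pooling without retraining models.
#'
#' @param cohort A `cohort`.
#' @param modality Modality name.
#' @return Subjects x diagnoses matrix of probabilities.
#' @export
truth_modality_probs <- function(cohort, modality) {
  stopifnot(inherits(cohort, "cohort"))
  lp <- cohort$truth$modality_lp[[modality]]
  if (is.null(lp)) stop_data("unknown modality: ", modality)
  w <- vapply(cohort$config$diagnoses, function(d) {
    wm <- d$modality_weights[modality]
    if (is.na(wm)) 0 else unname(wm)
  }, 0)
  plogis(sweep(sweep(lp, 2, w, `*`), 2, cohort$truth$intercepts, `+`))
}

#' Derive the 14 target pain phenotypes
#'
#' Returns any-chronic and any-acute pain, seven per-site chronic phenotypes,
#' and four pain-spread categories (1, 2, 3, 4+ distinct chronic sites).
#' Subjects flagged pain-all-over count as any-chronic but are excluded from
#' site counts and spread categories; an all-zero subject is pain-free.
#'
#' @param cohort A `cohort`, or a list with elements `chronic` (subjects x
#'   sites 0/1), `acute` (same shape) and `pain_all_over` (logical).
#' @return Integer matrix, subjects x 14 phenotypes.
#' @export
derive_pain_phenotypes <- function(cohort) {
  pain <- if (inherits(cohort, "cohort")) cohort$pain else cohort
  chronic <- pain$chronic; acute <- pain$acute
  pao <- as.logical(pain$pain_all_over)
  stopifnot(is.matrix(chronic), is.matrix(acute),
            nrow(chronic) == length(pao))
  bad <- pao & (rowSums(chronic) > 0 | rowSums(acute) > 0)
  if (any(bad))
    stop_data("contradictory flags: pain-all-over set together with site ",
              "indicators for subjects ",
              paste(head(which(bad), 5), collapse = ", "))
  count <- rowSums(chronic)
  out <- cbind(
    chronic_any = as.integer(pao | count > 0),
    acute_any = as.integer(rowSums(acute) > 0),
    chronic * 1L,
    spread_1 = as.integer(count == 1),
    spread_2 = as.integer(count == 2),
    spread_3 = as.integer(count == 3),
    spread_4plus = as.integer(count >= 4)
  )
  colnames(out)[3:(2 + ncol(chronic))] <-
    paste0("chronic_", colnames(chronic))
  out
}

#' Diagnosis-free control subjects
#'
#' @param cohort A `cohort` (or a list with a `y` label matrix).
#' @return Integer vector of row indices with zero positive labels across all
#'   configured diagnoses.
#' @export
select_controls <- function(cohort) {
  y <- if (inherits(cohort, "cohort")) cohort$y else cohort$y
  stopifnot(is.matrix(y))
  idx <- which(rowSums(y) == 0)
  if (!length(idx))
    stop_data("empty control set: all ", nrow(y), " subjects carry at least ",
              "one of ", ncol(y), " diagnoses")
  idx
}

#' Write a cohort as delimited text tables
#'
#' One features file per modality, one confounders file, one labels file
#' (labels, onset times and events), one pain file, one medications file and
#' one truth file (planted coefficients), all keyed by `subject_id`.
#'
#' @param cohort A `cohort`.
#' @param dir Output directory (created if needed).
#' @param sep Field delimiter.
#' @return Named character vector of the files written.
#' @export
write_cohort <- function(cohort, dir, sep = "\t") {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  id <- data.frame(subject_id = cohort$subject_id)
  files <- c()
  for (nm in names(cohort$X)) {
    f <- file.path(dir, paste0("features_", nm, ".tsv"))
    write_table(cbind(id, cohort$X[[nm]]), f, sep)
    files[paste0("features_", nm)] <- f
  }
  f <- file.path(dir, "confounders.tsv")
  write_table(cbind(id, cohort$C), f, sep); files["confounders"] <- f
  lab <- cbind(id, cohort$y,
               setNames(as.data.frame(cohort$onset_time),
                        paste0("onset_time_", colnames(cohort$onset_time))),
               setNames(as.data.frame(cohort$onset_event),
                        paste0("onset_event_", colnames(cohort$onset_event))))
  f <- file.path(dir, "labels.tsv"); write_table(lab, f, sep)
  files["labels"] <- f
  pain <- cbind(id,
                setNames(as.data.frame(cohort$pain$chronic),
                         paste0("chronic_", colnames(cohort$pain$chronic))),
                setNames(as.data.frame(cohort$pain$acute),
                         paste0("acute_", colnames(cohort$pain$acute))),
                pain_all_over = as.integer(cohort$pain$pain_all_over))
  f <- file.path(dir, "pain.tsv"); write_table(pain, f, sep)
  files["pain"] <- f
  f <- file.path(dir, "medications.tsv")
  write_table(cbind(id, cohort$med), f, sep); files["medications"] <- f
  truth <- do.call(rbind, lapply(names(cohort$truth$beta), function(nm) {
    B <- cohort$truth$beta[[nm]]
    data.frame(modality = nm, feature = rownames(B),
               as.data.frame(B), check.names = FALSE)
  }))
  f <- file.path(dir, "truth.tsv")
  data.table::fwrite(truth, f, sep = sep, quote = FALSE)
  files["truth"] <- f
  files
}
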