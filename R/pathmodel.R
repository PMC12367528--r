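#' Bootstrap path model from risks through diagnosis to pain outcomes
#'
#' Observed-variable path analysis fit equation-wise: the binary mediator
#' (diagnosis onset) is modelled by logistic regression on the standardized
#' biological risk, psychosocial risk and their interaction (product of the
#' centred scores, itself standardized); each continuous pain outcome is
#' modelled by linear regression on the mediator plus the standardized risks,
#' with the outcome standardized so coefficients are on a common scale.
#' Significance comes from a subject-level bootstrap (resample rows, refit
#' every equation) with percentile CIs and two-sided percentile p-values.
#'
#' @param data Data frame with columns `bio`, `psy`, a binary mediator column
#'   (`mediator`), and the outcome columns.
#' @param outcomes Character vector of outcome column names.
#' @param mediator Name of the binary mediator column (default `"dx"`).
#' @param n_bootstrap Bootstrap iterations.
#' @param seed Integer seed.
#' @return An object of class `path_result`: data frame with one row per
#'   arrow (`from`, `to`, `estimate`, `ci_low`, `ci_high`, `p`,
#'   `significant`), plus attributes `n_bootstrap` and `n`.
#' @export
fit_path_model <- function(data, outcomes, mediator = "dx",
                           n_bootstrap = 1000L, seed = 1L) {
  need <- c("bio", "psy", mediator, outcomes)
  missing <- setdiff(need, names(data))
  if (length(missing))
    stop_data("missing variables: ", paste(missing, collapse = ", "))
  if (anyNA(data[need])) stop_data("missing values in path variables")
  check_two_classes(data[[mediator]], "mediator labels")
  for (oc in outcomes)
    if (sd(data[[oc]]) == 0) stop_data("zero-variance outcome: ", oc)

  est <- path_fit_once(data, outcomes, mediator)
  boot <- withr::with_seed(seed, {
    n <- nrow(data)
    vapply(seq_len(n_bootstrap), function(i) {
      repeat {
        idx <- sample.int(n, replace = TRUE)
        fit <- tryCatch(path_fit_once(data[idx, , drop = FALSE],
                                      outcomes, mediator),
                        error = function(e) NULL)
        if (!is.null(fit)) return(fit)
      }
    }, est)
  })
  ci <- apply(boot, 1, quantile, probs = c(0.025, 0.975))
  p <- apply(boot, 1, function(b) {
    lo <- (sum(b <= 0) + 1) / (length(b) + 1)
    hi <- (sum(b >= 0) + 1) / (length(b) + 1)
    min(1, 2 * min(lo, hi))
  })
  arrows <- path_arrow_names(outcomes, mediator)
  out <- data.frame(from = arrows$from, to = arrows$to,
                    estimate = est, ci_low = ci[1, ], ci_high = ci[2, ],
                    p = p, significant = p < 0.05,
                    row.names = names(est))
  structure(out, class = c("path_result", "data.frame"),
            n_bootstrap = as.integer(n_bootstrap), n = nrow(data),
            boot = boot)
}

path_arrow_names <- function(outcomes, mediator) {
  from <- c("bio", "psy", "bio:psy",
            unlist(lapply(outcomes, function(o) c(mediator, "bio", "psy"))))
  to <- c(rep(mediator, 3), rep(outcomes, each = 3))
  list(from = from, to = to)
}

# One full equation-wise fit on standardized variables; used for both the
# point estimate and every bootstrap replicate.
path_fit_once <- function(data, outcomes, mediator) {
  zb <- drop(scale(data$bio)); zp <- drop(scale(data$psy))
  inter <- zb * zp
  inter <- (inter - mean(inter)) / sd(inter)
  dx <- data[[mediator]]
  Xm <- cbind(1, zb, zp, inter)
  fit <- suppressWarnings(glm.fit(Xm, dx, family = binomial()))
  if (!fit$converged || any(abs(fit$coefficients) > 50))
    stop_data("separation in the mediator equation")
  est <- fit$coefficients[-1]
  names(est) <- paste0(c("bio", "psy", "bio:psy"), "->", mediator)
  for (oc in outcomes) {
    yz <- drop(scale(data[[oc]]))
    Xo <- cbind(1, dx, zb, zp)
    b <- stats::lm.fit(Xo, yz)$coefficients[-1]
    names(b) <- paste0(c(mediator, "bio", "psy"), "->", oc)
    est <- c(est, b)
  }
  est
}

#' Simulate data with a planted path structure
#'
#' Generates standardized independent biological and psychosocial risk
#' scores, a binary mediator from a logistic model on the risks and their
#' interaction, and continuous outcomes from linear models on the mediator
#' and risks. Used to check sign and coverage recovery of
#' [fit_path_model()].
#'
#' @param n Sample size.
#' @param coefs Named list with `bio_dx`, `psy_dx`, `inter_dx`,
#'   `dx_intercept`, and per-outcome vectors `c(dx, bio, psy)` under
#'   `outcomes`.
#' @param noise_sd Residual SD of the outcomes.
#' @param seed Integer seed.
#' @return Data frame with `bio`, `psy`, `dx` and the outcome columns.
#' @export
simulate_path_data <- function(n, coefs, noise_sd = 1, seed = 1L) {
  withr::with_seed(seed, {
    bio <- rnorm(n); psy <- rnorm(n)
    eta <- coefs$dx_intercept + coefs$bio_dx * bio + coefs$psy_dx * psy +
      coefs$inter_dx * bio * psy
    dx <- rbinom(n, 1, plogis(eta))
    out <- data.frame(bio = bio, psy = psy, dx = dx)
    for (oc in names(coefs$outcomes)) {
      b <- coefs$outcomes[[oc]]
      out[[oc]] <- b[1] * dx + b[2] * bio + b[3] * psy +
        rnorm(n, sd = noise_sd)
    }
    out
  })
}
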