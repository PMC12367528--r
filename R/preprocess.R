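#' Fit a fold-wise residualizer (deconfounder + standardizer)
#'
#' Fits one ordinary-least-squares regression per feature on the confounders
#' (plus intercept) using training rows only, then records the mean and
#' standard deviation of the training residuals. Downstream features are the
#' standardized residuals, so confounder effects that leak into the features
#' are removed without ever touching validation rows.
#'
#' @param X_train Training feature matrix (subjects x features).
#' @param C_train Training confounder matrix, columns named.
#' @param fitted_on Optional fold identifier recorded for audit.
#' @return An object of class `residualizer` with elements `coef`
#'   (`(n_confounders + 1) x n_features`), `center`, `scale`, `keep`
#'   (zero-variance features are flagged and mapped to zero), and the
#'   feature/confounder names.
#' @export
fit_residualizer <- function(X_train, C_train, fitted_on = NA_character_) {
  X_train <- as.matrix(X_train); C_train <- as.matrix(C_train)
  if (nrow(X_train) != nrow(C_train))
    stop_data("X_train and C_train row counts differ")
  if (nrow(X_train) <= ncol(C_train) + 1)
    stop_data("need n_train > n_confounders + 1")
  C1 <- cbind(`(intercept)` = 1, C_train)
  qrC <- qr(C1)
  if (qrC$rank < ncol(C1)) {
    bad <- colnames(C1)[qrC$pivot[(qrC$rank + 1):ncol(C1)]]
    stop_data("rank-deficient confounder matrix; collinear columns: ",
              paste(bad, collapse = ", "))
  }
  coefs <- qr.coef(qrC, X_train)
  R <- X_train - C1 %*% coefs
  center <- colMeans(R)
  scale <- apply(R, 2, sd)
  keep <- is.finite(scale) & scale > 1e-10
  scale[!keep] <- 1
  structure(list(coef = coefs, center = center, scale = scale, keep = keep,
                 features = colnames(X_train),
                 confounders = colnames(C_train),
                 fitted_on = fitted_on),
            class = "residualizer")
}

#' Apply a fitted residualizer
#'
#' Removes the training-estimated confounder effects from `X` and scales by
#' the training residual statistics. Zero-variance (flagged) features map to
#' zero columns so signature dimensionality is preserved across folds.
#'
#' @param rz A fitted [fit_residualizer()] object.
#' @param X Feature matrix with the same columns as the training matrix.
#' @param C Confounder matrix with the training confounder columns.
#' @return Deconfounded, standardized feature matrix.
#' @export
apply_residualizer <- function(rz, X, C) {
  stopifnot(inherits(rz, "residualizer"))
  X <- as.matrix(X); C <- as.matrix(C)
  if (!is.null(rz$features) && !is.null(colnames(X)) &&
      !identical(colnames(X), rz$features))
    stop_data("feature columns do not match the fitted residualizer")
  if (!is.null(rz$confounders)) {
    if (is.null(colnames(C)) || !all(rz$confounders %in% colnames(C)))
      stop_data("confounder columns missing: ",
                paste(setdiff(rz$confounders, colnames(C)), collapse = ", "))
    extra <- setdiff(colnames(C), rz$confounders)
    if (length(extra))
      stop_data("unseen confounder columns: ", paste(extra, collapse = ", "))
    C <- C[, rz$confounders, drop = FALSE]
  }
  C1 <- cbind(`(intercept)` = 1, C)
  out <- sweep(sweep(X - C1 %*% rz$coef, 2, rz$center, `-`),
               2, rz$scale, `/`)
  out[, !rz$keep] <- 0
  out
}

#' Serialize a residualizer to a coefficient table
#'
#' @param rz A fitted residualizer.
#' @param path Optional path to write a delimited audit table.
#' @return A data frame with one row per term (confounder coefficients plus
#'   the standardization statistics) and one column per feature.
#' @export
residualizer_table <- function(rz, path = NULL) {
  stopifnot(inherits(rz, "residualizer"))
  tab <- rbind(rz$coef, center = rz$center, scale = rz$scale,
               keep = as.numeric(rz$keep))
  out <- data.frame(term = rownames(tab), tab, check.names = FALSE)
  if (!is.null(path)) write_table(out, path)
  out
}
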