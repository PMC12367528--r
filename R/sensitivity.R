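#' Medication-exclusion sensitivity of a signature's discrimination
#'
#' For each medication family, recomputes the AUC and Cohen's d of the
#' signature scores on the subset of subjects not taking that family, and
#' reports the deltas against the full-cohort values. Families whose
#' exclusion empties a class are flagged and their metrics omitted.
#'
#' @param scores Per-subject signature scores.
#' @param labels Binary case/control labels.
#' @param med_flags Subjects x families 0/1 matrix of medication use.
#' @return Data frame with one row per family: `family`, `n_excluded`,
#'   `auc`, `d`, `delta_auc`, `delta_d`, `degenerate` flag; full-cohort
#'   values are carried in attributes `full_auc` and `full_d`.
#' @export
medication_sensitivity <- function(scores, labels, med_flags) {
  check_two_classes(labels)
  M <- as.matrix(med_flags)
  if (!ncol(M)) stop_data("need at least one medication family")
  if (nrow(M) != length(labels)) stop_data("medication flags not aligned")
  full_auc <- auc(scores, labels)
  full_d <- cohens_d(scores[labels == 1], scores[labels == 0],
                     n_bootstrap = 2L, seed = 1L)$d
  fam <- colnames(M)
  if (is.null(fam)) fam <- paste0("med", seq_len(ncol(M)))
  rows <- lapply(seq_len(ncol(M)), function(f) {
    keep <- M[, f] == 0
    yk <- labels[keep]
    if (length(unique(yk)) < 2 || sum(yk == 1) < 2 || sum(yk == 0) < 2) {
      return(data.frame(family = fam[f], n_excluded = sum(!keep),
                        auc = NA_real_, d = NA_real_,
                        delta_auc = NA_real_, delta_d = NA_real_,
                        degenerate = TRUE))
    }
    a <- auc(scores[keep], yk)
    dd <- cohens_d(scores[keep][yk == 1], scores[keep][yk == 0],
                   n_bootstrap = 2L, seed = 1L)$d
    data.frame(family = fam[f], n_excluded = sum(!keep), auc = a, d = dd,
               delta_auc = a - full_auc, delta_d = dd - full_d,
               degenerate = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "full_auc") <- full_auc
  attr(out, "full_d") <- full_d
  out
}
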