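#' Configure the end-to-end demo pipeline
#'
#' @param cohort A [cohort_config()] describing the cohort to simulate.
#' @param cv A [cv_config()] for the per-(modality, diagnosis) classifiers.
#' @param densities Signature density ladder evaluated for the composite
#'   signature.
#' @param horizon Follow-up horizon (years) for the prognostic contrast.
#' @param n_permutations Label permutations for the signature null test.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(5000),
                            cv = cv_config(repeats = 1L),
                            densities = c(1, 0.5, 0.25, 0.1),
                            horizon = NULL,
                            n_permutations = 200L) {
  stopifnot(inherits(cohort, "cohort_config"), inherits(cv, "cv_config"))
  structure(list(cohort = cohort, cv = cv, densities = densities,
                 horizon = horizon %||%
                   max(cohort$followup$visit_offsets_years),
                 n_permutations = as.integer(n_permutations)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline on a simulated cohort
#'
#' Executes simulate -> train (per modality, per diagnosis) -> encoding maps
#' -> composite signatures -> deviance partition -> synergy grids ->
#' survival contrasts -> path model, writing every stage output as a
#' delimited table plus a manifest with md5 checksums. Identical config and
#' seed produce byte-identical tables.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest data frame.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_data("pipeline stage '", name, "' failed (seed ",
                config$cohort$seed, "): ", conditionMessage(e)))
  }

  cohort <- stage("simulate", generate_cohort(config$cohort))
  write_cohort(cohort, file.path(out_dir, "cohort"))
  dx_names <- colnames(cohort$y)
  mod_names <- names(cohort$X)
  roles <- cohort$truth$roles

  bundles <- list(); metrics <- list(); maps <- list()
  for (m in mod_names) {
    bundles[[m]] <- list(); maps[[m]] <- list()
    for (d in dx_names) {
      b <- stage(paste0("train:", m, ":", d),
                 nested_cv_train(cohort$X[[m]], cohort$y[, d], cohort$C,
                                 config$cv))
      bundles[[m]][[d]] <- b
      bs <- bootstrap_summary(b$auc, seed = config$cohort$seed)
      metrics[[paste(m, d, sep = ":")]] <-
        data.frame(modality = m, diagnosis = d, mean_auc = bs$mean,
                   ci_low = bs$ci[1], ci_high = bs$ci[2],
                   n_folds = length(b$auc))
      maps[[m]][[d]] <- stage(paste0("encode:", m, ":", d),
                              structure_coefficients(b, cohort$X[[m]],
                                                     cohort$C))
    }
  }
  metrics <- do.call(rbind, metrics)
  write_table(metrics, file.path(out_dir, "model_metrics.tsv"))

  composites <- list(); null_tests <- list()
  y_any <- as.integer(rowSums(cohort$y) > 0)
  for (m in mod_names) {
    sig <- stage(paste0("signature:", m), composite_signature(maps[[m]]))
    composites[[m]] <- sig
    write_signature(sig, file.path(out_dir,
                                   paste0("signature_", m, ".tsv")))
    rz <- fit_residualizer(cohort$X[[m]], cohort$C, fitted_on = "cohort")
    dens_rows <- lapply(config$densities, function(dd) {
      sc <- score_subjects(threshold_signature(sig, dd), cohort$X[[m]],
                           cohort$C, rz)
      data.frame(modality = m, density = dd, auc = auc(sc, y_any))
    })
    write_table(do.call(rbind, dens_rows),
                file.path(out_dir, paste0("signature_density_", m, ".tsv")))
    null_tests[[m]] <- stage(paste0("nulltest:", m),
      permutation_null_auc(sig, cohort$X[[m]], y_any, cohort$C, rz,
                           n_permutations = config$n_permutations,
                           seed = config$cohort$seed))
  }
  nt <- do.call(rbind, lapply(mod_names, function(m)
    data.frame(modality = m, observed = null_tests[[m]]$observed,
               null_mean = null_tests[[m]]$null_mean,
               null_sd = null_tests[[m]]$null_sd, z = null_tests[[m]]$z,
               p = null_tests[[m]]$p,
               null_consistent = abs(null_tests[[m]]$z) < 3)))
  write_table(nt, file.path(out_dir, "signature_null_tests.tsv"))

  # deviance partition per diagnosis from out-of-fold probabilities
  bio_mod <- roles$bio; psy_mod <- roles$psy
  dev_rows <- lapply(dx_names, function(d) {
    pb <- oof_probabilities(bundles[[bio_mod]][[d]])
    pp <- oof_probabilities(bundles[[psy_mod]][[d]])
    pt <- partition_deviance(cohort$y[, d], pb, pp)
    data.frame(diagnosis = d, d2_bio = pt$d2_bio, d2_psy = pt$d2_psy,
               d2_combined = pt$d2_combined, unique_bio = pt$unique_bio,
               unique_psy = pt$unique_psy, shared = pt$shared)
  })
  write_table(do.call(rbind, dev_rows),
              file.path(out_dir, "deviance_partition.tsv"))

  # synergy: pooled risk quintiles from out-of-fold probabilities
  pb <- vapply(dx_names, function(d)
    oof_probabilities(bundles[[bio_mod]][[d]]), numeric(cohort$config$n_subjects))
  pp <- vapply(dx_names, function(d)
    oof_probabilities(bundles[[psy_mod]][[d]]), numeric(cohort$config$n_subjects))
  bio_score <- pooled_risk_scores(pb, bio_mod)
  psy_score <- pooled_risk_scores(pp, psy_mod)
  bq <- assign_quintiles(bio_score); pq <- assign_quintiles(psy_score)
  grid <- stage("synergy", quintile_or_grid(bq, pq, y_any))
  write_table(data.frame(bio_quintile = rownames(grid$log_or),
                         grid$log_or, check.names = FALSE),
              file.path(out_dir, "synergy_log_or_grid.tsv"))
  marg <- do.call(rbind, lapply(c("bio", "psy"), function(src) {
    ml <- grid[[paste0("marginal_", src)]]
    do.call(rbind, lapply(names(ml), function(q)
      data.frame(source = src, quintile = q, or = ml[[q]]$or,
                 log_or = ml[[q]]$log_or, ci_low = ml[[q]]$ci[1],
                 ci_high = ml[[q]]$ci[2])))
  }))
  write_table(marg, file.path(out_dir, "synergy_marginal_or.tsv"))
  dcase <- cohens_d(bio_score[y_any == 1], bio_score[y_any == 0],
                    seed = config$cohort$seed)
  write_table(data.frame(source = bio_mod, d = dcase$d,
                         ci_low = dcase$ci[1], ci_high = dcase$ci[2]),
              file.path(out_dir, "risk_score_cohens_d.tsv"))

  # survival across the four corner risk groups, first-event time
  ft <- apply(cohort$onset_time, 1, min)
  first_dx <- apply(cohort$onset_time, 1, which.min)
  fe <- cohort$onset_event[cbind(seq_len(nrow(cohort$y)), first_dx)]
  grp <- ifelse(bq == "high", "H", ifelse(bq == "low", "L", NA))
  grp2 <- ifelse(pq == "high", "H", ifelse(pq == "low", "L", NA))
  keep <- !is.na(grp) & !is.na(grp2)
  groups <- paste0(grp[keep], "-", grp2[keep])
  surv_out <- stage("survival", {
    lr <- logrank_test(ft[keep], fe[keep], groups)
    hr <- cox_hr(ft[keep], fe[keep], groups, mode = "vs_rest")
    list(lr = lr, hr = hr)
  })
  hr_tab <- surv_out$hr
  hr_tab$logrank_chisq <- surv_out$lr$chisq
  hr_tab$logrank_p <- surv_out$lr$p
  write_table(hr_tab, file.path(out_dir, "survival_risk_groups.tsv"))
  km_tab <- do.call(rbind, lapply(unique(groups), function(g) {
    k <- km_curve(ft[keep][groups == g], fe[keep][groups == g])
    cbind(group = g, k)
  }))
  write_table(km_tab, file.path(out_dir, "km_curves.tsv"))

  # path model: risks -> first-diagnosis onset -> pain spread
  pdat <- data.frame(bio = bio_score, psy = psy_score,
                     dx = as.integer(fe),
                     pain_spread = cohort$pain$chronic_count)
  path <- stage("pathmodel",
                fit_path_model(pdat, outcomes = "pain_spread",
                               n_bootstrap = 200L,
                               seed = config$cohort$seed))
  write_table(as.data.frame(path), file.path(out_dir, "path_model.tsv"))

  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  files <- setdiff(files, file.path(out_dir, "manifest.tsv"))
  manifest <- data.frame(file = sub(paste0("^", out_dir, "/?"), "", files),
                         bytes = file.size(files),
                         md5 = unname(tools::md5sum(files)))
  manifest <- manifest[order(manifest$file), ]
  write_table(manifest, file.path(out_dir, "manifest.tsv"))

  invisible(list(cohort = cohort, metrics = metrics,
                 composites = composites, null_tests = null_tests,
                 grid = grid, survival = surv_out, path = path,
                 manifest = manifest))
}
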