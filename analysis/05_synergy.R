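#!/usr/bin/env Rscript
# Pool model probabilities into biological and psychosocial risk scores,
# stratify into quintiles, and compute the marginal and 25-cell odds-ratio
# grids plus effect sizes and pain-spread associations.

source("analysis/00_config.R")

cohort <- analysis_cohort()
dx <- colnames(cohort$y)
pb <- as.matrix(read_table(file.path(OUT, "oof_probs_blood.tsv"))[, dx])
pp <- as.matrix(read_table(file.path(OUT, "oof_probs_psychosocial.tsv"))[, dx])

bio <- pooled_risk_scores(pb, "blood")
psy <- pooled_risk_scores(pp, "psychosocial")
bq <- assign_quintiles(bio); pq <- assign_quintiles(psy)
y_any <- as.integer(rowSums(cohort$y) > 0)

grid <- quintile_or_grid(bq, pq, y_any)
write_table(data.frame(bio_quintile = rownames(grid$log_or), grid$log_or,
                       check.names = FALSE),
            file.path(OUT, "synergy_log_or_grid.tsv"))
cat(sprintf("log-OR corners: HH %.2f | HL %.2f | LH %.2f | LL %.2f\n",
            grid$log_or["high", "high"], grid$log_or["high", "low"],
            grid$log_or["low", "high"], grid$log_or["low", "low"]))

marg <- do.call(rbind, lapply(c("bio", "psy"), function(src) {
  ml <- grid[[paste0("marginal_", src)]]
  do.call(rbind, lapply(names(ml), function(q)
    data.frame(source = src, quintile = q, or = ml[[q]]$or,
               ci_low = ml[[q]]$ci[1], ci_high = ml[[q]]$ci[2])))
}))
write_table(marg, file.path(OUT, "synergy_marginal_or.tsv"))

d_bio <- cohens_d(bio[y_any == 1], bio[y_any == 0], seed = ANALYSIS_SEED)
cat(sprintf("Pooled blood risk Cohen's d (cases vs controls): %.2f [%.2f, %.2f]\n",
            d_bio$d, d_bio$ci[1], d_bio$ci[2]))

# pain-spread association (0 to 4+ chronic sites): psychosocial risk
# should dominate
sp <- pmin(cohort$pain$chronic_count, 4)
keep <- !cohort$pain$pain_all_over
assoc <- data.frame(
  source = c("blood", "psychosocial"),
  r2 = c(spearman_assoc(bio[keep], sp[keep])$r2,
         spearman_assoc(psy[keep], sp[keep])$r2))
write_table(assoc, file.path(OUT, "spread_associations.tsv"))
cat(sprintf("Pain-spread R2: blood %.3f vs psychosocial %.3f\n",
            assoc$r2[1], assoc$r2[2]))
write_table(data.frame(subject_id = cohort$subject_id, bio_score = bio,
                       psy_score = psy, bio_quintile = as.character(bq),
                       psy_quintile = as.character(pq)),
            file.path(OUT, "risk_scores.tsv"))
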