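#!/usr/bin/env Rscript
# Partition the deviance explained in each diagnosis between the biological
# (blood) and psychosocial prediction sources, using the out-of-fold
# probabilities from the trained models.

source("analysis/00_config.R")

cohort <- analysis_cohort()
pb <- read_table(file.path(OUT, "oof_probs_blood.tsv"))
pp <- read_table(file.path(OUT, "oof_probs_psychosocial.tsv"))

rows <- lapply(colnames(cohort$y), function(d) {
  pt <- partition_deviance(cohort$y[, d], pb[[d]], pp[[d]])
  cat(sprintf("%s: D2 combined %.4f = unique bio %.4f + unique psy %.4f + shared %.4f\n",
              d, pt$d2_combined, pt$unique_bio, pt$unique_psy, pt$shared))
  data.frame(diagnosis = d, d2_bio = pt$d2_bio, d2_psy = pt$d2_psy,
             d2_combined = pt$d2_combined, unique_bio = pt$unique_bio,
             unique_psy = pt$unique_psy, shared = pt$shared)
})
write_table(do.call(rbind, rows), file.path(OUT, "deviance_partition.tsv"))
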