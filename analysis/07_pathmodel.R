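#!/usr/bin/env Rscript
# Bootstrap path model: baseline biological and psychosocial risk (plus
# their interaction) -> diagnosis onset -> pain spread.

source("analysis/00_config.R")

cohort <- analysis_cohort()
rs <- read_table(file.path(OUT, "risk_scores.tsv"))

onset_any <- as.integer(apply(cohort$onset_event, 1, max) == 1)
dat <- data.frame(bio = rs$bio_score, psy = rs$psy_score, dx = onset_any,
                  pain_spread = cohort$pain$chronic_count)
fit <- fit_path_model(dat, outcomes = "pain_spread",
                      n_bootstrap = 1000L, seed = ANALYSIS_SEED)
write_table(as.data.frame(fit), file.path(OUT, "path_model.tsv"))
for (i in seq_len(nrow(fit)))
  cat(sprintf("%-18s %+.3f [%+.3f, %+.3f] p = %.3g%s\n",
              paste0(fit$from[i], " -> ", fit$to[i]), fit$estimate[i],
              fit$ci_low[i], fit$ci_high[i], fit$p[i],
              if (fit$significant[i]) " *" else ""))
cat("Path model written to", file.path(OUT, "path_model.tsv"), "\n")
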