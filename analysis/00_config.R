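# Shared configuration for the numbered analysis drivers.
#
# The drivers run the full biopsychosocial pipeline on a simulated cohort at
# a desk scale (n = 4,000, two modalities, three diagnoses) and exchange
# results exclusively through delimited text tables under results/analysis/.

library(painbps)

ANALYSIS_SEED <- 42L
OUT <- "results/analysis"
dir.create(OUT, showWarnings = FALSE, recursive = TRUE)

analysis_modalities <- function() {
  list(modality_spec("blood", 52, n_latent = 4),
       modality_spec("psychosocial", 30, n_latent = 4))
}

analysis_cohort_config <- function() {
  mods <- analysis_modalities()
  cohort_config(4000, modalities = mods,
                diagnoses = default_diagnoses(mods, n = 3,
                                              interaction_strength = 0.5),
                seed = ANALYSIS_SEED)
}

analysis_cv_config <- function() {
  cv_config(outer_folds = 5L, inner_folds = 3L, repeats = 2L,
            n_hyperparameter_draws = 10L, base_seed = ANALYSIS_SEED)
}

# deterministic regeneration of the cohort used by every driver
analysis_cohort <- function() generate_cohort(analysis_cohort_config())
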