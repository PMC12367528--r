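# painbps

Biopsychosocial biomarker pipelines for chronic pain conditions, on tabular
cohort data.

## The problem

Chronic pain accompanies many medical conditions (rheumatoid arthritis,
gout, fibromyalgia, ...), and candidate biomarkers for it come from very
different places: blood assays, brain and bone imaging features,
psychosocial questionnaires. Evaluating such biomarkers honestly requires a
pipeline that (i) classifies diagnoses from high-dimensional correlated
features without leaking confounders or validation data, (ii) turns opaque
model weights into interpretable per-feature signatures, (iii) quantifies
how much biological and psychosocial sources each explain — uniquely and
jointly — and (iv) tests whether the two sources act synergistically on
disease risk, cross-sectionally and over follow-up time. `painbps`
implements that chain for biostatisticians and methodologists, and ships a
synthetic cohort generator with planted ground truth so every stage is
verifiable without access-restricted biobank data.

## The core machinery

- **Deconfounded nested CV.** Per-feature OLS residualization on confounders
  is fit inside every training partition and applied to the matching
  validation rows; L2 logistic models with balanced class weights
  `w_c = n / (2 n_c)` are tuned by inner-CV AUC over log-uniform penalty
  draws and evaluated by out-of-fold ROC-AUC with bootstrap CIs.
- **Encoding maps.** A trained model is reported through structure
  coefficients `r_j = cor(x_j, x' beta)` — the correlation of each
  deconfounded feature with the decision score — averaged over folds;
  per-disease maps average into a composite signature `s = mean_d r^(d)`,
  which scores subjects by dot product and supports top-k simplification
  and density thresholding with permutation-null AUC validation.
- **Deviance partition.** For biological and psychosocial probability
  sources, `D2 = 1 - dev(model)/dev(null)` from logistic refits on logits,
  decomposed as `unique_B = D2_BP - D2_P`, `unique_P = D2_BP - D2_B`,
  `shared = D2_B + D2_P - D2_BP` (an exact identity).
- **Risk-quintile synergy.** Pooled risk scores `mean_d ln p_d` are split
  into quintiles; odds ratios `(ad)/(bc)` with Haldane-Anscombe correction
  populate marginal and 25-cell biological x psychosocial grids.
- **Survival and path model.** Kaplan-Meier/log-rank/Cox (Breslow ties)
  contrasts of the four corner risk groups, prognostic Cohen's d + AUC at
  follow-up horizons, medication-exclusion sensitivity, and an
  equation-wise bootstrap path model: risks (+ interaction) -> diagnosis
  onset -> pain impact/spread/intensity.

## Worked example

```r
library(painbps)

mods <- list(modality_spec("blood", 52), modality_spec("psychosocial", 30))
cfg  <- cohort_config(4000, modalities = mods,
                      diagnoses = default_diagnoses(mods, n = 3,
                                                    interaction_strength = 0.5),
                      seed = 42)
cohort <- generate_cohort(cfg)

bundle <- nested_cv_train(cohort$X$blood, cohort$y[, "dx1"], cohort$C,
                          cv_config(repeats = 2, inner_folds = 3,
                                    n_hyperparameter_draws = 10,
                                    base_seed = 42))
bootstrap_summary(bundle$auc, seed = 42)$mean
```

The numbered drivers under `analysis/` run the full chain on this cohort
and narrate what they find:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_train_models.R
Rscript analysis/03_signatures.R
Rscript analysis/04_deviance.R
Rscript analysis/05_synergy.R
Rscript analysis/06_survival.R
Rscript analysis/07_pathmodel.R
```

Representative output (seed 42):

```
blood          dx1  AUC 0.679 [0.663, 0.698]
psychosocial   dx1  AUC 0.707 [0.692, 0.724]
...
blood composite: AUC 0.671 at full density, 0.630 at 5%
blood permutation null: observed 0.671, null 0.500 (sd 0.0106), p = 0.0010
dx1: D2 combined 0.1307 = unique bio 0.0529 + unique psy 0.0808 + shared -0.0030
log-OR corners: HH 2.21 | HL -0.48 | LH -0.38 | LL -1.21
Pain-spread R2: blood 0.012 vs psychosocial 0.086
  HR H-H vs rest: 8.20 [6.54, 10.29]
  HR H-L vs rest: 0.62 [0.48, 0.80]
Prognostic contrast at 4 years: d = 0.59 [0.53, 0.65], AUC 0.666
bio -> dx          +0.702 [+0.622, +0.781] p = 0.002 *
bio:psy -> dx      +0.226 [+0.149, +0.303] p = 0.002 *
psy -> pain_spread +0.253 [+0.224, +0.282] p = 0.002 *
```

Read: both modalities classify the planted diagnoses at AUC ~0.7; the
composite signature discriminates any-diagnosis subjects far outside its
permutation null and survives density thresholding; deviance splits into
unique biological, unique psychosocial and shared parts that sum exactly
to the combined D2; the high-high risk corner carries a log-OR of 2.2
against negative single-high corners (the planted synergy); onset is
fastest in the high-high group (HR 8.2 vs rest); and pain spread tracks
psychosocial risk far more than biological risk, as planted. Tables land
under `results/analysis/`.

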