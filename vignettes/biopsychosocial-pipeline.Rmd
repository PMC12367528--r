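---
title: "Methods: biopsychosocial biomarker pipelines on tabular cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: biopsychosocial biomarker pipelines on tabular cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`painbps` implements a complete analysis chain for multimodal tabular
biomarker studies of pain-associated medical conditions: a synthetic cohort
generator with planted ground truth, fold-wise regression deconfounding,
repeated nested cross-validated ridge logistic classification, structure-
coefficient encoding maps and composite signatures, deviance-explained
partitioning, risk-quintile odds-ratio synergy grids, survival contrasts of
baseline risk groups, medication-exclusion sensitivity checks, and a
bootstrap path model. Every stage is exercised end to end on generated
cohorts, so the statistical machinery is testable without access-restricted
biobank data.

This vignette documents the models, the parameters that matter, the
numerical choices, and what the synthetic validation does and does not show
about real cohorts.

# The synthetic cohort generator

The generator is first-class, tested code: it defines the statistical
structure that every downstream module assumes, and it exposes the planted
truth so recovery can be verified.

**Features.** Each modality (for example a 52-column blood-assay block and
an 81-column psychososical block) is driven by `n_latent` standard-normal
latent factors. Feature `j` loads `sqrt(rho)` on latent block
`((j - 1) mod n_latent) + 1`, receives `leakage_strength` times one
confounder (round-robin assignment), and adds independent Gaussian noise
with variance `1 - rho`, so the within-block correlation is `rho`
(default 0.3) before leakage. Features are exchangeable continuous columns;
no attempt is made to emulate realistic assay distributions, units or
missingness patterns (missingness defaults to 0%, with an optional MCAR
rate for robustness tests). The real correlation structure among blood
assays is unknown to us; block correlation is a stand-in, not an estimate.

**Diagnoses.** Labels are drawn as
`y ~ Bernoulli(plogis(c + sum_m w_m (X_m beta_m) + gamma z_bio z_psy))`.
The planted coefficient vector `beta_m` blends a sparse random direction
(`effect_sparsity`, default 0.5, Gaussian values) with a uniform loading on
the modality's block-1 features (`effect_latent_loading`, default 0.6), and
is scaled analytically so that `sd(X_m beta_m) = effect_scale` under the
generative covariance; effects are therefore in interpretable log-odds
units. The latent loading gives disease effects a shared general-factor
axis — diseases within a modality are partly driven by one common factor
(systemic inflammation on the biological side, general distress on the
psychosocial side) — which is what makes pooled model risk scores track
the same latent that drives pain spread. With the loading at zero, effect
directions are exchangeable and model risk scores are nearly orthogonal to
the spread-driving latent, an unrealistic decoupling. `z_bio` and `z_psy` are the
first latent factors of the biological and psychosocial modalities, and
`gamma` (`interaction_strength`) plants a biological-by-psychosocial
synergy. The intercept `c` is calibrated by bisection on a 100,000-draw
simulation of the linear predictor, because no closed form exists once the
latent interaction is present; empirical prevalence then matches
`base_rate` to within binomial error.

**Pain sites.** The number of chronic pain sites follows a cumulative-logit
model with equally spaced cutpoints (`1.1 + 0.8 k`), the simplest ordinal
model that produces a monotone spread structure. Its linear predictor loads
`psychosocial_weight` (default 1.2) on `z_psy` and `biological_weight`
(default 0.4) on `z_bio`, reproducing the qualitative asymmetry in which
pain spread tracks psychosocial risk far more strongly than biological
risk. The first cutpoint puts chronic-pain prevalence near 25% at zero
risk. The top ordinal category maps to a mutually exclusive pain-all-over
flag; such subjects count as any-chronic but never contribute to site
counts or spread categories. Acute sites are drawn independently at low
rates for sites without chronic pain.

**Follow-up and medications.** Onset times are exponential with hazard
`hazard_scale * exp(eta)` and administrative censoring at the last
follow-up offset (defaults 4/9/15 years), matching biobank-style visit
structure. Medication-family flags are opaque Bernoulli indicators with
diagnosis-conditional rates (5% baseline, 25% with any diagnosis); only a
marginal association is needed for the exclusion sensitivity analysis, so
no drug ontology is modelled.

Identical config and seed reproduce cohorts bit for bit; all randomness
flows through one seeded stream.

# Deconfounding

Confounder effects are removed by per-feature ordinary least squares on the
confounders (plus intercept), fit on training rows only; features become
the standardized training residuals. Standardization happens *after*
residualization, using training-residual statistics, which keeps encoding
maps comparable across folds; the ordering is a package choice since
"standardization and residualization" admits either order. Zero-variance
features are flagged and mapped to zero rather than dropped, preserving
signature dimensionality across folds. Residualizers are refit inside every
outer and inner training partition, so validation statistics can never leak
into preprocessing — a property tested bit-exactly by perturbing validation
rows.

# Nested cross-validated classification

Classifiers are L2-penalized logistic regressions (via `glmnet`) with
balanced class weights `n / (2 n_c)`, so rare diagnoses do not collapse to
the majority class. The outer and inner loops default to stratified
fivefold splits (stratification is a package choice; several diagnoses are
rare), repeated with distinct seeds. The penalty is selected per outer fold
from `n_hyperparameter_draws` log-uniform samples over `[1e-4, 1e4]`
(25 draws by default; the search distribution is exposed in the config
because no canonical range exists), maximizing inner-fold AUC — the same
metric reported outside. Ties in inner AUC resolve toward the larger
penalty. Solver convergence failures are errors, not warnings. AUC uses the
rank (Wilcoxon) formulation with ties counted one half; fold summaries get
percentile bootstrap 95% CIs (1,000 resamples, seeded).

# Encoding maps and composite signatures

The weights of a regularized linear model are not interpretable feature
associations, so models are reported through *structure coefficients*: the
Pearson correlation between each deconfounded standardized feature and the
model's linear decision score over the training partition, averaged across
folds and repeats. This is the standard encoding ("activation-pattern")
view; the correlation (rather than covariance) scaling is a documented
package choice, and it places every feature on a common [-1, 1] scale, so
composite signatures average raw coefficients across disease models without
rescaling, recording the per-feature SD across models.

Signatures are simplified (top-`k` by |coefficient|) or thresholded to a
density (top `ceiling(density * n_features)`), with ties broken
deterministically by feature order; retained sets are nested along the
density ladder and density 1 is exactly the identity. Subjects are scored
by the dot product of the signature with their deconfounded standardized
profile. Discrimination is validated against a label-permutation null
(default 1,000 permutations, config override; the empirical p uses the
`(count + 1) / (n + 1)` convention), and map similarity uses Pearson
correlation with a feature-permutation p (exact enumeration available for
small maps).

One identifiability caveat matters for validation: structure coefficients
estimate the covariance-weighted pattern `Sigma beta`, not `beta`. With
block-correlated features, correlated neighbours of truly predictive
features legitimately acquire coefficients, so recovery of the *planted*
vector is only a well-posed target when features are uncorrelated. The
signature-recovery checks therefore run the generator at block correlation
0 with the latent loading disabled (cosine similarity with truth >= 0.9,
top-10 retention across seeds) — without latents an alignment axis has no
meaning, and its uniform loadings would make the planted top-10 ill-defined
through ties — while every other check keeps the defaults.

# Deviance partitioning

The deviance explained by a prediction source is
`D2 = 1 - deviance(model) / deviance(intercept-only)` from a logistic
refit of the labels on the logit-transformed out-of-fold probabilities
(clipped to `[1e-6, 1 - 1e-6]`; probabilities near 0/1 destabilize the
refit and the link scale of the original procedure is unstated, so the
logit entry is pinned here). Unique and shared contributions are
`unique_bio = D2_combined - D2_psy`, `unique_psy = D2_combined - D2_bio`,
`shared = D2_bio + D2_psy - D2_combined`; the identity
`unique_bio + unique_psy + shared = D2_combined` holds exactly by
construction. Negative shared deviance (suppression) is reported as
computed, never truncated. Perfectly collinear duplicate predictors are
dropped with a warning; separation is an error.

# Risk scores and synergy grids

Per-subject risk scores are the mean natural-log predicted probability
across the contributing diagnosis models (natural log is a pinned choice;
the base only rescales scores and cannot change ranks or quintiles).
Probabilities are clipped at `1e-6` so one model cannot dominate the pooled
mean. Quintiles (`low`, `reduced`, `neutral`, `elevated`, `high`) split at
the empirical 20/40/60/80 percentiles; ties go to the lower bin, stated
openly as a determinism rule. Odds ratios are unconditional
maximum-likelihood cross-products with the Haldane-Anscombe +0.5 correction
when any cell is zero and Wald 95% CIs (a package choice; no CI method is
canonical for reported ORs). The 25-cell grid compares each biological x
psychosocial quintile combination against all other subjects; marginal
grids do the same per source. Count-weighted pooling of the 25 cells
reconstructs the cohort exactly.

# Survival and sensitivity analyses

Kaplan-Meier curves use the product-limit estimator (events before
censorings at tied times); group differences use the two-sided log-rank
test; hazard ratios come from Cox proportional-hazards fits with Breslow
tie handling (simple and adequate for continuous synthetic times) and Wald
CIs. HRs are reported per risk group against the complement of that group
by default, with a reference-group parameterization available, since both
framings are in use. Prognostic contrasts compare baseline signature scores
between subjects with onset by a horizon and subjects diagnosis-free
through it, via Cohen's d (pooled SD with n-1 weighting, within-group
bootstrap CI) and AUC. Medication-exclusion sensitivity recomputes AUC and
Cohen's d on the subset not taking each family; exclusions that empty a
class are flagged and omitted.

# Path model

The path analysis is observed-variable and equation-wise rather than a
covariance-fitting SEM: the model has no latent variables and its
significance testing is bootstrap-based, so equation-wise regression with a
subject-level bootstrap (resample rows, refit all equations) is the direct
implementation; SEM fit indices are out of scope. The binary mediator
(diagnosis onset) uses a logistic link — the original link choice is
unstated, and a logistic mediator respects the binary outcome. Exogenous
risks are standardized; the interaction is the product of the centred
scores, itself standardized; continuous outcomes are standardized so
coefficients share a scale. Percentile CIs and two-sided percentile
p-values use `(count + 1) / (n + 1)`. Refitting the un-resampled data
reproduces the point estimates exactly.

# Problem sizes and validation design

The test suite validates every operation against independent oracles
(exhaustive pairwise concordance for AUC, counting oracles for ORs, an
independent IRLS fit for D2, hand product-limit tables for KM, a
grid-search partial-likelihood maximizer for Cox, hand formulas for
Cohen's d and Spearman) and then checks recovery of planted structure at
the following scales, chosen to keep each property measurable with
comfortable statistical margins: signature recovery with 13 diagnoses
sharing one planted 52-feature vector at n = 20,000 over 20 seeds (with
lean CV settings — 3 outer folds, 2 inner folds, 5 penalty draws, 1 repeat
— since encoding maps are insensitive to the exact penalty); synergy
recovery over 50 replicates at n = 20,000; Cox recovery of a rate ratio of
2.0 at n = 5,000; log-rank type-I calibration over 1,000 null replicates;
path-model sign recovery at n = 20,000 and bootstrap coverage over 100
replicates at n = 5,000 with 200 resamples each; and a fully deterministic
end-to-end pipeline at n = 5,000. The numbered scripts under `analysis/`
run the same chain narratively at n = 4,000.

# What passing tests do and do not show

Passing recovery tests show the estimators are correct under the generator's
assumptions: linear effects, Gaussian exchangeable features, logistic
labels, exponential hazards, administrative censoring. They do not show that
real cohorts satisfy those assumptions — real assay panels have skewed,
bounded and co-regulated distributions, confounding is rarely purely
linear, diagnoses arrive through noisy healthcare records rather than a
Bernoulli draw, and censoring is not purely administrative. Headline
performance numbers from restricted biobank data are therefore not
reproduction targets here; the package validates machinery, not empirical
effect sizes.

# Known limitations

- Deconfounding is linear-regression-based only; no nonlinear or
  propensity-based alternatives.
- The classifier family is ridge logistic regression; SVMs and boosted
  trees are out of scope.
- The deviance partition supports exactly two sources.
- No time-varying covariates or competing risks in the survival module.
- The path model fits a fixed acyclic arrow set; no model search, latent
  variables or fit indices.
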