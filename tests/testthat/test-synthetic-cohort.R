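test_that("identical config and seed reproduce the cohort exactly", {
  cfg <- small_config(400, seed = 11)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$X, b$X)
  expect_identical(a$y, b$y)
  expect_identical(a$onset_time, b$onset_time)
  expect_identical(a$pain, b$pain)
  expect_identical(a$truth$beta, b$truth$beta)
})

test_that("empirical prevalence is calibrated to the configured base rate", {
  cfg <- small_config(6000, seed = 3)
  co <- generate_cohort(cfg)
  for (d in colnames(co$y)) {
    p <- 0.1
    se <- sqrt(p * (1 - p) / nrow(co$y))
    expect_lt(abs(mean(co$y[, d]) - p), 3 * se)
  }
})

test_that("true linear predictor AUC matches a Monte-Carlo oracle of the model", {
  mods <- list(modality_spec("blood", 20, n_latent = 4, effect_scale = 1))
  cfg <- cohort_config(20000, modalities = mods,
                       diagnoses = default_diagnoses(mods, n = 1,
                                                     interaction_strength = 0),
                       seed = 5)
  co <- generate_cohort(cfg)
  emp <- auc(co$truth$eta[, 1], co$y[, 1])
  # oracle: eta ~ N(0, total sd), y ~ Bern(plogis(c + eta)), 200k draws;
  # total sd = sqrt(w^2 * effect_scale^2) = 1 here by construction
  orc <- withr::with_seed(99, {
    eta <- rnorm(200000, sd = 1)
    y <- rbinom(200000, 1, plogis(co$truth$intercepts[1] + eta))
    auc(eta, y)
  })
  expect_lt(abs(emp - orc), 0.01)
})

test_that("zero planted effects leave no learnable signal", {
  mods <- list(modality_spec("blood", 15, effect_scale = 0),
               modality_spec("psychosocial", 10, effect_scale = 0))
  cfg <- cohort_config(1500, modalities = mods,
                       diagnoses = default_diagnoses(mods, n = 1,
                                                     interaction_strength = 0),
                       seed = 21)
  co <- generate_cohort(cfg)
  b <- nested_cv_train(co$X$blood, co$y[, 1], co$C, fast_cv(seed = 21))
  se <- sd(b$auc) / sqrt(length(b$auc))
  expect_lt(abs(mean(b$auc) - 0.5), 3 * max(se, 0.02))
})

test_that("confounder leakage is visible raw and removed by residualization", {
  cfg <- small_config(5000, seed = 13)
  co <- generate_cohort(cfg)
  # feature 1 is assigned to the age confounder by round-robin
  r_raw <- cor(co$X$blood[, 1], co$C[, "age"])
  expect_gt(abs(r_raw), 0.05)
  rz <- fit_residualizer(co$X$blood, co$C)
  Xt <- apply_residualizer(rz, co$X$blood, co$C)
  r_post <- max(abs(cor(Xt, co$C)))
  expect_lt(r_post, 1e-8)
})

test_that("invalid generator configs are rejected", {
  mods <- small_modalities()
  expect_error(modality_spec("m", 3, n_latent = 5), "n_features >= n_latent")
  expect_error(diagnosis_spec("d", base_rate = 0, modality_weights = c(blood = 1)),
               "base_rate")
  expect_error(cohort_config(5, modalities = mods,
                             diagnoses = default_diagnoses(mods, base_rate = 0.1)),
               "no cases possible")
  expect_error(modality_spec("m", 10, feature_block_correlation = 1),
               "feature_block_correlation")
})

test_that("pain phenotypes reproduce the 14-phenotype derivation rules", {
  sites <- c("headache", "facial", "neck_shoulder", "stomach_abdominal",
             "back", "hip", "knee")
  chronic <- matrix(0L, 3, 7, dimnames = list(NULL, sites))
  acute <- matrix(0L, 3, 7, dimnames = list(NULL, sites))
  chronic[1, c("back", "knee")] <- 1L   # back + knee -> spread 2
  pao <- c(FALSE, TRUE, FALSE)          # subject 2: pain all over
  ph <- derive_pain_phenotypes(list(chronic = chronic, acute = acute,
                                    pain_all_over = pao))
  expect_equal(unname(ph[1, "spread_2"]), 1L)
  expect_equal(unname(ph[1, "chronic_back"]), 1L)
  expect_equal(unname(ph[1, "chronic_knee"]), 1L)
  expect_equal(unname(ph[1, "spread_1"] + ph[1, "spread_3"] +
                        ph[1, "spread_4plus"]), 0L)
  # pain-all-over counts as any-chronic but not in site/spread phenotypes
  expect_equal(unname(ph[2, "chronic_any"]), 1L)
  site_cols <- setdiff(grep("^chronic_", colnames(ph), value = TRUE),
                       "chronic_any")
  expect_equal(sum(ph[2, site_cols]), 0L)
  expect_equal(sum(ph[2, grepl("^spread", colnames(ph))]), 0L)
  # all-zero subject is pain-free on every phenotype
  expect_equal(sum(ph[3, ]), 0L)
})

test_that("phenotype category counts equal a direct per-row recount", {
  co <- generate_cohort(small_config(200, seed = 31))
  ph <- derive_pain_phenotypes(co)
  count <- rowSums(co$pain$chronic)
  for (k in 1:3)
    expect_equal(unname(colSums(ph)[paste0("spread_", k)]),
                 sum(count == k & !co$pain$pain_all_over))
  expect_equal(unname(colSums(ph)["spread_4plus"]),
               sum(count >= 4 & !co$pain$pain_all_over))
  expect_equal(unname(colSums(ph)["chronic_any"]),
               sum(count > 0 | co$pain$pain_all_over))
})

test_that("contradictory pain flags are rejected", {
  chronic <- matrix(1L, 1, 2, dimnames = list(NULL, c("back", "knee")))
  acute <- matrix(0L, 1, 2, dimnames = list(NULL, c("back", "knee")))
  expect_error(derive_pain_phenotypes(list(chronic = chronic, acute = acute,
                                           pain_all_over = TRUE)),
               "contradictory")
})

test_that("control selection equals the set-difference oracle", {
  co <- generate_cohort(small_config(500, seed = 41))
  ctrl <- select_controls(co)
  oracle <- setdiff(seq_len(500), which(co$y[, 1] == 1 | co$y[, 2] == 1))
  expect_identical(ctrl, oracle)
  expect_true(all(rowSums(co$y[ctrl, ]) == 0))
  # any single positive label excludes a subject
  expect_false(any(which(co$y[, 2] == 1) %in% ctrl))
})

test_that("onset times are positive and censored administratively", {
  co <- generate_cohort(small_config(300, seed = 51))
  cens <- max(co$config$followup$visit_offsets_years)
  expect_true(all(co$onset_time > 0))
  expect_true(all(co$onset_time <= cens))
  expect_true(all(co$onset_time[co$onset_event == 0] == cens))
})

test_that("cohort round-trips through delimited text files", {
  co <- generate_cohort(small_config(60, seed = 61))
  dir <- withr::local_tempdir()
  files <- write_cohort(co, dir)
  feat <- read_table(files[["features_blood"]])
  expect_equal(as.matrix(feat[, -1]), co$X$blood, ignore_attr = TRUE,
               tolerance = 1e-12)
  lab <- read_table(files[["labels"]])
  expect_equal(lab$dx1, unname(co$y[, 1]))
})
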