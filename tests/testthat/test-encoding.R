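# helper: minimal bundle with fixed weights over given data (bypasses CV)
fixed_bundle <- function(X, C, beta, y = NULL) {
  rz <- fit_residualizer(X, C)
  structure(list(folds = list(list(repeat_id = 1L, fold = 1L, beta = beta,
                                   intercept = 0, lambda = 1,
                                   residualizer = rz,
                                   train_idx = seq_len(nrow(X)),
                                   val_idx = seq_len(nrow(X)),
                                   val_scores = numeric(0),
                                   val_probs = numeric(0), val_auc = NA)),
                 auc = NA_real_, config = NULL,
                 feature_names = colnames(X), n = nrow(X), y = y),
            class = "model_bundle")
}

test_that("structure coefficients match direct correlations with the score", {
  withr::with_seed(1, {
    X <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, c("a", "b", "c")))
    C <- cbind(age = rnorm(100))
    beta <- c(1.5, -0.7, 0.2)
    b <- fixed_bundle(X, C, beta)
    em <- structure_coefficients(b, X, C)
    Xt <- apply_residualizer(b$folds[[1]]$residualizer, X, C)
    s <- drop(Xt %*% beta)
    expect_equal(em$coef, unname(apply(Xt, 2, cor, y = s)), tolerance = 1e-12)
  })
})

test_that("a single-feature model has structure coefficient sign(beta) * 1", {
  withr::with_seed(2, {
    X <- matrix(rnorm(50), 50, 1, dimnames = list(NULL, "only"))
    C <- cbind(age = rnorm(50))
    em_pos <- structure_coefficients(fixed_bundle(X, C, 2), X, C)
    em_neg <- structure_coefficients(fixed_bundle(X, C, -3), X, C)
    expect_equal(em_pos$coef, 1)
    expect_equal(em_neg$coef, -1)
  })
})

test_that("anti-correlated feature pairs get equal-magnitude opposite coefficients", {
  withr::with_seed(3, {
    x <- rnorm(80)
    X <- cbind(up = x, down = -x, noise = rnorm(80))
    C <- cbind(age = rnorm(80))
    em <- structure_coefficients(fixed_bundle(X, C, c(1, 0, 0.3)), X, C)
    expect_equal(em$coef[1], -em$coef[2], tolerance = 1e-12)
  })
})

test_that("a feature orthogonal to the decision score has coefficient near zero", {
  withr::with_seed(4, {
    n <- 4000
    X <- cbind(sig = rnorm(n), orth = rnorm(n))
    C <- cbind(age = rnorm(n))
    em <- structure_coefficients(fixed_bundle(X, C, c(1, 0)), X, C)
    expect_lt(abs(em$coef[2]), 0.05)
  })
})

test_that("composite averaging equals a loop-based oracle and records SD", {
  withr::with_seed(5, {
    maps <- lapply(1:13, function(i)
      structure(data.frame(feature = paste0("f", 1:9), coef = runif(9, -1, 1)),
                class = c("encoding_map", "data.frame")))
    cs <- composite_signature(maps)
    oracle <- sapply(1:9, function(j)
      mean(sapply(maps, function(m) m$coef[j])))
    expect_equal(cs$coef, oracle, tolerance = 1e-14)
    sd_oracle <- sapply(1:9, function(j)
      sd(sapply(maps, function(m) m$coef[j])))
    expect_equal(cs$coef_sd, sd_oracle, tolerance = 1e-14)
    # identical maps -> composite equals any input, SD zero
    cs2 <- composite_signature(maps[c(1, 1, 1)])
    expect_equal(cs2$coef, maps[[1]]$coef)
    expect_equal(cs2$coef_sd, rep(0, 9))
    # exact negatives cancel
    neg <- maps[[1]]; neg$coef <- -neg$coef
    expect_equal(composite_signature(list(maps[[1]], neg))$coef, rep(0, 9))
  })
})

test_that("composite rejects mismatched feature sets", {
  a <- data.frame(feature = c("x", "y"), coef = c(0.1, 0.2))
  b <- data.frame(feature = c("x", "z"), coef = c(0.1, 0.2))
  expect_error(composite_signature(list(a, b)), "feature")
})

test_that("simplification keeps the top-k by |coefficient| with stable ties", {
  withr::with_seed(6, {
    co <- runif(52, -1, 1)
    sig <- data.frame(feature = paste0("f", 1:52), coef = co)
    s10 <- simplify_signature(sig, 10)
    kept <- which(s10$coef != 0)
    oracle <- sort(order(-abs(co))[1:10])
    expect_equal(kept, oracle)
    expect_equal(s10$coef[kept], co[kept]) # values unchanged
  })
  # tie at the rank boundary: earlier feature kept
  sig <- data.frame(feature = c("a", "b", "c"), coef = c(0.5, -0.5, 0.1))
  s1 <- simplify_signature(sig, 1)
  expect_equal(which(s1$coef != 0), 1L)
  # already exactly k nonzeros: unchanged
  sig2 <- data.frame(feature = c("a", "b", "c"), coef = c(0.5, 0, 0.3))
  expect_equal(simplify_signature(sig2, 2)$coef, sig2$coef)
  expect_error(simplify_signature(sig, 0), "positive")
})

test_that("density thresholding uses the ceiling rule and nests", {
  withr::with_seed(7, {
    co <- rnorm(52)
    sig <- data.frame(feature = paste0("f", 1:52), coef = co)
    expect_equal(threshold_signature(sig, 1)$coef, co) # identity
    t10 <- threshold_signature(sig, 0.1)
    expect_equal(sum(t10$coef != 0), 6L)  # ceiling(5.2)
    # retained sets are nested along the density ladder
    ladder <- c(1, 0.5, 0.25, 0.1, 0.05, 0.01, 0.005)
    sets <- lapply(ladder, function(d)
      which(threshold_signature(sig, d)$coef != 0))
    for (i in seq_len(length(sets) - 1))
      expect_true(all(sets[[i + 1]] %in% sets[[i]]))
    expect_error(threshold_signature(sig, 0), "density")
    expect_error(threshold_signature(sig, 1.2), "density")
  })
})

test_that("subject scoring is the dot product on the deconfounded scale", {
  withr::with_seed(8, {
    X <- matrix(rnorm(200), 40, 5, dimnames = list(NULL, paste0("f", 1:5)))
    C <- cbind(age = rnorm(40))
    rz <- fit_residualizer(X, C)
    co <- rnorm(5)
    sig <- data.frame(feature = paste0("f", 1:5), coef = co)
    s <- score_subjects(sig, X, C, rz)
    Xt <- apply_residualizer(rz, X, C)
    expect_equal(s, drop(Xt %*% co), tolerance = 1e-12)
    # all-zero signature
    sig0 <- data.frame(feature = paste0("f", 1:5), coef = rep(0, 5))
    expect_equal(score_subjects(sig0, X, C, rz), rep(0, 40))
    # one-hot signature equals that standardized column
    sig1 <- data.frame(feature = paste0("f", 1:5), coef = c(0, 1, 0, 0, 0))
    expect_equal(score_subjects(sig1, X, C, rz), Xt[, 2])
    # density-1 thresholding leaves the scores exactly unchanged
    expect_identical(score_subjects(threshold_signature(sig, 1), X, C, rz), s)
  })
})

test_that("encoding similarity reports r and a permutation p", {
  withr::with_seed(9, {
    a <- rnorm(20); b <- 0.8 * a + rnorm(20, sd = 0.3)
    sim <- encoding_similarity(a, b, n_permutations = 999, seed = 1)
    expect_equal(sim$r, cor(a, b))
    expect_lte(sim$p, 0.01)
    # self-similarity at the minimum attainable p
    self <- encoding_similarity(a, a, n_permutations = 999, seed = 1)
    expect_equal(self$r, 1)
    expect_equal(self$p, 1 / 1000)
    expect_equal(encoding_similarity(a, -a, n_permutations = 10, seed = 1)$r, -1)
    # exact enumeration on a 6-feature instance
    a6 <- c(0.3, -1.2, 0.5, 2.0, -0.7, 0.1)
    b6 <- c(0.1, -0.9, 0.8, 1.5, -0.2, 0.4)
    ex <- encoding_similarity(a6, b6, exact = TRUE)
    perms <- painbps:::all_permutations(6)
    rp <- apply(perms, 1, function(ix) cor(a6, b6[ix]))
    expect_equal(ex$p, mean(abs(rp) >= abs(cor(a6, b6)) - 1e-12))
    expect_equal(ex$n_permutations, factorial(6))
    expect_error(encoding_similarity(a, rep(1, 20)), "zero-variance")
  })
})

test_that("permutation-null AUC is calibrated and detects planted signal", {
  mods <- list(modality_spec("blood", 20, effect_scale = 1.2))
  cfg <- cohort_config(2000, modalities = mods,
                       diagnoses = default_diagnoses(mods, n = 1,
                                                     interaction_strength = 0),
                       seed = 15)
  co <- generate_cohort(cfg)
  rz <- fit_residualizer(co$X$blood, co$C)
  # signature aligned with the planted coefficients
  sig <- data.frame(feature = colnames(co$X$blood),
                    coef = co$truth$beta$blood[, 1])
  res <- permutation_null_auc(sig, co$X$blood, co$y[, 1], co$C, rz,
                              n_permutations = 500, seed = 5)
  expect_lt(abs(res$null_mean - 0.5), 3 * res$null_sd / sqrt(500))
  expect_lte(res$p, 0.01)
  expect_gt(res$observed, 0.6)
  # label-independent signature sits inside its own null
  sig0 <- data.frame(feature = colnames(co$X$blood),
                     coef = withr::with_seed(1, rnorm(20)))
  inside <- vapply(1:10, function(k) {
    y_perm <- withr::with_seed(100 + k, sample(co$y[, 1]))
    r <- permutation_null_auc(sig0, co$X$blood, y_perm, co$C, rz,
                              n_permutations = 200, seed = k)
    r$observed >= quantile(r$null, 0.025) &
      r$observed <= quantile(r$null, 0.975)
  }, NA)
  expect_gte(mean(inside), 0.9)
})

test_that("signatures round-trip through the two-column file format", {
  sig <- data.frame(feature = paste0("f", 1:5), coef = rnorm(5))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_signature(sig, path)
  back <- read_signature(path)
  expect_equal(back$coef, sig$coef, tolerance = 1e-12)
  expect_equal(back$feature, sig$feature)
})
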