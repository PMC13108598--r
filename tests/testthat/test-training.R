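test_that("intercept-only data recovers the closed-form logistic MLE", {
  n <- 4000
  f <- matrix(0, nrow = n, ncol = 6)
  # constant features are dropped internally; the intercept carries the fit
  set.seed(4)
  labels <- runif(n) < 0.3
  fit <- fitLogistic(f, labels)
  q <- mean(labels)
  expect_equal(unname(fit$coefficients["m0"]), log(q / (1 - q)),
               tolerance = 1e-6)
  expect_equal(unname(fit$coefficients[-1]), rep(0, 6))
})

test_that("labels independent of features give near-zero slopes", {
  gen <- generateLabelledFeatures(rep(0, 7), 5000, seed = 10)
  set.seed(11)
  labels <- runif(5000) < 0.5
  fit <- fitLogistic(gen$features, labels)
  se <- sqrt(diag(fit$vcov))[-1]
  expect_true(all(abs(fit$coefficients[-1]) <= 3 * se))
})

test_that("fitLogistic matches an independent glm fit", {
  truth <- c(0.5, -3, 2, 0.01, -1, -1.5, 0.8)
  gen <- generateLabelledFeatures(truth, 4000, seed = 12)
  fit <- fitLogistic(gen$features, gen$labels)
  ref <- glm.fit(cbind(1, gen$features), as.numeric(gen$labels),
                 family = binomial())
  expect_equal(unname(fit$coefficients), unname(ref$coefficients),
               tolerance = 1e-6)
})

test_that("parameter recovery: known coefficients are re-estimated", {
  truth <- c(1, -6, 4, 0.01, -1, -2, -1)
  gen <- generateLabelledFeatures(truth, 20000, seed = 2024)
  fit <- fitLogistic(gen$features, gen$labels)
  # joint 95% Wald confidence region around the estimate covers the truth
  d <- fit$coefficients - truth
  stat <- as.numeric(t(d) %*% solve(fit$vcov) %*% d)
  expect_lt(stat, qchisq(0.95, df = 7))
  # held-out columns: fitted classification reproduces the generator's
  held <- generateLabelledFeatures(truth, 10000, seed = 2025)
  pFit <- preservationScore(held$features, filterModel(fit$coefficients))
  expect_gte(mean((pFit > 0.5) == (held$prob > 0.5)), 0.99)
})

test_that("the IRLS loss trace is monotonically decreasing", {
  gen <- generateLabelledFeatures(c(0.5, -2, 1, 0, -1, 0.5, -0.5), 2000,
                                  seed = 33)
  fit <- fitLogistic(gen$features, gen$labels)
  expect_true(all(diff(fit$lossTrace) <= 1e-12))
  expect_true(fit$converged)
})

test_that("standardized and raw fits give identical predictions", {
  truth <- c(0.2, -2, 1.5, 0.005, -0.8, -1, 0.3)
  gen <- generateLabelledFeatures(truth, 3000, seed = 44)
  fitStd <- fitLogistic(gen$features, gen$labels, standardize = TRUE)
  fitRaw <- fitLogistic(gen$features, gen$labels, standardize = FALSE)
  pStd <- preservationScore(gen$features, filterModel(fitStd$coefficients))
  pRaw <- preservationScore(gen$features, filterModel(fitRaw$coefficients))
  expect_lt(max(abs(pStd - pRaw)), 1e-10)
})

test_that("degenerate training inputs raise informative errors", {
  gen <- generateLabelledFeatures(rep(0, 7), 200, seed = 1)
  expect_error(fitLogistic(gen$features, rep(TRUE, 200)), "single class")
  expect_error(fitLogistic(gen$features[1:5, ], gen$labels[1:5]),
               "at least 7")
  # perfectly separable labels are refused, not silently fitted
  f <- gen$features
  sep <- f[, "gap"] > 0.5
  expect_error(fitLogistic(f, sep), "separable|converge")
})

test_that("fitted coefficients ignore the order of training columns", {
  corpus <- generateCorpus(6, seed = 77)
  pooled <- poolTrainingData(corpusAlignments(corpus), corpusMasks(corpus))
  fit1 <- fitLogistic(pooled$features, pooled$labels)
  perm <- withr::with_seed(7, sample.int(nrow(pooled$features)))
  fit2 <- fitLogistic(pooled$features[perm, ], pooled$labels[perm])
  expect_equal(fit1$coefficients, fit2$coefficients, tolerance = 1e-6)
})

test_that("partitioning treats alignments as unbreakable units", {
  p <- partitionAlignments(4, c(2, 1, 1), seed = 1)
  expect_equal(lengths(p), c(train = 2L, validation = 1L, test = 1L))
  expect_setequal(unlist(p), 1:4)

  p21 <- partitionAlignments(21, c(2, 1, 1), seed = 5)
  # largest remainder: 10.5, 5.25, 5.25 -> (11, 5, 5)
  expect_equal(unname(lengths(p21)), c(11L, 5L, 5L))
  expect_setequal(unlist(p21), 1:21)
  expect_equal(anyDuplicated(unlist(p21)), 0L)

  expect_identical(partitionAlignments(21, seed = 5),
                   partitionAlignments(21, seed = 5))
  expect_error(partitionAlignments(2, c(2, 1, 1)), "cannot split")
})

test_that("mistake injection flips an exact, seeded set of flags", {
  mask <- withr::with_seed(3, runif(100) > 0.4)
  expect_identical(injectMistakes(mask, 0, seed = 1), mask)
  expect_identical(injectMistakes(mask, 1, seed = 1), !mask)
  half <- injectMistakes(mask, 0.5, seed = 9)
  expect_equal(sum(half != mask), 50)
  expect_identical(half, injectMistakes(mask, 0.5, seed = 9))
  expect_equal(sum(injectMistakes(mask, 0.33, seed = 2) != mask),
               round(0.33 * 100))
})

test_that("trainModel produces an unvalidated model with provenance", {
  corpus <- generateCorpus(8, seed = 15)
  model <- trainModel(corpusAlignments(corpus), corpusMasks(corpus))
  expect_s4_class(model, "FilterModel")
  expect_false(isValidated(model))
  expect_equal(threshold(model), 0.5)
  expect_equal(unname(bootstrapSettings(model)["b"]), 0)
  expect_length(coef(model), 7L)
  expect_match(modelMetadata(model)$trained_on, "8 alignments")
})
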