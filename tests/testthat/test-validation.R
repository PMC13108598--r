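test_that("threshold search maximizes the metric with deterministic ties", {
  # any t in [0.2, 0.8) is perfect; the tie-break returns 0.5
  res <- findThreshold(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(res$threshold, 0.5)
  expect_equal(res$metricValue, 1)

  # labels self-consistent with t = 0.5
  set.seed(6)
  p <- runif(60, 0.01, 0.99)
  truth <- p > 0.5
  res <- findThreshold(p, truth)
  expect_equal(res$metricValue, 1)
  expect_equal(res$threshold, 0.5)

  expect_error(findThreshold(p, rep(TRUE, 60)), "both classes")
})

test_that("the returned metric equals a brute-force scan of the grid", {
  set.seed(14)
  for (metric in c("mcc", "accuracy", "fbeta")) {
    p <- runif(80, 0.01, 0.99)
    truth <- runif(80) > 0.45
    res <- findThreshold(p, truth, metric = metric, beta = 0.5)
    grid <- seq(0, 1, by = 0.01)
    best <- max(vapply(grid, function(t) {
      metricFromCounts <- switch(metric,
        mcc = mcc, accuracy = accuracy,
        fbeta = function(cc) fBeta(cc, beta = 0.5))
      metricFromCounts(confusionCounts(p > t, truth))
    }, numeric(1)))
    expect_equal(res$metricValue, best, tolerance = 1e-12)
  }
})

test_that("bootstrap pass counts are seeded and degenerate cases collapse", {
  corpus <- generateAlignment(12, list(blockSpec(15, "conserved"),
                                       blockSpec(10, "gappy")), seed = 2)
  model <- filterModel(c(2, -8, 2, 0, -1, -1, -1), threshold = 0.5,
                       validated = TRUE)
  c1 <- bootstrapPassCounts(corpus$alignment, model, b = 50, seed = 4)
  c2 <- bootstrapPassCounts(corpus$alignment, model, b = 50, seed = 4)
  expect_identical(c1, c2)
  expect_true(all(c1 >= 0 & c1 <= 50))

  # single-sequence alignment: every replicate is identical
  one <- Msa(c(a = "AAAA--TT"))
  cOne <- bootstrapPassCounts(one, model, b = 20, seed = 1)
  expect_true(all(cOne %in% c(0L, 20L)))

  # b = 1 equals the 0/1 classification of the single replicate
  cB1 <- bootstrapPassCounts(one, model, b = 1, seed = 1)
  expect_true(all(cB1 %in% c(0L, 1L)))

  # pass fractions are stable across seeds at large b
  cA <- bootstrapPassCounts(corpus$alignment, model, b = 500, seed = 11)
  cB <- bootstrapPassCounts(corpus$alignment, model, b = 500, seed = 22)
  expect_lte(max(abs(cA - cB) / 500), 0.1)
})

test_that("the bootstrap preservation rule reads 'at least tb*b'", {
  expect_true(bootstrapDecision(70, b = 100, tb = 0.7))
  expect_false(bootstrapDecision(69, b = 100, tb = 0.7))
  expect_true(all(bootstrapDecision(0:10, b = 10, tb = 0)))
  # monotone in count, anti-monotone in tb
  d <- bootstrapDecision(0:100, b = 100, tb = 0.35)
  expect_true(all(diff(d) >= 0))
  expect_gte(sum(bootstrapDecision(0:100, 100, 0.2)),
             sum(bootstrapDecision(0:100, 100, 0.8)))
  expect_error(bootstrapDecision(101, 100, 0.5), "\\[0, b\\]")
})

test_that("regularized score trades metric gain against replicate count", {
  expect_equal(regularizedScore(0.95, 0), 0.95)
  # +100 replicates need a 0.005 gain with the default penalty
  expect_lt(regularizedScore(0.954, 100), regularizedScore(0.950, 0))
  expect_gt(regularizedScore(0.960, 100), regularizedScore(0.950, 0))
})

test_that("bootstrap selection prefers b = 0 unless the gain justifies it", {
  corpus <- generateCorpus(4, seed = 50)
  model <- trainModel(corpusAlignments(corpus), corpusMasks(corpus))
  vmodel <- filterModel(coef(model), threshold = 0.5, validated = TRUE)
  sel <- selectBootstrap(corpusAlignments(corpus), corpusMasks(corpus),
                         vmodel, candidateB = c(0L, 20L),
                         candidateTb = c(0.3, 0.5, 0.7), seed = 3)
  expect_true(sel$b %in% c(0L, 20L))
  expect_equal(sel$score, regularizedScore(sel$metricValue, sel$b))
  # the reported best is the max of the diagnostics grid
  expect_equal(sel$score, max(sel$grid$S), tolerance = 1e-12)
  # a huge penalty always forces b = 0
  sel0 <- selectBootstrap(corpusAlignments(corpus), corpusMasks(corpus),
                          vmodel, candidateB = c(0L, 20L),
                          candidateTb = c(0.5), penalty = 1, seed = 3)
  expect_equal(sel0$b, 0L)
})

test_that("identical rows make bootstrap and plain filtering agree", {
  msa <- Msa(setNames(rep("AAAATT--CC----GG", 8), paste0("s", 1:8)))
  model <- filterModel(c(3, -9, 1, 0, -2, -2, 0), threshold = 0.5,
                       bootstrapReplicates = 30L, bootstrapThreshold = 0.9,
                       validated = TRUE)
  plain <- classifyColumns(scoreAlignment(msa, model), threshold(model))
  boot <- filterAlignment(msa, model, seed = 5)$mask
  expect_identical(unname(boot), unname(plain))
})

test_that("validateModel calibrates t and reproduces its reported metric", {
  corpus <- generateCorpus(10, seed = 60)
  idx <- partitionAlignments(10, c(2, 1, 1), seed = 1)
  tr <- corpus[idx$train]; va <- corpus[idx$validation]
  model <- trainModel(corpusAlignments(tr), corpusMasks(tr))
  v <- validateModel(model, corpusAlignments(va), corpusMasks(va),
                     candidateB = c(0L, 20L), candidateTb = c(0.3, 0.7),
                     seed = 8)
  expect_true(isValidated(v))
  info <- attr(v, "validation")
  # re-applying the selected settings reproduces the reported M exactly
  truth <- unlist(corpusMasks(va))
  if (bootstrapSettings(v)[["b"]] == 0) {
    p <- unlist(lapply(corpusAlignments(va), scoreAlignment, model = v))
    M <- mcc(confusionCounts(p > threshold(v), truth))
    expect_equal(M, info$bootstrap$metricValue, tolerance = 1e-12)
  }
  expect_equal(info$thresholdMetric,
               findThreshold(
                 unlist(lapply(corpusAlignments(va), scoreAlignment,
                               model = model)), truth)$metricValue)
})
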