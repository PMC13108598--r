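test_that("confusion counts tally preserve as the positive class", {
  t4 <- c(TRUE, TRUE, FALSE, FALSE)
  expect_equal(confusionCounts(t4, t4), c(tp = 2L, tn = 2L, fp = 0L, fn = 0L))
  expect_equal(confusionCounts(!t4, t4), c(tp = 0L, tn = 0L, fp = 2L, fn = 2L))
  set.seed(2)
  pred <- runif(100) > 0.5
  truth <- runif(100) > 0.5
  cc <- confusionCounts(pred, truth)
  expect_equal(unname(cc["tp"]), sum(pred & truth))
  expect_equal(sum(cc), 100)
  expect_error(confusionCounts(pred, truth[1:99]), "lengths differ")
})

test_that("MCC, accuracy and F-beta match worked examples", {
  expect_equal(mcc(c(tp = 2, tn = 2, fp = 0, fn = 0)), 1)
  expect_equal(mcc(c(tp = 0, tn = 0, fp = 2, fn = 2)), -1)
  expect_equal(mcc(c(tp = 40, tn = 40, fp = 10, fn = 10)), 0.6)
  # zero marginal -> 0 by convention
  expect_equal(mcc(c(tp = 5, tn = 0, fp = 5, fn = 0)), 0)

  expect_equal(accuracy(c(tp = 40, tn = 40, fp = 10, fn = 10)), 0.8)
  expect_equal(accuracy(c(tp = 3, tn = 2, fp = 0, fn = 0)), 1)
  expect_error(accuracy(c(tp = 0, tn = 0, fp = 0, fn = 0)), "zero columns")

  expect_equal(fBeta(c(tp = 40, tn = 40, fp = 10, fn = 10), beta = 1), 0.8)
  expect_equal(fBeta(c(tp = 5, tn = 5, fp = 0, fn = 0)), 1)
  # large beta with no false negatives approaches 1
  expect_gt(fBeta(c(tp = 10, tn = 0, fp = 50, fn = 0), beta = 100), 0.99)
  expect_equal(fBeta(c(tp = 0, tn = 5, fp = 2, fn = 3)), 0)
})

test_that("metrics agree with direct formulas on random confusion tables", {
  set.seed(7)
  for (i in 1:1000) {
    cc <- setNames(as.numeric(sample(0:50, 4, replace = TRUE)),
                   c("tp", "tn", "fp", "fn"))
    expect_equal(mcc(cc), oracleMcc(cc["tp"], cc["tn"], cc["fp"], cc["fn"]),
                 tolerance = 1e-12)
    expect_gte(mcc(cc), -1); expect_lte(mcc(cc), 1)
    if (sum(cc) > 0) {
      a <- accuracy(cc)
      expect_equal(a, unname((cc["tp"] + cc["tn"]) / sum(cc)),
                   tolerance = 1e-12)
      expect_gte(a, 0); expect_lte(a, 1)
    }
    b <- runif(1, 0.2, 5)
    fb <- fBeta(cc, beta = b)
    den <- (1 + b^2) * cc["tp"] + b^2 * cc["fn"] + cc["fp"]
    if (den > 0) {
      expect_equal(fb, unname((1 + b^2) * cc["tp"] / den), tolerance = 1e-12)
    }
    expect_gte(fb, 0); expect_lte(fb, 1)
    # MCC is invariant under the simultaneous swap tp<->tn, fp<->fn
    expect_equal(mcc(cc), mcc(setNames(cc[c("tn", "tp", "fn", "fp")],
                                       names(cc))), tolerance = 1e-12)
  }
})

test_that("log loss matches direct summation and its limits", {
  truth <- c(TRUE, FALSE, TRUE)
  expect_equal(logLoss(rep(0.5, 3), truth), log(2))
  nearPerfect <- ifelse(truth, 1 - 1e-12, 1e-12)
  expect_lt(logLoss(nearPerfect, truth), 1e-10)
  set.seed(5)
  p <- runif(200, 0.01, 0.99)
  y <- runif(200) > 0.5
  direct <- -mean(ifelse(y, log(p), log(1 - p)))
  expect_equal(logLoss(p, y), direct, tolerance = 1e-12)
  expect_error(logLoss(p, y[1:100]), "lengths differ")
  expect_error(logLoss(c(0, 0.5), c(TRUE, FALSE)), "strictly inside")
})

test_that("ROC/AUC match the pairwise-rank oracle and trapezoid area", {
  expect_equal(rocAuc(c(0.9, 0.8, 0.4, 0.3), c(TRUE, FALSE, TRUE, FALSE))$auc,
               0.75)
  expect_equal(rocAuc(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE))$auc,
               1)
  expect_equal(rocAuc(rep(0.4, 6), rep(c(TRUE, FALSE), 3))$auc, 0.5)
  expect_error(rocAuc(c(0.1, 0.9), c(TRUE, TRUE)), "both classes")

  set.seed(13)
  for (i in 1:60) {
    n <- sample(5:40, 1)
    # ties on purpose: scores drawn from a small grid
    p <- sample(seq(0.05, 0.95, by = 0.05), n, replace = TRUE)
    truth <- runif(n) > 0.5
    if (!any(truth) || all(truth)) next
    ra <- rocAuc(p, truth)
    expect_equal(ra$auc, oracleAuc(p, truth), tolerance = 1e-12)
    expect_equal(trapezoidArea(ra$roc), ra$auc, tolerance = 1e-12)
    expect_equal(ra$roc$fpr[1], 0); expect_equal(ra$roc$tpr[1], 0)
    expect_equal(tail(ra$roc$fpr, 1), 1); expect_equal(tail(ra$roc$tpr, 1), 1)
    expect_true(all(diff(ra$roc$fpr) >= 0))
    expect_true(all(diff(ra$roc$tpr) >= 0))
  }
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(99)
  for (i in 1:10) {
    p <- runif(80)
    truth <- runif(80) > 0.4
    ref <- as.numeric(suppressMessages(
      pROC::auc(pROC::roc(response = truth, predictor = p,
                          direction = "<", quiet = TRUE))))
    expect_equal(rocAuc(p, truth)$auc, ref, tolerance = 1e-12)
  }
})

test_that("evaluation reports bundle the metrics coherently", {
  set.seed(17)
  p <- runif(120, 0.01, 0.99)
  truth <- runif(120) > 0.5
  pred <- p > 0.5
  rep_ <- evaluationReport(p, pred, truth, beta = 2)
  expect_s4_class(rep_, "EvaluationReport")
  cc <- confusionCounts(pred, truth)
  expect_equal(rep_@mcc, mcc(cc))
  expect_equal(rep_@accuracy, accuracy(cc))
  expect_equal(rep_@fBeta, fBeta(cc, beta = 2))
  expect_equal(rep_@logLoss, logLoss(p, truth))
  expect_equal(rep_@confidence, confidenceScore(p))
  expect_equal(rep_@auc, rocAuc(p, truth)$auc)

  f <- withr::local_tempfile(fileext = ".json")
  writeReport(rep_, f)
  parsed <- jsonlite::fromJSON(f)
  expect_equal(parsed$mcc, rep_@mcc)
  expect_equal(parsed$confusion$tp, unname(cc["tp"]))
  writeReport(rep_, f, format = "text")
  expect_match(paste(readLines(f), collapse = " "), "MCC=")
})
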