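test_that("fusion modes implement OR / AND over aligned call sets", {
  n <- 10
  truth <- rep(c(TRUE, FALSE), 5)
  a <- data.frame(level = 1:n, positive = rep(FALSE, n))
  b <- data.frame(level = 1:n, positive = c(rep(TRUE, 4), rep(FALSE, 6)))
  expect_identical(fuseCalls(a, b, "complement_negative")$positive, b$positive)
  a2 <- data.frame(level = 1:n, positive = rep(TRUE, n))
  expect_identical(fuseCalls(a2, b, "confirm_positive")$positive, b$positive)
  expect_identical(fuseCalls(a2, b, "standalone"), a2)
  expect_error(fuseCalls(a, data.frame(level = 2:11, positive = b$positive),
                         "complement_negative"),
               "aligned")
})

test_that("fusing the published call profiles reproduces the printed OR counts", {
  truth <- cohortTruth()
  ov <- overlappingCalls(tpA = 102, fpA = 82, tpB = 100, fpB = 7,
                         tpBoth = 82, fpBoth = 2)
  or <- confusionMatrix(truth, fuseCalls(ov$a, ov$b, "complement_negative"))
  expect_identical(counts(or), c(tp = 120L, fp = 87L, tn = 795L, fn = 28L))
  and <- confusionMatrix(truth, fuseCalls(ov$a, ov$b, "confirm_positive"))
  expect_identical(counts(and), c(tp = 82L, fp = 2L, tn = 880L, fn = 66L))
})

test_that("inclusion-exclusion and fusion ordering hold on random cohorts", {
  set.seed(99)
  for (i in 1:1000) {
    n <- sample(20:80, 1)
    truth <- runif(n) < runif(1, 0.1, 0.5)
    if (!any(truth) || all(truth)) next
    a <- data.frame(level = 1:n, positive = runif(n) < runif(1, 0.1, 0.9))
    b <- data.frame(level = 1:n, positive = runif(n) < runif(1, 0.1, 0.9))
    cmA <- counts(confusionMatrix(truth, a))
    cmB <- counts(confusionMatrix(truth, b))
    cmOr <- counts(confusionMatrix(truth, fuseCalls(a, b, "complement_negative")))
    cmAnd <- counts(confusionMatrix(truth, fuseCalls(a, b, "confirm_positive")))
    expect_identical(cmOr[["tp"]] + cmAnd[["tp"]], cmA[["tp"]] + cmB[["tp"]])
    expect_identical(cmOr[["fp"]] + cmAnd[["fp"]], cmA[["fp"]] + cmB[["fp"]])
    # sensitivity(OR) >= both components; specificity(AND) >= both
    sens <- function(k) k[["tp"]] / (k[["tp"]] + k[["fn"]])
    spec <- function(k) k[["tn"]] / (k[["tn"]] + k[["fp"]])
    expect_gte(sens(cmOr), max(sens(cmA), sens(cmB)))
    expect_gte(spec(cmAnd), max(spec(cmA), spec(cmB)))
  }
})

test_that("confusion matrices count the four joint outcomes", {
  truth <- c(TRUE, TRUE, FALSE, FALSE, FALSE)
  calls <- data.frame(level = 1:5, positive = truth)
  expect_identical(counts(confusionMatrix(truth, calls)),
                   c(tp = 2L, fp = 0L, tn = 3L, fn = 0L))
  anti <- data.frame(level = 1:5, positive = !truth)
  expect_identical(counts(confusionMatrix(truth, anti)),
                   c(tp = 0L, fp = 3L, tn = 0L, fn = 2L))
  # the evaluated cohort with the height-based screening profile
  cm <- confusionMatrix(cohortTruth(), callsFromCounts(tp = 102, fp = 82))
  expect_identical(counts(cm), c(tp = 102L, fp = 82L, tn = 800L, fn = 46L))
})

test_that("metrics and their closed forms agree on printed examples", {
  cm <- confusionCounts(102, 82, 800, 46)
  expect_equal(round(detectionMetric(cm, "sensitivity")$value, 2), 68.92)
  cmE <- confusionCounts(100, 7, 875, 48)
  expect_equal(round(detectionMetric(cmE, "precision")$value, 2), 93.46)
  all100 <- confusionCounts(1, 0, 1, 0)
  for (m in c("sensitivity", "specificity", "accuracy", "precision"))
    expect_equal(detectionMetric(all100, m)$value, 100)
  expect_error(detectionMetric(confusionCounts(0, 0, 5, 0), "precision"),
               "zero denominator")
})

test_that("Wilson intervals match the score-test inversion (prop.test oracle)", {
  expect_equal(unname(round(wilsonCI(102, 148), 2)), c(61.06, 75.82))
  expect_equal(unname(round(wilsonCI(875, 882), 2)), c(98.37, 99.62))
  expect_equal(unname(wilsonCI(0, 50))[1], 0)
  set.seed(7)
  for (i in 1:25) {
    n <- sample(10:2000, 1)
    x <- sample(0:n, 1)
    ours <- wilsonCI(x, n) / 100
    ref <- stats::prop.test(x, n, correct = FALSE)$conf.int
    expect_equal(unname(ours), as.numeric(ref), tolerance = 1e-9)
    expect_true(ours[1] >= 0 && ours[2] <= 1)
    if (x > 0 && x < n) expect_lt(ours[1], ours[2])
  }
  expect_error(wilsonCI(1, 0), "n must be")
})

test_that("ROC handles perfect, chance and analytic-overlap score sets", {
  expect_equal(auc(rocCurve(c(TRUE, TRUE, FALSE, FALSE),
                            c(0.9, 0.8, 0.2, 0.1))), 1)
  expect_equal(auc(rocCurve(c(TRUE, FALSE, TRUE, FALSE), rep(0.5, 4))), 0.5)
  expect_error(rocCurve(c(TRUE, TRUE), c(0.1, 0.2)), "single class")

  # class-conditional uniforms U(0,0.6) vs U(0.4,1): closed-form AUC oracle
  aucTrue <- stats::integrate(function(x) punif(x, 0, 0.6), 0.4, 1)$value / 0.6
  set.seed(12)
  nPer <- 5000
  truth <- c(rep(TRUE, nPer), rep(FALSE, nPer))
  scores <- c(runif(nPer, 0.4, 1), runif(nPer, 0, 0.6))
  se <- sqrt(aucTrue * (1 - aucTrue) / nPer)
  expect_lt(abs(auc(rocCurve(truth, scores)) - aucTrue), 3 * se)
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(5)
  truth <- runif(200) < 0.3
  truth[1:2] <- c(TRUE, FALSE)
  scores <- runif(200)
  a0 <- auc(rocCurve(truth, scores))
  expect_equal(auc(rocCurve(truth, scores^3)), a0, tolerance = 1e-12)
  expect_equal(auc(rocCurve(truth, plogis(5 * scores))), a0, tolerance = 1e-12)
})

test_that("trapezoidal AUC agrees with an independent ROC implementation", {
  set.seed(31)
  truth <- runif(300) < 0.25
  truth[1:2] <- c(TRUE, FALSE)
  scores <- round(runif(300), 2)   # force ties
  ours <- auc(rocCurve(truth, scores))
  ref <- as.numeric(pROC::auc(pROC::roc(response = truth, predictor = scores,
                                        direction = "<", quiet = TRUE)))
  expect_equal(ours, ref, tolerance = 1e-9)
})

test_that("single-operating-point ROC joins the endpoints", {
  r <- rocFromConfusion(confusionCounts(102, 82, 800, 46))
  pts <- rocPoints(r)
  expect_identical(nrow(pts), 3L)
  expect_equal(pts$tpr[2], 102 / 148, tolerance = 1e-12)
  expect_equal(pts$fpr[2], 82 / 882, tolerance = 1e-12)
  expect_true(auc(r) > 0.5 && auc(r) < 1)
})
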