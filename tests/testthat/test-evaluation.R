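test_that("perfect predictions have zero FP and FN everywhere", {
  truth <- rep(c("a", "b", "c"), times = c(5, 3, 2))
  cc <- confusionCounts(truth, truth, c("a", "b", "c"))
  expect_true(all(cc@counts[, "FP"] == 0))
  expect_true(all(cc@counts[, "FN"] == 0))
  expect_equal(sum(cc@counts[, "TP"]), 10L)
})

test_that("TP + FN recovers each class's support", {
  set.seed(51)
  fams <- c("x", "y", "z")
  truth <- sample(fams, 60, replace = TRUE)
  pred <- sample(fams, 60, replace = TRUE)
  cc <- confusionCounts(truth, pred, fams)
  support <- table(factor(truth, levels = fams))
  expect_equal(unname(cc@counts[, "TP"] + cc@counts[, "FN"]),
               as.integer(support))
  expect_error(confusionCounts(truth, c(pred[-1], "w"), fams), "unknown")
  expect_error(confusionCounts(truth[-1], pred), "equal length")
})

test_that("confusion counts match the double-loop oracle on random data", {
  set.seed(52)
  fams <- c("a", "b", "c")
  for (rep in 1:5) {
    truth <- sample(fams, 50, replace = TRUE)
    pred <- sample(fams, 50, replace = TRUE)
    cc <- confusionCounts(truth, pred, fams)
    expect_equal(cc@counts, oracleConfusion(truth, pred, fams),
                 ignore_attr = FALSE)
  }
})

test_that("metrics follow their defining formulas on hand cases", {
  # two predictions, both right
  cc <- confusionCounts(c("a", "b"), c("a", "b"))
  m <- classificationMetrics(cc)
  expect_equal(c(m@accuracy, m@sensitivity, m@precision, m@f1),
               rep(1, 4))
  # class with half its members missed, nothing falsely assigned to it
  cc2 <- new("ConfusionCounts",
             counts = matrix(c(50L, 0L, 0L, 50L), 1, 4,
                             dimnames = list("a", c("TP", "TN", "FP", "FN"))),
             n = 100L)
  m2 <- classificationMetrics(cc2)
  expect_equal(m2@perClass$sensitivity, 0.5)
  expect_equal(m2@perClass$precision, 1.0)
  expect_equal(m2@perClass$f1, 2 / 3, tolerance = 1e-12)
})

test_that("F1 equals the harmonic mean of precision and sensitivity", {
  set.seed(53)
  for (rep in 1:20) {
    truth <- sample(c("a", "b", "c"), 40, replace = TRUE)
    pred <- sample(c("a", "b", "c"), 40, replace = TRUE)
    m <- suppressWarnings(
      classificationMetrics(confusionCounts(truth, pred,
                                            c("a", "b", "c"))))
    pc <- m@perClass
    ok <- pc$precision + pc$sensitivity > 0
    expect_equal(pc$f1[ok],
                 2 * pc$precision[ok] * pc$sensitivity[ok] /
                   (pc$precision[ok] + pc$sensitivity[ok]),
                 tolerance = 1e-12)
    # F1 lies between precision and sensitivity when both positive
    both <- pc$precision > 0 & pc$sensitivity > 0
    expect_true(all(pc$f1[both] >= pmin(pc$precision, pc$sensitivity)[both] &
                      pc$f1[both] <= pmax(pc$precision,
                                          pc$sensitivity)[both]))
  }
})

test_that("micro precision = micro sensitivity = overall accuracy", {
  set.seed(54)
  truth <- sample(c("a", "b", "c", "d"), 80, replace = TRUE)
  pred <- sample(c("a", "b", "c", "d"), 80, replace = TRUE)
  cc <- confusionCounts(truth, pred, c("a", "b", "c", "d"))
  m <- classificationMetrics(cc, "micro")
  expect_equal(m@precision, m@sensitivity, tolerance = 1e-12)
  expect_equal(m@precision, m@overallAccuracy, tolerance = 1e-12)
})

test_that("metrics are invariant to simultaneous permutation of labels", {
  set.seed(55)
  truth <- sample(c("a", "b"), 30, replace = TRUE)
  pred <- sample(c("a", "b"), 30, replace = TRUE)
  perm <- sample(30)
  m1 <- suppressWarnings(classificationMetrics(
    confusionCounts(truth, pred, c("a", "b"))))
  m2 <- suppressWarnings(classificationMetrics(
    confusionCounts(truth[perm], pred[perm], c("a", "b"))))
  expect_equal(m1@f1, m2@f1)
  expect_equal(m1@accuracy, m2@accuracy)
})

test_that("zero denominators yield 0 with a recorded warning flag", {
  # class 'b' never occurs and is never predicted
  cc <- confusionCounts(c("a", "a"), c("a", "a"), c("a", "b"))
  expect_warning(m <- classificationMetrics(cc), "zero denominator")
  expect_true("b" %in% m@zeroDenominator)
  expect_equal(m@perClass$f1[m@perClass$class == "b"], 0)
})

test_that("the F1 correlation matrix is symmetric with unit diagonal", {
  set.seed(56)
  f1 <- matrix(runif(10 * 4), 10, 4,
               dimnames = list(NULL, paste0("fam", 1:4)))
  cm <- f1CorrelationMatrix(f1)
  expect_equal(cm, t(cm))
  expect_equal(unname(diag(cm)), rep(1, 4))
  expect_true(all(cm >= -1 - 1e-12 & cm <= 1 + 1e-12))
  # a duplicated family column correlates exactly 1 with its twin
  f1dup <- cbind(f1, fam5 = f1[, 1])
  cmd <- f1CorrelationMatrix(f1dup)
  expect_equal(cmd["fam1", "fam5"], 1, tolerance = 1e-12)
  # zero-variance column -> missing values off the diagonal
  f1z <- cbind(f1, const = rep(0.5, 10))
  cmz <- f1CorrelationMatrix(f1z)
  expect_true(all(is.na(cmz["const", colnames(f1)])))
  expect_equal(cmz["const", "const"], 1)
  expect_error(f1CorrelationMatrix(f1[1:2, ]), "3 folds")
})
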