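test_that("accuracy matches hand values and confusion-count arithmetic", {
  expect_equal(accuracy(c(rep(1, 90), rep(2, 10)), rep(1, 100)), 0.9)
  expect_equal(accuracy(1:5, 1:5), 1)
  # TP=40 TN=30 FP=20 FN=10 as binary vectors
  pred <- c(rep(1, 40), rep(0, 30), rep(1, 20), rep(0, 10))
  truth <- c(rep(1, 40), rep(0, 30), rep(0, 20), rep(1, 10))
  expect_equal(accuracy(pred, truth), 0.70)
  expect_error(accuracy(integer(0), integer(0)), "nonempty")
})

test_that("per-class and macro F1 match hand-computed confusion values", {
  # TP=2 FP=1 FN=1 for class 1
  pred <- c(1, 1, 1, 2, 2)
  truth <- c(1, 1, 2, 1, 2)
  expect_equal(f1PerClass(pred, truth, 1), 2 * 2 / (2 * 2 + 1 + 1))
  expect_equal(f1PerClass(1:4, 1:4, 3), 1)
  expect_equal(f1PerClass(c(1, 2, 1, 2), c(1, 1, 2, 2), 1), 0.5)
  expect_warning(f1 <- f1PerClass(c(1, 1), c(1, 1), 9), "absent")
  expect_equal(f1, 0)
  expect_equal(f1Macro(1:4, 1:4), 1)
  expect_equal(f1Macro(c(1, 2, 1, 2), c(1, 1, 2, 2)), 0.5)
})

test_that("metrics agree exactly with the confusion-matrix oracle", {
  set.seed(8)
  for (i in 1:100) {
    k <- sample(2:4, 1)
    n <- sample(5:60, 1)
    truth <- sample.int(k, n, replace = TRUE)
    pred <- sample.int(k, n, replace = TRUE)
    o <- confusionOracle(pred, truth, 1:k)
    expect_identical(accuracy(pred, truth), o$accuracy)
    expect_identical(suppressWarnings(f1Macro(pred, truth, 1:k)), o$f1Macro)
  }
})

test_that("uniform random prediction converges to 1/K accuracy", {
  set.seed(9)
  truth <- rep(1:3, length.out = 1e5)
  pred <- sample.int(3L, 1e5, replace = TRUE)
  expect_lt(abs(accuracy(pred, truth) - 1 / 3), 0.01)
  expect_lt(abs(f1Macro(pred, truth, 1:3) - 1 / 3), 0.01)
})

test_that("valence/arousal labels binarize at the threshold", {
  expect_equal(makeVALabels(7, 3), 2L)  # high V, low A
  expect_equal(makeVALabels(2, 2), 0L)  # low V, low A
  expect_equal(makeVALabels(5, 5), 3L)  # boundary counts as high
  expect_equal(makeVALabels(c(0, 10, 4.9), c(10, 0, 5.1)), c(1L, 2L, 1L))
  expect_error(makeVALabels(11, 3), "0, 10")
})

test_that("fold assignment groups trials, stratifies classes, and is audited", {
  labels <- rep(rep(1:3, each = 4), each = 10)   # 12 trials x 10 windows
  trial <- rep(1:12, each = 10)
  trialIds <- unique(trial)
  trialClasses <- vapply(trialIds, function(tr) labels[trial == tr][1], 1L)
  folds <- ssleeg:::assignTrialFolds(trialIds, trialClasses, 4L, seed = 1L)
  expect_equal(sort(unique(folds)), 1:4)
  for (f in 1:4) expect_equal(sort(trialClasses[folds == f]), 1:3)
  # no trial's windows may straddle folds: assignment is per trial by
  # construction, and the evaluator maps windows through their trial id
  expect_length(folds, 12L)
})

test_that("a cheating oracle scores 100% and label permutation chance-level", {
  labels <- rep(rep(1:3, each = 4), each = 50)
  trial <- rep(1:12, each = 50)
  oneHot <- diag(3)[labels, ]
  rep1 <- crossvalEvaluate(oneHot, labels, trial, nFolds = 4L, seed = 2L)
  expect_equal(rep1@foldAccuracy, rep(100, 4))
  # permuted labels on informative features: chance for 3 balanced classes
  set.seed(3)
  x <- oneHot + matrix(rnorm(length(oneHot), sd = 0.2), ncol = 3)
  perm <- permuteLabels(labels, seed = 4L)
  rep2 <- crossvalEvaluate(x, perm, trial, nFolds = 4L, seed = 2L)
  expect_lt(abs(mean(rep2@foldAccuracy) - 100 / 3), 5)
  expect_identical(permuteLabels(labels, seed = 4L), perm)
})

test_that("evaluation refuses folds that lose a class", {
  labels <- rep(c(1, 1, 1, 1, 2), each = 10)  # class 2 has one trial
  trial <- rep(1:5, each = 10)
  expect_error(
    crossvalEvaluate(matrix(rnorm(100), 50, 2), labels, trial, nFolds = 2L),
    "missing a class")
})

test_that("the random baseline hits chance and fine-tuning learns", {
  labels <- rep(rep(1:3, each = 4), each = 30)
  trial <- rep(1:12, each = 30)
  x <- diag(3)[labels, ] * 2 + matrix(rnorm(360 * 3, sd = 0.5), ncol = 3)
  rnd <- crossvalEvaluate(x, labels, trial, method = "random", nFolds = 4L,
                          seed = 5L)
  expect_lt(abs(mean(rnd@foldAccuracy) - 100 / 3), 10)
  enc <- initEncoder(3L, 4L, 3L, seed = 6L)
  ft <- crossvalEvaluate(x, labels, trial, method = "finetune",
                         encoder = enc, nFolds = 4L, seed = 5L)
  expect_gt(mean(ft@foldAccuracy), 80)
})

test_that("label fraction subsamples the probe's training labels only", {
  labels <- rep(rep(1:3, each = 4), each = 30)
  trial <- rep(1:12, each = 30)
  x <- diag(3)[labels, ] * 3 + matrix(rnorm(360 * 3, sd = 0.3), ncol = 3)
  r <- crossvalEvaluate(x, labels, trial, nFolds = 4L, labelFraction = 0.1,
                        seed = 7L)
  expect_gt(mean(r@foldAccuracy), 90)  # easy task survives 10% labels
  expect_equal(r@labelFraction, 0.1)
})

test_that("Wilcoxon comparison matches a hand-ranked oracle", {
  expect_error(wilcoxonCompare(1:5, 1:5), "degenerate")
  a <- c(60, 62, 58, 65, 61, 63, 59, 64, 66, 57)
  w <- wilcoxonCompare(a, a - 2)  # constant positive shift
  expect_equal(w$statistic, 55)   # every rank is positive: V = n(n+1)/2
  expect_lt(w$pValue, 0.05)
  # hand-ranked example: diffs 1, -2, 3, -4, 5, 6 -> |d| ranks 1..6,
  # positive ranks {1, 3, 5, 6} sum to V = 15
  b <- c(11, 10, 13, 8, 15, 16); d <- c(10, 12, 10, 12, 10, 10)
  w2 <- wilcox.test(b, d, paired = TRUE)
  expect_equal(wilcoxonCompare(b, d)$statistic, 15)
  expect_equal(wilcoxonCompare(b, d)$statistic, unname(w2$statistic))
  expect_equal(wilcoxonCompare(b, d)$pValue, w2$p.value)
})

test_that("pairwise comparison reports Bonferroni-adjusted p-values", {
  mk <- function(name, acc) new("EvalReport", method = name,
    foldAccuracy = acc, foldF1 = acc, nFolds = length(acc),
    labelFraction = 1, seed = 1L, fingerprint = "x")
  set.seed(10)
  base <- runif(10, 50, 60)
  reports <- list(mk("a", base + 5 + runif(10)), mk("b", base),
                  mk("c", base - 5 - runif(10)))
  cmp <- compareMethods(reports)
  expect_equal(nrow(cmp), 3L)
  expect_equal(cmp$pAdjusted, pmin(1, cmp$pValue * 3))
})
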