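# Downstream emotion-classification evaluation: transfer metrics (accuracy,
# per-class and macro F1), DEAP-style valence/arousal label construction,
# trial-grouped stratified 10-fold cross-validation with a linear probe, and
# Wilcoxon pairwise method comparison with Bonferroni correction.

#' Classification accuracy
#'
#' Fraction of predictions equal to the true labels; for binary confusion
#' counts this is (TP + TN) / (TP + TN + FP + FN).
#'
#' @param pred,truth equal-length label vectors.
#' @return accuracy as a fraction in [0, 1].
#' @export
accuracy <- function(pred, truth) {
  stopIfNot(length(pred) == length(truth) && length(pred) >= 1L,
            "pred and truth must be equal-length and nonempty")
  mean(pred == truth)
}

#' Per-class F1 score
#'
#' F1 = 2 TP / (2 TP + FP + FN), the harmonic mean of precision and recall
#' for class `cls`. When the class appears in neither `pred` nor `truth` the
#' score is 0/0; it is defined as 0 here (and flagged with a warning) so that
#' macro averages stay well defined.
#'
#' @param pred,truth equal-length label vectors.
#' @param cls the class to score.
#' @return F1 in [0, 1].
#' @export
f1PerClass <- function(pred, truth, cls) {
  stopIfNot(length(pred) == length(truth) && length(pred) >= 1L,
            "pred and truth must be equal-length and nonempty")
  tp <- sum(pred == cls & truth == cls)
  fp <- sum(pred == cls & truth != cls)
  fn <- sum(pred != cls & truth == cls)
  if (2 * tp + fp + fn == 0) {
    warning(sprintf("class %s absent from pred and truth; F1 set to 0", cls))
    return(0)
  }
  2 * tp / (2 * tp + fp + fn)
}

#' Macro F1 score
#'
#' Unweighted mean of per-class F1 over all `classes` (every class counts,
#' present in the data or not).
#'
#' @param pred,truth equal-length label vectors.
#' @param classes vector of all class labels (default: union observed).
#' @return macro F1 in [0, 1].
#' @export
f1Macro <- function(pred, truth, classes = sort(unique(c(pred, truth)))) {
  stopIfNot(length(classes) >= 2L, "need at least 2 classes")
  mean(vapply(classes, function(k)
    suppressWarnings(f1PerClass(pred, truth, k)), numeric(1)))
}

#' Four-class labels from valence/arousal ratings
#'
#' Binarizes each dimension at `threshold` (>= threshold counts as high) and
#' combines them as class = 2 * highValence + highArousal, giving 0 =
#' low-V/low-A, 1 = low-V/high-A, 2 = high-V/low-A, 3 = high-V/high-A.
#'
#' @param valence,arousal ratings in [0, 10].
#' @param threshold binarization threshold (default 5).
#' @return integer class labels in {0, 1, 2, 3}.
#' @export
makeVALabels <- function(valence, arousal, threshold = 5) {
  stopIfNot(all(valence >= 0 & valence <= 10) &&
            all(arousal >= 0 & arousal <= 10),
            "ratings must lie in [0, 10]")
  as.integer(2L * (valence >= threshold) + (arousal >= threshold))
}

# Stratified trial-level fold assignment: trials of each class are shuffled
# under the seed and dealt round-robin, so every fold's training set keeps
# all classes whenever trials allow it.
assignTrialFolds <- function(trialIds, trialClasses, nFolds, seed) {
  folds <- integer(length(trialIds))
  withSeed(seed, {
    for (k in unique(trialClasses)) {
      idx <- which(trialClasses == k)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(nFolds), length(idx))
    }
  })
  folds
}

#' Cross-validated downstream evaluation
#'
#' Trial-grouped, class-stratified k-fold cross-validation: all windows of a
#' trial land in the same fold (window-level splitting would leak
#' within-trial autocorrelation into the test folds). Per fold, a classifier
#' is fitted on (a fraction of) the training windows and scored on every
#' test window.
#'
#' Methods: `"probe"` fits a multinomial logistic head on frozen features
#' (pass embeddings, or raw features, as `x`); `"finetune"` additionally
#' unfreezes a supplied encoder and trains it with the softmax head;
#' `"random"` ignores `x` and predicts uniformly at random (the chance
#' baseline).
#'
#' @param x nWindows x p feature/embedding matrix.
#' @param labels class label per window (constant within trial).
#' @param trial integer trial index per window.
#' @param method "probe", "finetune" or "random".
#' @param encoder optional [Encoder-class]: features are encoded before
#'   probing ("probe" freezes it; "finetune" trains a copy per fold).
#' @param nFolds number of folds (default 10).
#' @param labelFraction fraction of training windows whose labels the
#'   classifier may use (seeded subsample; at least one window per class).
#' @param seed evaluation seed.
#' @param methodName name recorded in the report.
#' @param scale standardize features using training-fold statistics.
#' @return an [EvalReport-class] with per-fold accuracy and macro F1 (%).
#' @export
crossvalEvaluate <- function(x, labels, trial, method = c("probe", "finetune",
                                                          "random"),
                             encoder = NULL, nFolds = 10L, labelFraction = 1,
                             seed = 1L, methodName = NULL, scale = TRUE) {
  method <- match.arg(method)
  stopIfNot(nFolds >= 2L, "nFolds must be >= 2")
  stopIfNot(length(labels) == length(trial), "labels/trial length mismatch")
  if (!is.matrix(x)) x <- as.matrix(x)
  classes <- sort(unique(labels))
  trialIds <- unique(trial)
  stopIfNot(length(trialIds) >= nFolds, "need at least nFolds trials")
  trialClasses <- vapply(trialIds, function(tr) labels[trial == tr][1],
                         labels[1])
  folds <- assignTrialFolds(trialIds, trialClasses, nFolds, seed)

  accs <- f1s <- numeric(nFolds)
  for (f in seq_len(nFolds)) {
    testTrials <- trialIds[folds == f]
    testRows <- which(trial %in% testTrials)
    trainRows <- which(!(trial %in% testTrials))
    if (!all(classes %in% labels[trainRows]))
      stop(sprintf("fold %d training set is missing a class; ", f),
           "use more trials per class", call. = FALSE)

    if (method == "random") {
      pred <- withSeed(deriveSeed(seed, 23L, f),
                       sample(classes, length(testRows), replace = TRUE))
    } else {
      xtr <- x[trainRows, , drop = FALSE]
      xte <- x[testRows, , drop = FALSE]
      if (method == "probe" && !is.null(encoder)) {
        xtr <- encode(encoder, xtr)
        xte <- encode(encoder, xte)
      }
      if (labelFraction < 1) {
        keep <- withSeed(deriveSeed(seed, 29L, f), {
          k <- unlist(lapply(classes, function(cl) {
            rows <- which(labels[trainRows] == cl)
            nKeep <- max(1L, round(labelFraction * length(rows)))
            rows[sample.int(length(rows), nKeep)]
          }))
          sort(k)
        })
        xtr <- xtr[keep, , drop = FALSE]
        ytr <- labels[trainRows][keep]
      } else {
        ytr <- labels[trainRows]
      }
      if (scale) {
        mu <- colMeans(xtr)
        sg <- apply(xtr, 2L, sd)
        sg[sg == 0 | !is.finite(sg)] <- 1
        xtr <- sweep(sweep(xtr, 2L, mu), 2L, sg, "/")
        xte <- sweep(sweep(xte, 2L, mu), 2L, sg, "/")
      }
      if (method == "finetune") {
        stopIfNot(!is.null(encoder), "finetune requires an encoder")
        ft <- trainSupervised(encoder, xtr, ytr, classes,
                              seed = deriveSeed(seed, 31L, f))
        pred <- predictSupervised(ft, xte, classes)
      } else {
        fit <- fitMultinomProbe(xtr, ytr, classes)
        pred <- predictMultinomProbe(fit, xte, classes)
      }
    }
    accs[f] <- 100 * accuracy(pred, labels[testRows])
    f1s[f] <- 100 * f1Macro(pred, labels[testRows], classes)
  }
  if (is.null(methodName)) methodName <- method
  new("EvalReport", method = methodName, foldAccuracy = accs, foldF1 = f1s,
      nFolds = as.integer(nFolds), labelFraction = labelFraction,
      seed = as.integer(seed),
      fingerprint = objectFingerprint(list(method, nFolds, labelFraction,
                                           seed, dim(x))))
}

fitMultinomProbe <- function(x, y, classes) {
  df <- data.frame(y = factor(y, levels = classes), x)
  nw <- (ncol(x) + 1L) * length(classes) + 10L
  fit <- nnet::multinom(y ~ ., data = df, trace = FALSE, maxit = 300L,
                        MaxNWts = max(nw, 1000L), decay = 1e-4)
  fit
}

predictMultinomProbe <- function(fit, x, classes) {
  p <- predict(fit, newdata = data.frame(x), type = "class")
  cls <- classes[match(as.character(p), as.character(classes))]
  cls
}

# Fine-tuning: unfreeze the encoder and train it with a softmax head by
# full-batch Adam on the cross-entropy.
trainSupervised <- function(encoder, x, y, classes, epochs = 60L, lr = 5e-3,
                            seed = 1L) {
  k <- length(classes)
  yIdx <- match(y, classes)
  weights <- encoder@weights
  d <- encoder@embeddingDim
  Wh <- withSeed(seed, matrix(rnorm(k * d, sd = 1 / sqrt(d)), k, d))
  bh <- numeric(k)
  flat <- function() c(unlist(lapply(weights, function(l) list(l$W, l$b)),
                              recursive = FALSE), list(Wh, bh))
  opt <- adamInit(flat())
  n <- nrow(x)
  for (epoch in seq_len(epochs)) {
    acts <- mlpForward(weights, x)
    z <- acts[[length(weights) + 1L]]
    logits <- sweep(z %*% t(Wh), 2L, bh, "+")
    lse <- logSumExpRows(logits)
    p <- exp(logits - lse)
    dlog <- p
    dlog[cbind(seq_len(n), yIdx)] <- dlog[cbind(seq_len(n), yIdx)] - 1
    dlog <- dlog / n
    dWh <- t(dlog) %*% z
    dbh <- colSums(dlog)
    dZ <- dlog %*% Wh
    bk <- mlpBackward(weights, acts, dZ)
    grads <- c(unlist(lapply(bk$grads, function(g) list(g$W, g$b)),
                      recursive = FALSE), list(dWh, dbh))
    st <- adamStep(flat(), grads, opt, lr = lr)
    opt <- st$state
    pp <- st$params
    j <- 1L
    for (l in seq_along(weights)) {
      weights[[l]]$W <- pp[[j]]; weights[[l]]$b <- pp[[j + 1L]]
      j <- j + 2L
    }
    Wh <- pp[[j]]; bh <- pp[[j + 1L]]
  }
  list(weights = weights, Wh = Wh, bh = bh)
}

predictSupervised <- function(fit, x, classes) {
  z <- mlpForward(fit$weights, x)[[length(fit$weights) + 1L]]
  logits <- sweep(z %*% t(fit$Wh), 2L, fit$bh, "+")
  classes[max.col(logits, ties.method = "first")]
}

#' Permute window labels for a permutation-null evaluation
#'
#' Shuffles labels across windows (seeded), destroying any label-feature
#' association while leaving the fold geometry intact. Fold grouping and
#' stratification still use the original trial labels, so the evaluation
#' runs under identical geometry to the real one.
#'
#' @param labels label vector.
#' @param seed permutation seed.
#' @return permuted label vector.
#' @export
permuteLabels <- function(labels, seed = 1L) {
  withSeed(seed, labels[sample.int(length(labels))])
}

#' Wilcoxon signed-rank comparison of two methods
#'
#' Two-sided paired signed-rank test on per-fold scores. Errors when every
#' paired difference is zero (the test is degenerate there).
#'
#' @param scoresA,scoresB equal-length per-fold scores (length >= 5).
#' @return list with `statistic` (V, the positive-rank sum) and `pValue`.
#' @export
wilcoxonCompare <- function(scoresA, scoresB) {
  stopIfNot(length(scoresA) == length(scoresB) && length(scoresA) >= 5L,
            "need equal-length score vectors of length >= 5")
  if (all(scoresA == scoresB))
    stop("degenerate comparison: all paired differences are zero",
         call. = FALSE)
  wt <- suppressWarnings(wilcox.test(scoresA, scoresB, paired = TRUE,
                                     alternative = "two.sided"))
  list(statistic = unname(wt$statistic), pValue = wt$p.value)
}

#' Pairwise Wilcoxon comparison across methods
#'
#' Runs [wilcoxonCompare()] on per-fold accuracies for every method pair and
#' reports Bonferroni-adjusted p-values alongside the raw ones. Degenerate
#' pairs (identical fold scores) get NA statistics rather than aborting the
#' whole table.
#'
#' @param reports list of [EvalReport-class] objects (same fold layout).
#' @param metric "accuracy" or "f1".
#' @return data.frame with columns methodA, methodB, statistic, pValue,
#'   pAdjusted.
#' @export
compareMethods <- function(reports, metric = c("accuracy", "f1")) {
  metric <- match.arg(metric)
  stopIfNot(length(reports) >= 2L, "need at least two reports")
  get <- function(r) if (metric == "accuracy") r@foldAccuracy else r@foldF1
  combs <- utils::combn(length(reports), 2L)
  out <- data.frame(methodA = character(0), methodB = character(0),
                    statistic = numeric(0), pValue = numeric(0))
  for (i in seq_len(ncol(combs))) {
    a <- reports[[combs[1, i]]]; b <- reports[[combs[2, i]]]
    w <- tryCatch(wilcoxonCompare(get(a), get(b)),
                  error = function(e) list(statistic = NA_real_,
                                           pValue = NA_real_))
    out <- rbind(out, data.frame(methodA = a@method, methodB = b@method,
                                 statistic = w$statistic,
                                 pValue = w$pValue))
  }
  out$pAdjusted <- p.adjust(out$pValue, method = "bonferroni")
  out
}
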