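# Relative Position (RP) and Temporal Shuffling (TS) pretext tasks.
#
# Both tasks manufacture binary pseudo-labels from window positions inside a
# trial. RP labels a pair (t, t') as +1 when |t - t'| <= tau_pos and -1 when
# |t - t'| > tau_neg; pairs in the dead zone between the two radii are never
# sampled. TS draws two anchor windows from the positive context and a third
# window either strictly between them (temporally ordered, +1) or from the
# negative context (shuffled, -1); the label is +1 iff t < t' < t''. Both
# heads combine encoder outputs through element-wise absolute differences
# and are trained with a logistic loss. Pairs and triples are always sampled
# within a single trial: adjacency across trial boundaries is physically
# meaningless.

#' Sampler configuration for RP and TS
#'
#' @param nSamples number N of pseudo-labeled samples to draw.
#' @param windowLength window length in samples, used only to express the
#'   default radii (12 windows positive, 60 windows negative).
#' @param tauPos positive-context radius in samples.
#' @param tauNeg negative-context radius in samples; must satisfy
#'   0 < tauPos <= tauNeg. Distances in (tauPos, tauNeg] form the dead zone.
#' @param seed RNG seed for sampling.
#' @return a list of class `rpSamplerConfig`.
#' @export
rpSamplerConfig <- function(nSamples = 1000L, windowLength = 200L,
                            tauPos = 12L * windowLength,
                            tauNeg = 60L * windowLength, seed = 1L) {
  stopIfNot(tauPos > 0 && tauPos <= tauNeg,
            "need 0 < tauPos <= tauNeg")
  stopIfNot(nSamples >= 2L, "need at least 2 samples")
  structure(list(nSamples = as.integer(nSamples),
                 tauPos = as.numeric(tauPos), tauNeg = as.numeric(tauNeg),
                 seed = as.integer(seed)),
            class = "rpSamplerConfig")
}

asStartsList <- function(starts) {
  if (!is.list(starts)) list(starts) else starts
}

#' Sample Relative Position pairs
#'
#' Draws `nSamples` window pairs, half positive (|t - t'| <= tauPos) and half
#' negative (|t - t'| > tauNeg), uniformly over the eligible within-trial
#' pairs. The dead zone tauPos < |t - t'| <= tauNeg is never emitted, and the
#' anchor never pairs with itself.
#'
#' @param starts valid window start samples: an integer vector (one trial) or
#'   a list of vectors (one per trial).
#' @param config an [rpSamplerConfig()].
#' @return data.frame with columns `trial`, `t`, `tPrime`, `y`.
#' @export
sampleRP <- function(starts, config) {
  sl <- asStartsList(starts)
  pos <- list(); neg <- list()
  for (tr in seq_along(sl)) {
    s <- sort(unique(as.numeric(sl[[tr]])))
    if (length(s) < 2L) next
    pr <- expand.grid(t = s, tPrime = s)
    d <- abs(pr$t - pr$tPrime)
    keepPos <- d > 0 & d <= config$tauPos
    keepNeg <- d > config$tauNeg
    if (any(keepPos))
      pos[[length(pos) + 1L]] <- cbind(trial = tr, pr[keepPos, ])
    if (any(keepNeg))
      neg[[length(neg) + 1L]] <- cbind(trial = tr, pr[keepNeg, ])
  }
  posAll <- if (length(pos)) do.call(rbind, pos) else NULL
  negAll <- if (length(neg)) do.call(rbind, neg) else NULL
  if (is.null(posAll))
    stop("positive RP class unrealizable: no pair with |t - t'| <= tauPos",
         call. = FALSE)
  if (is.null(negAll))
    stop("negative RP class unrealizable: no pair with |t - t'| > tauNeg ",
         "(trials shorter than tauNeg?)", call. = FALSE)
  nPos <- config$nSamples %/% 2L
  nNeg <- config$nSamples - nPos
  withSeed(config$seed, {
    ip <- sample.int(nrow(posAll), nPos, replace = TRUE)
    ineg <- sample.int(nrow(negAll), nNeg, replace = TRUE)
    out <- rbind(cbind(posAll[ip, ], y = 1),
                 cbind(negAll[ineg, ], y = -1))
    rownames(out) <- NULL
    out
  })
}

#' Sample Temporal Shuffling triples
#'
#' Anchors (t, t'') with 0 < t'' - t <= tauPos are drawn from the positive
#' context. For ordered triples (+1) the third window t' lies strictly
#' between the anchors; for shuffled triples (-1) it comes from the negative
#' context (farther than tauNeg from both anchors), so the stored order
#' (t, t', t'') violates t < t' < t''. Labels follow the ordering rule
#' exactly: y = +1 iff t < t' < t''.
#'
#' @inheritParams sampleRP
#' @return data.frame with columns `trial`, `t`, `tPrime`, `tDPrime`, `y`.
#' @export
sampleTS <- function(starts, config) {
  sl <- asStartsList(starts)
  pos <- list(); neg <- list()
  for (tr in seq_along(sl)) {
    s <- sort(unique(as.numeric(sl[[tr]])))
    if (length(s) < 3L) next
    anch <- expand.grid(t = s, tDPrime = s)
    anch <- anch[anch$tDPrime > anch$t &
                 anch$tDPrime - anch$t <= config$tauPos, ]
    for (i in seq_len(nrow(anch))) {
      t1 <- anch$t[i]; t3 <- anch$tDPrime[i]
      between <- s[s > t1 & s < t3]
      far <- s[pmin(abs(s - t1), abs(s - t3)) > config$tauNeg]
      if (length(between))
        pos[[length(pos) + 1L]] <-
          data.frame(trial = tr, t = t1, tPrime = between, tDPrime = t3)
      if (length(far))
        neg[[length(neg) + 1L]] <-
          data.frame(trial = tr, t = t1, tPrime = far, tDPrime = t3)
    }
  }
  posAll <- if (length(pos)) do.call(rbind, pos) else NULL
  negAll <- if (length(neg)) do.call(rbind, neg) else NULL
  if (is.null(posAll))
    stop("ordered TS class unrealizable: no start strictly between anchors",
         call. = FALSE)
  if (is.null(negAll))
    stop("shuffled TS class unrealizable: no start farther than tauNeg ",
         "from both anchors", call. = FALSE)
  nPos <- config$nSamples %/% 2L
  nNeg <- config$nSamples - nPos
  withSeed(config$seed, {
    ip <- sample.int(nrow(posAll), nPos, replace = TRUE)
    ineg <- sample.int(nrow(negAll), nNeg, replace = TRUE)
    out <- rbind(posAll[ip, ], negAll[ineg, ])
    out$y <- ifelse(out$t < out$tPrime & out$tPrime < out$tDPrime, 1, -1)
    rownames(out) <- NULL
    out
  })
}

#' Absolute-difference contrastive heads
#'
#' `gRP` combines two embeddings as the element-wise absolute difference
#' |h - h'| (symmetric in its arguments); `gTS` combines three embeddings as
#' the concatenation (|h - h'|, |h' - h''|), a vector of length 2D.
#'
#' @param h,hPrime,hDPrime embedding vectors of equal length D, or matrices
#'   with matching rows.
#' @return combined feature vector (or matrix), length D for `gRP`, 2D for
#'   `gTS`.
#' @export
gRP <- function(h, hPrime) {
  stopIfNot(length(h) == length(hPrime), "embedding length mismatch")
  abs(h - hPrime)
}

#' @rdname gRP
#' @export
gTS <- function(h, hPrime, hDPrime) {
  stopIfNot(length(h) == length(hPrime) &&
            length(hPrime) == length(hDPrime), "embedding length mismatch")
  if (is.matrix(h)) cbind(abs(h - hPrime), abs(hPrime - hDPrime))
  else c(abs(h - hPrime), abs(hPrime - hDPrime))
}

#' Logistic pretext loss
#'
#' The summed logistic loss sum_i log(1 + exp(-y_i (w' g_i + w0))) over
#' combined features, the training objective shared by RP and TS. Computed
#' via log1p for numerical stability.
#'
#' @param features n x F matrix of combined features.
#' @param y labels in {-1, +1}.
#' @param w,w0 linear head weights and intercept.
#' @return the summed loss (nonnegative; n log 2 at zero score).
#' @export
logisticLoss <- function(features, y, w, w0) {
  if (!is.matrix(features)) features <- matrix(features, nrow = 1L)
  stopIfNot(all(y %in% c(-1, 1)), "labels must be in {-1, +1}")
  stopIfNot(nrow(features) == length(y) && ncol(features) == length(w),
            "shape mismatch")
  score <- drop(features %*% w) + w0
  sum(log1p(exp(-abs(y * score))) + pmax(-y * score, 0))
}

# d(mean loss)/dscore for the logistic loss.
logisticScoreGrad <- function(score, y) {
  -y * stats::plogis(-y * score) / length(y)
}

# Map (trial, start) pairs to row indices of the window table.
windowIndexMap <- function(trial, start) {
  key <- paste(trial, start, sep = ":")
  stats::setNames(seq_along(key), key)
}

lookupWindows <- function(map, trial, start) {
  idx <- unname(map[paste(trial, start, sep = ":")])
  stopIfNot(!anyNA(idx), "sampled window start not present in the data")
  idx
}

#' Train the RP or TS pretext task
#'
#' Draws a fixed pseudo-labeled sample set, then optimizes the shared
#' encoder and the linear logistic head jointly by full-batch Adam. The
#' reported history is the mean per-sample logistic loss on that fixed set,
#' evaluated at the start of each epoch and once more after the final update.
#'
#' @param x nWindows x F matrix of window representations (e.g. flattened DE
#'   features from [assembleFeatures()]).
#' @param trial integer trial index per window.
#' @param starts window start sample per window (within its trial).
#' @param encoder an [Encoder-class] (its input dim must match `x`).
#' @param sampler an [rpSamplerConfig()].
#' @param epochs,lr,weightDecay optimizer settings.
#' @return an [SSLModel-class] with task "rp" or "ts".
#' @export
trainRP <- function(x, trial, starts, encoder = NULL,
                    sampler = rpSamplerConfig(), epochs = 30L, lr = 0.01,
                    weightDecay = 1e-4) {
  trainPairTask(x, trial, starts, encoder, sampler, epochs, lr, weightDecay,
                task = "rp")
}

#' @rdname trainRP
#' @export
trainTS <- function(x, trial, starts, encoder = NULL,
                    sampler = rpSamplerConfig(), epochs = 30L, lr = 0.01,
                    weightDecay = 1e-4) {
  trainPairTask(x, trial, starts, encoder, sampler, epochs, lr, weightDecay,
                task = "ts")
}

trainPairTask <- function(x, trial, starts, encoder, sampler, epochs, lr,
                          weightDecay, task) {
  if (is.null(encoder))
    encoder <- initEncoder(ncol(x), seed = sampler$seed)
  uids <- sort(unique(trial))
  startsList <- unname(split(starts, trial))
  samples <- if (task == "rp") sampleRP(startsList, sampler)
             else sampleTS(startsList, sampler)
  samples$trial <- uids[samples$trial]
  map <- windowIndexMap(trial, starts)
  i1 <- lookupWindows(map, samples$trial, samples$t)
  i2 <- lookupWindows(map, samples$trial, samples$tPrime)
  i3 <- if (task == "ts") lookupWindows(map, samples$trial, samples$tDPrime)
        else NULL
  y <- samples$y
  n <- length(y)
  d <- encoder@embeddingDim
  fdim <- if (task == "ts") 2L * d else d

  weights <- encoder@weights
  w <- withSeed(deriveSeed(sampler$seed, 7L),
                rnorm(fdim, sd = 1 / sqrt(fdim)))
  w0 <- 0
  flat <- function() c(unlist(lapply(weights, function(l) list(l$W, l$b)),
                              recursive = FALSE), list(w), list(w0))
  opt <- adamInit(flat())
  history <- numeric(0)

  for (epoch in seq_len(epochs + 1L)) {
    acts <- mlpForward(weights, x)
    z <- acts[[length(weights) + 1L]]
    h1 <- z[i1, , drop = FALSE]; h2 <- z[i2, , drop = FALSE]
    if (task == "ts") {
      h3 <- z[i3, , drop = FALSE]
      g <- cbind(abs(h1 - h2), abs(h2 - h3))
    } else {
      g <- abs(h1 - h2)
    }
    score <- drop(g %*% w) + w0
    history <- c(history, mean(log1p(exp(-abs(y * score))) +
                               pmax(-y * score, 0)))
    if (epoch > epochs) break

    ds <- logisticScoreGrad(score, y)
    dw <- drop(crossprod(g, ds)) + weightDecay * w
    dw0 <- sum(ds)
    dg <- outer(ds, w)
    dZ <- z * 0
    if (task == "ts") {
      s12 <- sign(h1 - h2); s23 <- sign(h2 - h3)
      d12 <- dg[, seq_len(d), drop = FALSE] * s12
      d23 <- dg[, d + seq_len(d), drop = FALSE] * s23
      dZ <- addRows(dZ, i1, d12)
      dZ <- addRows(dZ, i2, -d12 + d23)
      dZ <- addRows(dZ, i3, -d23)
    } else {
      s12 <- sign(h1 - h2)
      d12 <- dg * s12
      dZ <- addRows(dZ, i1, d12)
      dZ <- addRows(dZ, i2, -d12)
    }
    bk <- mlpBackward(weights, acts, dZ)
    grads <- lapply(seq_along(weights), function(l)
      list(bk$grads[[l]]$W + weightDecay * weights[[l]]$W,
           bk$grads[[l]]$b))
    gflat <- c(unlist(grads, recursive = FALSE), list(dw), list(dw0))
    st <- adamStep(flat(), gflat, opt, lr = lr)
    opt <- st$state
    p <- st$params
    j <- 1L
    for (l in seq_along(weights)) {
      weights[[l]]$W <- p[[j]]; weights[[l]]$b <- p[[j + 1L]]
      j <- j + 2L
    }
    w <- p[[j]]; w0 <- p[[j + 1L]]
  }

  enc <- encoder
  enc@weights <- weights
  new("SSLModel", task = task, encoder = enc, context = NULL,
      head = list(w = w, w0 = w0),
      history = data.frame(epoch = seq_along(history) - 1L, loss = history),
      config = list(sampler = unclass(sampler), epochs = epochs, lr = lr,
                    weightDecay = weightDecay))
}

#' Held-out pretext accuracy for an RP/TS model
#'
#' Draws a fresh pseudo-labeled sample set (use a different sampler seed than
#' training) and reports the fraction classified correctly by the trained
#' head.
#'
#' @inheritParams trainRP
#' @param model a trained [SSLModel-class] with task "rp" or "ts".
#' @return accuracy as a fraction.
#' @export
pretextAccuracy <- function(model, x, trial, starts,
                            sampler = rpSamplerConfig()) {
  stopIfNot(model@task %in% c("rp", "ts"), "model must be an RP or TS model")
  uids <- sort(unique(trial))
  startsList <- unname(split(starts, trial))
  samples <- if (model@task == "rp") sampleRP(startsList, sampler)
             else sampleTS(startsList, sampler)
  samples$trial <- uids[samples$trial]
  map <- windowIndexMap(trial, starts)
  z <- encode(model@encoder, x)
  h1 <- z[lookupWindows(map, samples$trial, samples$t), , drop = FALSE]
  h2 <- z[lookupWindows(map, samples$trial, samples$tPrime), , drop = FALSE]
  g <- if (model@task == "ts") {
    h3 <- z[lookupWindows(map, samples$trial, samples$tDPrime), ,
            drop = FALSE]
    cbind(abs(h1 - h2), abs(h2 - h3))
  } else abs(h1 - h2)
  score <- drop(g %*% model@head$w) + model@head$w0
  mean(sign(score) == samples$y)
}
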