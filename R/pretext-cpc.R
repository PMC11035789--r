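# Contrastive Predictive Coding.
#
# The encoder g_enc maps each window to z_t; the causal model g_ar summarizes
# z_{<=t} into a context c_t; a per-step log-bilinear score
# f_k(z, c) = exp(z' W_k c) rates how well a candidate window matches the
# context k steps back. Training minimizes InfoNCE: the mean categorical
# cross-entropy of identifying the true future z_{t+k} among N candidates
# (one positive, N-1 negatives drawn from anywhere in the dataset). All
# score arithmetic is done in log space (log-sum-exp), so exp(z' W_k c)
# never overflows.

#' CPC training configuration
#'
#' @param predictionSteps number of future steps K predicted from each
#'   context; each step has its own bilinear matrix W_k.
#' @param negatives negatives per positive (contrast-set size N is
#'   negatives + 1).
#' @param contextLength windows of history fed to the causal model before a
#'   context is used for prediction.
#' @param epochs,lr,weightDecay optimizer settings (full-batch Adam).
#' @param seed RNG seed (initialization and negative sampling).
#' @return a list of class `cpcConfig`.
#' @export
cpcConfig <- function(predictionSteps = 4L, negatives = 7L,
                      contextLength = 16L, epochs = 30L, lr = 5e-3,
                      weightDecay = 1e-4, seed = 1L) {
  stopIfNot(predictionSteps >= 1L, "predictionSteps must be >= 1")
  stopIfNot(negatives >= 1L, "need at least one negative")
  stopIfNot(contextLength >= 1L, "contextLength must be >= 1")
  structure(list(predictionSteps = as.integer(predictionSteps),
                 negatives = as.integer(negatives),
                 contextLength = as.integer(contextLength),
                 epochs = as.integer(epochs), lr = lr,
                 weightDecay = weightDecay, seed = as.integer(seed)),
            class = "cpcConfig")
}

#' Log-bilinear score f_k
#'
#' f_k(z, c) = exp(z' W_k c). The log-score is bilinear in (z, c); use
#' `log = TRUE` to obtain it directly and avoid overflow.
#'
#' @param z embedding vector (length D).
#' @param cT context vector.
#' @param Wk D x contextDim bilinear matrix.
#' @param log return the log-score instead of the score.
#' @return a positive scalar (or its log).
#' @export
scoreFk <- function(z, cT, Wk, log = FALSE) {
  stopIfNot(length(z) == nrow(Wk) && length(cT) == ncol(Wk),
            "shape mismatch between z, W_k and c")
  ls <- drop(crossprod(z, Wk %*% cT))
  if (log) ls else exp(ls)
}

#' Assemble a CPC contrast batch from an index plan
#'
#' @param plan one row set from [makeCPCBatches()].
#' @param zAll nWindows x D embedding matrix for the whole dataset.
#' @param cAnchors m x contextDim context vectors aligned with `plan` rows.
#' @return a CPC batch: list with `cT`, `zPos`, `zNeg` (m x negatives x D
#'   array) and `k`.
#' @export
buildCPCBatch <- function(plan, zAll, cAnchors) {
  negIdx <- as.matrix(plan[, grep("^neg", names(plan)), drop = FALSE])
  m <- nrow(plan)
  zNeg <- array(0, dim = c(m, ncol(negIdx), ncol(zAll)))
  for (j in seq_len(ncol(negIdx)))
    zNeg[, j, ] <- zAll[negIdx[, j], , drop = FALSE]
  list(cT = cAnchors, zPos = zAll[plan$pos, , drop = FALSE],
       zNeg = zNeg, k = plan$k)
}

#' InfoNCE loss of a CPC batch
#'
#' Mean categorical cross-entropy of picking the positive among the N
#' candidates, computed in log space. Equals ln N exactly when all candidate
#' scores are equal, and 0 when each entry has no negatives.
#'
#' @param batch a batch from [buildCPCBatch()] (fields `cT`, `zPos`, `zNeg`,
#'   `k`).
#' @param scorer list of W_k matrices indexed by step k.
#' @return nonnegative scalar loss in nats.
#' @export
infonceLoss <- function(batch, scorer) {
  m <- nrow(batch$cT)
  stopIfNot(m >= 1L, "empty batch")
  nNeg <- if (length(dim(batch$zNeg)) == 3L) dim(batch$zNeg)[2] else 0L
  total <- 0
  for (k in sort(unique(batch$k))) {
    rows <- which(batch$k == k)
    Wk <- scorer[[k]]
    q <- batch$cT[rows, , drop = FALSE] %*% t(Wk)     # rows x D
    logits <- matrix(0, length(rows), nNeg + 1L)
    logits[, 1L] <- rowSums(q * batch$zPos[rows, , drop = FALSE])
    if (nNeg > 0L)
      for (j in seq_len(nNeg))
        logits[, j + 1L] <- rowSums(q * batch$zNeg[rows, j, ])
    total <- total + sum(logSumExpRows(logits) - logits[, 1L])
  }
  total / m
}

#' Enumerate CPC training samples and draw negatives
#'
#' Windows are taken in temporal order within each trial. Anchors are the
#' positions t with a full context behind them and K future steps ahead:
#' t in [contextLength, L - K] (1-based within-trial position). Every valid
#' (t, k) pair is used exactly once; its positive is the window at t + k and
#' its negatives are drawn uniformly from all other windows of the dataset
#' (any trial), excluding the positive itself.
#'
#' @param trial integer trial index per window, windows ordered in time
#'   within each trial.
#' @param config a [cpcConfig()].
#' @param seed seed for negative sampling (default: config seed).
#' @return data.frame with columns `trial`, `t`, `k`, `pos` (global window
#'   row of the positive) and `neg1..negJ` (global rows of the negatives).
#' @export
makeCPCBatches <- function(trial, config, seed = config$seed) {
  n <- length(trial)
  offsets <- c(0L, cumsum(rle(trial)$lengths))
  lens <- rle(trial)$lengths
  ids <- rle(trial)$values
  plans <- list()
  for (g in seq_along(ids)) {
    l <- lens[g]
    tMax <- l - config$predictionSteps
    if (tMax < config$contextLength)
      stop(sprintf(
        "trial %s too short: need >= %d windows (context %d + %d steps)",
        ids[g], config$contextLength + config$predictionSteps,
        config$contextLength, config$predictionSteps), call. = FALSE)
    anchors <- seq.int(config$contextLength, tMax)
    grid <- expand.grid(t = anchors, k = seq_len(config$predictionSteps))
    grid$trial <- ids[g]
    grid$pos <- offsets[g] + grid$t + grid$k
    plans[[g]] <- grid[, c("trial", "t", "k", "pos")]
  }
  plan <- do.call(rbind, plans)
  m <- nrow(plan)
  neg <- withSeed(seed, {
    draw <- matrix(sample.int(n - 1L, m * config$negatives, replace = TRUE),
                   m, config$negatives)
    draw + (draw >= plan$pos)  # shift over the excluded positive
  })
  colnames(neg) <- paste0("neg", seq_len(config$negatives))
  cbind(plan, neg)
}

#' Train a CPC model
#'
#' Joint full-batch Adam over the encoder, the causal context model and the
#' per-step bilinear matrices, minimizing InfoNCE. Negatives are redrawn
#' each epoch from a seeded stream, so the whole run is reproducible. The
#' history records the loss at the parameters each epoch started with, plus
#' one final evaluation after the last update.
#'
#' @param x nWindows x F matrix of window representations, ordered in time
#'   within each trial.
#' @param trial integer trial index per window.
#' @param encoder an [Encoder-class] (default: new encoder seeded from the
#'   config).
#' @param context a [ContextModel-class] (default: context dim = embedding
#'   dim).
#' @param config a [cpcConfig()].
#' @return an [SSLModel-class] with task "cpc"; the head holds the W_k list.
#' @export
trainCPC <- function(x, trial, encoder = NULL, context = NULL,
                     config = cpcConfig()) {
  stopIfNot(nrow(x) == length(trial), "x / trial length mismatch")
  if (is.null(encoder))
    encoder <- initEncoder(ncol(x), seed = config$seed)
  d <- encoder@embeddingDim
  if (is.null(context))
    context <- initContextModel(d, d, seed = deriveSeed(config$seed, 11L))
  dc <- nrow(context@U)
  K <- config$predictionSteps
  Wk <- withSeed(deriveSeed(config$seed, 13L),
                 lapply(seq_len(K), function(k)
                   matrix(rnorm(d * dc, sd = 1 / sqrt(dc)), d, dc)))
  weights <- encoder@weights
  rnn <- list(U = context@U, V = context@V, b = context@b)

  flat <- function() c(unlist(lapply(weights, function(l) list(l$W, l$b)),
                              recursive = FALSE),
                       list(rnn$U, rnn$V, rnn$b), Wk)
  opt <- adamInit(flat())
  history <- numeric(0)
  trialRows <- split(seq_along(trial), trial)
  names(trialRows) <- NULL

  for (epoch in seq_len(config$epochs + 1L)) {
    plan <- makeCPCBatches(trial, config,
                           seed = deriveSeed(config$seed, 17L, epoch))
    acts <- mlpForward(weights, x)
    zAll <- acts[[length(weights) + 1L]]
    m <- nrow(plan)

    dZ <- zAll * 0
    dU <- rnn$U * 0; dV <- rnn$V * 0; db <- rnn$b * 0
    dWk <- lapply(Wk, function(w) w * 0)
    totalLoss <- 0

    for (g in seq_along(trialRows)) {
      rows <- trialRows[[g]]
      zT <- zAll[rows, , drop = FALSE]
      cseq <- rnnForward(rnn, zT)
      prows <- which(plan$trial == trial[rows[1]])
      sub <- plan[prows, , drop = FALSE]
      dC <- cseq * 0
      for (k in seq_len(K)) {
        sk <- sub[sub$k == k, , drop = FALSE]
        if (!nrow(sk)) next
        anchors <- sk$t
        cA <- cseq[anchors, , drop = FALSE]
        q <- cA %*% t(Wk[[k]])                       # mk x D
        negIdx <- as.matrix(sk[, grep("^neg", names(sk)), drop = FALSE])
        nNeg <- ncol(negIdx)
        logits <- matrix(0, nrow(sk), nNeg + 1L)
        logits[, 1L] <- rowSums(q * zAll[sk$pos, , drop = FALSE])
        for (j in seq_len(nNeg))
          logits[, j + 1L] <- rowSums(q * zAll[negIdx[, j], , drop = FALSE])
        lse <- logSumExpRows(logits)
        totalLoss <- totalLoss + sum(lse - logits[, 1L])
        if (epoch > config$epochs) next

        p <- exp(logits - lse)
        p[, 1L] <- p[, 1L] - 1                        # dloss/dlogit
        # accumulate into z, W_k, c
        dQ <- p[, 1L] * zAll[sk$pos, , drop = FALSE]
        dZ <- addRows(dZ, sk$pos, p[, 1L] * q)
        for (j in seq_len(nNeg)) {
          dQ <- dQ + p[, j + 1L] * zAll[negIdx[, j], , drop = FALSE]
          dZ <- addRows(dZ, negIdx[, j], p[, j + 1L] * q)
        }
        dWk[[k]] <- dWk[[k]] + crossprod(dQ, cA)
        dC <- addRows(dC, anchors, dQ %*% Wk[[k]])
      }
      if (epoch <= config$epochs) {
        bk <- rnnBackward(rnn, zT, cseq, dC)
        dU <- dU + bk$dU; dV <- dV + bk$dV; db <- db + bk$db
        dZ[rows, ] <- dZ[rows, , drop = FALSE] + bk$dZ
      }
    }

    history <- c(history, totalLoss / m)
    if (epoch > config$epochs) break

    bk <- mlpBackward(weights, acts, dZ / m)
    encGrads <- lapply(seq_along(weights), function(l)
      list(bk$grads[[l]]$W + config$weightDecay * weights[[l]]$W,
           bk$grads[[l]]$b))
    gflat <- c(unlist(encGrads, recursive = FALSE),
               list(dU / m + config$weightDecay * rnn$U,
                    dV / m + config$weightDecay * rnn$V, db / m),
               lapply(seq_len(K), function(k)
                 dWk[[k]] / m + config$weightDecay * Wk[[k]]))
    st <- adamStep(flat(), gflat, opt, lr = config$lr)
    opt <- st$state
    pp <- st$params
    j <- 1L
    for (l in seq_along(weights)) {
      weights[[l]]$W <- pp[[j]]; weights[[l]]$b <- pp[[j + 1L]]
      j <- j + 2L
    }
    rnn$U <- pp[[j]]; rnn$V <- pp[[j + 1L]]; rnn$b <- pp[[j + 2L]]
    j <- j + 3L
    for (k in seq_len(K)) Wk[[k]] <- pp[[j + k - 1L]]
  }

  enc <- encoder
  enc@weights <- weights
  ctx <- context
  ctx@U <- rnn$U; ctx@V <- rnn$V; ctx@b <- rnn$b
  new("SSLModel", task = "cpc", encoder = enc, context = ctx,
      head = list(Wk = Wk),
      history = data.frame(epoch = seq_along(history) - 1L, loss = history),
      config = list(cpc = unclass(config)))
}

#' Evaluate the InfoNCE loss of a trained CPC model on a dataset
#'
#' Enumerates anchors and draws fresh seeded negatives on the given data
#' (typically a held-out dataset), then computes the mean InfoNCE loss with
#' the model's frozen parameters. Chance level is ln(negatives + 1).
#'
#' @param model a trained CPC [SSLModel-class].
#' @param x,trial windows as in [trainCPC()].
#' @param seed negative-sampling seed.
#' @return mean InfoNCE loss in nats.
#' @export
evalCPCLoss <- function(model, x, trial, seed = 1L) {
  stopIfNot(model@task == "cpc", "model must be a CPC model")
  cfg <- do.call(cpcConfig, model@config$cpc)
  plan <- makeCPCBatches(trial, cfg, seed = seed)
  zAll <- encode(model@encoder, x)
  cAnchors <- matrix(0, nrow(plan), nrow(model@context@U))
  trialRows <- split(seq_along(trial), trial)
  names(trialRows) <- NULL
  for (g in seq_along(trialRows)) {
    rows <- trialRows[[g]]
    cseq <- contextualize(model@context, zAll[rows, , drop = FALSE])
    prows <- which(plan$trial == trial[rows[1]])
    cAnchors[prows, ] <- cseq[plan$t[prows], , drop = FALSE]
  }
  batch <- buildCPCBatch(plan, zAll, cAnchors)
  infonceLoss(batch, model@head$Wk)
}
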