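# Trainable feature extractor h_theta / g_enc and the causal context model
# g_ar. Both are deliberately small (a fully-connected tanh stack and a
# single-layer tanh recurrence): every pretext task shares the same encoder
# class, and all gradients are computed analytically (verified against
# finite differences in the test suite).

#' Initialize an encoder
#'
#' Weights are drawn N(0, 1/fan_in) under the given seed, so initialization
#' is bit-reproducible.
#'
#' @param inputDim input dimensionality (length of a DE feature vector, or
#'   channels * T for a flattened raw window).
#' @param hiddenSizes integer vector of hidden widths (tanh); may be empty
#'   for a linear encoder.
#' @param embeddingDim embedding dimensionality D (linear output).
#' @param seed RNG seed.
#' @return an [Encoder-class].
#' @export
initEncoder <- function(inputDim, hiddenSizes = 32L, embeddingDim = 16L,
                        seed = 1L) {
  dims <- c(as.integer(inputDim), as.integer(hiddenSizes),
            as.integer(embeddingDim))
  weights <- withSeed(seed, {
    lapply(seq_len(length(dims) - 1L), function(l) {
      list(W = matrix(rnorm(dims[l + 1] * dims[l], sd = 1 / sqrt(dims[l])),
                      dims[l + 1], dims[l]),
           b = numeric(dims[l + 1]))
    })
  })
  new("Encoder", inputDim = as.integer(inputDim),
      hiddenSizes = as.integer(hiddenSizes),
      embeddingDim = as.integer(embeddingDim),
      weights = weights, seed = as.integer(seed))
}

# Forward pass with caches for backprop. x: n x inputDim.
mlpForward <- function(weights, x) {
  nl <- length(weights)
  acts <- vector("list", nl + 1L)
  acts[[1]] <- x
  for (l in seq_len(nl)) {
    a <- acts[[l]] %*% t(weights[[l]]$W)
    a <- sweep(a, 2L, weights[[l]]$b, "+")
    acts[[l + 1]] <- if (l < nl) tanh(a) else a  # hidden tanh, linear output
  }
  acts
}

# Backward pass. dOut: n x D gradient at the output. Returns per-layer
# gradients (same structure as weights) and dX.
mlpBackward <- function(weights, acts, dOut) {
  nl <- length(weights)
  grads <- vector("list", nl)
  delta <- dOut
  for (l in rev(seq_len(nl))) {
    if (l < nl) delta <- delta * (1 - acts[[l + 1]]^2)  # tanh'
    grads[[l]] <- list(W = t(delta) %*% acts[[l]], b = colSums(delta))
    delta <- delta %*% weights[[l]]$W
  }
  list(grads = grads, dX = delta)
}

#' @describeIn encode Encode a vector or a matrix of window representations.
#' @export
setMethod("encode", "Encoder", function(encoder, x) {
  vec <- !is.matrix(x)
  if (vec) x <- matrix(x, nrow = 1L)
  stopIfNot(ncol(x) == encoder@inputDim,
            sprintf("input dim %d does not match encoder input dim %d",
                    ncol(x), encoder@inputDim))
  stopIfNot(all(is.finite(x)), "input contains non-finite values")
  z <- mlpForward(encoder@weights, x)[[length(encoder@weights) + 1L]]
  if (vec) drop(z) else z
})

#' Initialize the causal context model
#'
#' @param inputDim embedding dimensionality D.
#' @param contextDim context dimensionality (defaults to D).
#' @param seed RNG seed.
#' @return a [ContextModel-class].
#' @export
initContextModel <- function(inputDim, contextDim = inputDim, seed = 1L) {
  withSeed(seed, {
    new("ContextModel",
        U = matrix(rnorm(contextDim * inputDim, sd = 1 / sqrt(inputDim)),
                   contextDim, inputDim),
        V = matrix(rnorm(contextDim * contextDim, sd = 0.5 / sqrt(contextDim)),
                   contextDim, contextDim),
        b = numeric(contextDim), seed = as.integer(seed))
  })
}

# Forward recurrence c_t = tanh(U z_t + V c_{t-1} + b) from a zero state.
rnnForward <- function(model, z) {
  l <- nrow(z)
  dc <- nrow(model$U)
  cseq <- matrix(0, l, dc)
  prev <- numeric(dc)
  for (t in seq_len(l)) {
    prev <- tanh(drop(model$U %*% z[t, ]) + drop(model$V %*% prev) + model$b)
    cseq[t, ] <- prev
  }
  cseq
}

# Backprop through time. dC: L x Dc gradients wrt each c_t. Returns grads
# for U, V, b and dZ (L x D).
rnnBackward <- function(model, z, cseq, dC) {
  l <- nrow(z)
  dU <- model$U * 0; dV <- model$V * 0; db <- model$b * 0
  dZ <- z * 0
  carry <- numeric(nrow(model$U))
  for (t in rev(seq_len(l))) {
    da <- (dC[t, ] + carry) * (1 - cseq[t, ]^2)
    prev <- if (t > 1L) cseq[t - 1L, ] else numeric(nrow(model$U))
    dU <- dU + outer(da, z[t, ])
    dV <- dV + outer(da, prev)
    db <- db + da
    dZ[t, ] <- drop(crossprod(model$U, da))
    carry <- drop(crossprod(model$V, da))
  }
  list(dU = dU, dV = dV, db = db, dZ = dZ)
}

#' @describeIn contextualize Run the recurrence over an L x D embedding
#'   sequence.
#' @export
setMethod("contextualize", "ContextModel", function(model, z) {
  if (!is.matrix(z)) z <- matrix(z, nrow = 1L)
  stopIfNot(nrow(z) >= 1L, "empty embedding sequence")
  stopIfNot(ncol(z) == ncol(model@U), "embedding dim mismatch")
  rnnForward(list(U = model@U, V = model@V, b = model@b), z)
})

#' Save / load a model checkpoint
#'
#' Checkpoints are single-file RDS archives holding the model object (which
#' carries its configuration and seeds).
#'
#' @param model an [SSLModel-class], [Encoder-class] or [ContextModel-class].
#' @param path file path.
#' @return `loadCheckpoint` returns the stored object.
#' @export
saveCheckpoint <- function(model, path) {
  saveRDS(model, path, version = 2)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) readRDS(path)
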