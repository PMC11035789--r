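#' @import methods
#' @importFrom stats rnorm var sd fft wilcox.test p.adjust predict setNames
#'   plogis
NULL

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards. All internal randomness goes through this
# so that generation order never leaks between stages.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_seed) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(suppressWarnings(
        rm(".Random.seed", envir = globalenv())), add = TRUE)
    }
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  force(expr)
}

# Deterministic per-(stage, subject, trial) substream seed below 2^31.
deriveSeed <- function(seed, ...) {
  ids <- c(...)
  s <- as.double(seed %% 2147483647L)
  for (k in seq_along(ids)) {
    s <- (s * 48271 + as.double(ids[k]) * 2246822519 + 104729) %% 2147483647
  }
  as.integer(s)
}

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

# ---- Adam optimiser over a flat list of numeric arrays --------------------

adamInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adamStep <- function(params, grads, state, lr = 1e-2,
                     beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (i in seq_along(params)) {
    state$m[[i]] <- beta1 * state$m[[i]] + (1 - beta1) * grads[[i]]
    state$v[[i]] <- beta2 * state$v[[i]] + (1 - beta2) * grads[[i]]^2
    params[[i]] <- params[[i]] -
      lr * (state$m[[i]] / bc1) / (sqrt(state$v[[i]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# Scatter-add `contrib` (m x d) into rows `idx` of `target`, aggregating
# duplicate indices.
addRows <- function(target, idx, contrib) {
  agg <- rowsum(contrib, group = idx, reorder = FALSE)
  rows <- as.integer(rownames(agg))
  target[rows, ] <- target[rows, , drop = FALSE] + agg
  target
}

logSumExpRows <- function(x) {
  m <- apply(x, 1L, max)
  m + log(rowSums(exp(x - m)))
}

# md5 fingerprint of an arbitrary R object (via canonical serialization).
objectFingerprint <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}
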