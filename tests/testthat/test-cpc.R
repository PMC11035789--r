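# Direct transcription of the InfoNCE definition: ratio of exponentiated
# bilinear scores, no log-space tricks. Oracle for the packaged loss.
naiveInfoNCE <- function(batch, Wk) {
  m <- nrow(batch$cT)
  tot <- 0
  for (i in seq_len(m)) {
    k <- batch$k[i]
    fpos <- exp(drop(batch$zPos[i, ] %*% Wk[[k]] %*% batch$cT[i, ]))
    fall <- fpos
    if (length(dim(batch$zNeg)) == 3L && dim(batch$zNeg)[2] > 0)
      for (j in seq_len(dim(batch$zNeg)[2]))
        fall <- fall + exp(drop(batch$zNeg[i, j, ] %*% Wk[[k]] %*%
                                  batch$cT[i, ]))
    tot <- tot - log(fpos / fall)
  }
  tot / m
}

randomBatch <- function(m, nNeg, d, dc, kMax = 2L) {
  list(cT = matrix(rnorm(m * dc), m, dc),
       zPos = matrix(rnorm(m * d), m, d),
       zNeg = array(rnorm(m * nNeg * d), dim = c(m, nNeg, d)),
       k = sample.int(kMax, m, replace = TRUE))
}

test_that("the log-bilinear score matches hand arithmetic and is bilinear", {
  expect_equal(scoreFk(rnorm(3), rnorm(4), matrix(0, 3, 4)), 1)
  expect_equal(scoreFk(c(1, 0), c(1, 0), diag(2)), exp(1))
  set.seed(1)
  z <- rnorm(3); cT <- rnorm(3); Wk <- matrix(rnorm(9), 3, 3)
  expect_equal(scoreFk(2.5 * z, cT, Wk, log = TRUE),
               2.5 * scoreFk(z, cT, Wk, log = TRUE))
  expect_equal(scoreFk(z, -3 * cT, Wk, log = TRUE),
               -3 * scoreFk(z, cT, Wk, log = TRUE))
  expect_error(scoreFk(rnorm(3), rnorm(3), matrix(0, 3, 4)), "shape")
})

test_that("uniform candidate scores give exactly ln N for any N", {
  set.seed(2)
  for (n in c(2L, 8L, 33L)) {
    m <- 5L; d <- 4L
    zPos <- matrix(rnorm(m * d), m, d)
    zNeg <- array(rep(zPos, n - 1L), dim = c(m, d, n - 1L))
    zNeg <- aperm(zNeg, c(1, 3, 2))  # negatives identical to the positive
    batch <- list(cT = matrix(rnorm(m * d), m, d), zPos = zPos,
                  zNeg = zNeg, k = rep(1L, m))
    Wk <- list(matrix(rnorm(d * d), d, d))
    expect_equal(infonceLoss(batch, Wk), log(n), tolerance = 1e-12)
  }
})

test_that("a lone positive gives zero loss; a dominant positive nearly zero", {
  d <- 3L
  batch <- list(cT = matrix(rnorm(3 * d), 3, d),
                zPos = matrix(rnorm(3 * d), 3, d),
                zNeg = array(0, dim = c(3, 0, d)), k = rep(1L, 3))
  expect_equal(infonceLoss(batch, list(diag(d))), 0)
  # positive log-score 20, seven negatives at log-score 0
  b2 <- list(cT = matrix(c(1, 0, 0), 1, 3),
             zPos = matrix(c(20, 0, 0), 1, 3),
             zNeg = array(0, dim = c(1, 7, 3)), k = 1L)
  expect_equal(infonceLoss(b2, list(diag(3))), log1p(7 * exp(-20)))
  expect_equal(log1p(7 * exp(-20)), 1.4e-8, tolerance = 0.05)
})

test_that("log-space loss agrees with the naive exponential-ratio oracle", {
  set.seed(3)
  for (rep in 1:10) {
    batch <- randomBatch(m = 6L, nNeg = 5L, d = 4L, dc = 3L)
    Wk <- list(matrix(rnorm(12), 4, 3), matrix(rnorm(12), 4, 3))
    expect_equal(infonceLoss(batch, Wk), naiveInfoNCE(batch, Wk),
                 tolerance = 1e-6)
  }
})

test_that("batch enumeration matches brute force and excludes the positive", {
  trial <- rep(1:2, each = 60L)
  cfg <- cpcConfig(predictionSteps = 4L, negatives = 7L, contextLength = 16L,
                   seed = 5L)
  plan <- makeCPCBatches(trial, cfg)
  # brute force: anchors with full context and K future windows, each k once
  expected <- 0L
  for (tr in 1:2) for (t in 1:60) for (k in 1:4)
    if (t >= 16 && t + 4 <= 60) expected <- expected + 1L
  expect_equal(nrow(plan), expected)      # (60-16-4+1) anchors x 4 k x 2
  expect_equal(nrow(plan), 2L * 41L * 4L)
  offsets <- c(0L, 60L)
  expect_equal(plan$pos, offsets[match(plan$trial, 1:2)] + plan$t + plan$k)
  negs <- as.matrix(plan[, grep("^neg", names(plan))])
  expect_true(all(negs >= 1L & negs <= 120L))
  expect_true(all(negs != plan$pos))      # exhaustive exclusion audit
  expect_identical(plan, makeCPCBatches(trial, cfg))
  expect_error(makeCPCBatches(rep(1L, 12L), cfg), "too short")
})

test_that("CPC training lowers the loss and reproduces under the seed", {
  fa <- structuredData()
  cfg <- cpcConfig(predictionSteps = 2L, negatives = 7L, contextLength = 6L,
                   epochs = 8L, seed = 7L)
  m1 <- trainCPC(fa$xs, fa$trial, config = cfg)
  expect_lt(tail(m1@history$loss, 1), m1@history$loss[1])
  expect_lt(tail(m1@history$loss, 1), log(8))
  m2 <- trainCPC(fa$xs, fa$trial, config = cfg)
  expect_identical(m1@history, m2@history)
  expect_identical(m1@head$Wk, m2@head$Wk)
})

test_that("held-out CPC loss tracks the generator's dependence structure", {
  fa <- structuredData()
  nl <- nullData()
  cfg <- cpcConfig(predictionSteps = 2L, negatives = 7L, contextLength = 6L,
                   epochs = 15L, seed = 7L)
  mS <- trainCPC(fa$xs, fa$trial, config = cfg)
  mN <- trainCPC(nl$xs, nl$trial, config = cfg)
  # fresh data from the same processes
  cfg2 <- fa$config; cfg2@seed <- 101L
  fa2 <- assembleFeatures(lapply(generateDataset(cfg2), extractDEFeatures))
  cfg3 <- nl$config; cfg3@seed <- 102L
  nl2 <- assembleFeatures(lapply(generateDataset(cfg3), extractDEFeatures))
  lossS <- evalCPCLoss(mS, scale(fa2$x), fa2$trial, seed = 1L)
  lossN <- evalCPCLoss(mN, scale(nl2$x), nl2$trial, seed = 1L)
  expect_lt(lossS, log(8) - 0.3)       # structure is exploited
  expect_lt(abs(lossN - log(8)), 0.2)  # nothing to predict stays at chance
})
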