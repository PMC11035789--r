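# Window-unit geometry: starts at unit spacing, radii tauPos = 2, tauNeg = 4.
unitSampler <- function(n = 200L, seed = 1L)
  rpSamplerConfig(nSamples = n, tauPos = 2, tauNeg = 4, seed = seed)

test_that("RP labels follow the positive/negative radii with a dead zone", {
  starts <- 0:30
  s <- sampleRP(starts, unitSampler(400L))
  expect_equal(nrow(s), 400L)
  d <- abs(s$t - s$tPrime)
  expect_true(all(s$y[d <= 2] == 1))
  expect_true(all(s$y[d > 4] == -1))
  # dead-zone pairs (2 < d <= 4) are never emitted; anchors never self-pair
  expect_true(all(d <= 2 | d > 4))
  expect_true(all(d > 0))
  # both classes realized, balanced
  expect_equal(sum(s$y == 1), 200L)
  # canonical cases are reachable: adjacent pair positive, distance-5 negative
  expect_true(all(s$y[s$t == s$tPrime + 1 | s$tPrime == s$t + 1] == 1))
  expect_true(all(s$y[d == 5] == -1))
})

test_that("TS triples obey the ordering label rule exactly", {
  starts <- 0:30
  s <- sampleTS(starts, unitSampler(400L))
  expect_equal(nrow(s), 400L)
  ordered <- s$t < s$tPrime & s$tPrime < s$tDPrime
  expect_identical(s$y, ifelse(ordered, 1, -1))
  # anchors always come from the positive context
  expect_true(all(s$tDPrime - s$t > 0 & s$tDPrime - s$t <= 2))
  # shuffled triples take the third window from the negative context
  far <- pmin(abs(s$tPrime - s$t), abs(s$tPrime - s$tDPrime))
  expect_true(all(far[s$y == -1] > 4))
  expect_equal(sum(s$y == 1), 200L)
})

test_that("samplers refuse unrealizable classes by name", {
  expect_error(sampleRP(0:3, unitSampler()), "negative RP class")
  expect_error(sampleTS(0:3, unitSampler()), "shuffled TS class")
  expect_error(sampleRP(c(0, 10), rpSamplerConfig(nSamples = 10L,
                                                  tauPos = 1, tauNeg = 2)),
               "positive RP class")
  expect_error(rpSamplerConfig(tauPos = 5, tauNeg = 3), "tauPos <= tauNeg")
})

test_that("sampling is deterministic under the seed and within-trial only", {
  startsList <- list(0:20, 100:120)
  a <- sampleRP(startsList, unitSampler(100L, seed = 3L))
  b <- sampleRP(startsList, unitSampler(100L, seed = 3L))
  expect_identical(a, b)
  expect_false(identical(a, sampleRP(startsList, unitSampler(100L, 4L))))
  # every pair drawn inside one trial's start set
  for (i in seq_len(nrow(a))) {
    expect_true(a$t[i] %in% startsList[[a$trial[i]]])
    expect_true(a$tPrime[i] %in% startsList[[a$trial[i]]])
  }
})

test_that("absolute-difference heads match hand arithmetic", {
  expect_equal(gRP(c(1, -2), c(-1, 1)), c(2, 3))
  expect_equal(gRP(c(3, 3), c(3, 3)), c(0, 0))
  expect_equal(gTS(1, 3, 0), c(2, 3))
  expect_equal(gTS(c(1, 1), c(1, 1), c(1, 1)), rep(0, 4))
  set.seed(6)
  for (i in 1:20) {
    h <- rnorm(8); hp <- rnorm(8); hpp <- rnorm(8)
    expect_equal(gRP(h, hp), gRP(hp, h))               # symmetry
    expect_length(gTS(h, hp, hpp), 16L)
    # invariance to sign flips of the two differences
    expect_equal(gTS(h, hp, hpp), gTS(2 * hp - h, hp, hpp))
    expect_equal(gTS(h, hp, hpp), gTS(h, hp, 2 * hp - hpp))
  }
  expect_error(gRP(1:3, 1:4), "length mismatch")
})

test_that("logistic loss matches closed-form values and finite differences", {
  g <- matrix(rnorm(40), 10, 4)
  y <- rep(c(1, -1), 5)
  expect_equal(logisticLoss(g, y, rep(0, 4), 0), 10 * log(2))
  # margin +10 gives per-sample loss log1p(exp(-10))
  gg <- matrix(c(10, rep(0, 3)), 1, 4)
  expect_equal(logisticLoss(gg, 1, c(1, 0, 0, 0), 0), log1p(exp(-10)))
  expect_equal(log1p(exp(-10)), 4.54e-5, tolerance = 1e-2)
  expect_error(logisticLoss(g, rep(2, 10), rep(0, 4), 0), "labels")

  lossAt <- function(wv) logisticLoss(g, y, wv[1:4], wv[5])
  analytic <- {
    ds <- ssleeg:::logisticScoreGrad(drop(g %*% rep(0, 4)) + 0, y) * 10
    c(drop(crossprod(g, ds)), sum(ds))
  }
  expect_equal(analytic, numGrad(lossAt, rep(0, 5)), tolerance = 1e-5)
})

test_that("every emitted sample survives a brute-force label re-check", {
  fa <- structuredData()
  startsList <- unname(split(fa$start, fa$trial))
  cfg <- fixtureSampler(2000L, seed = 11L)
  rp <- sampleRP(startsList, cfg)
  d <- abs(rp$t - rp$tPrime)
  oracle <- ifelse(d <= cfg$tauPos, 1, ifelse(d > cfg$tauNeg, -1, NA))
  expect_identical(rp$y, oracle)  # NA would mean a dead-zone pair escaped
  ts <- sampleTS(startsList, cfg)
  expect_identical(ts$y,
                   ifelse(ts$t < ts$tPrime & ts$tPrime < ts$tDPrime, 1, -1))
})

test_that("RP and TS training reduces the pretext loss deterministically", {
  fa <- structuredData()
  for (trainer in list(trainRP, trainTS)) {
    m1 <- trainer(fa$xs, fa$trial, fa$start, sampler = fixtureSampler(400L),
                  epochs = 12L)
    expect_lt(tail(m1@history$loss, 1), m1@history$loss[1])
    m2 <- trainer(fa$xs, fa$trial, fa$start, sampler = fixtureSampler(400L),
                  epochs = 12L)
    expect_identical(m1@history, m2@history)
    expect_identical(m1@encoder@weights, m2@encoder@weights)
  }
})

test_that("pretext accuracy beats chance on structured data, not on noise", {
  # train on half the trials, evaluate pseudo-label accuracy on the others
  heldOutAcc <- function(fa, trainer) {
    tr <- fa$trial <= 6L
    m <- trainer(fa$xs[tr, ], fa$trial[tr], fa$start[tr],
                 sampler = fixtureSampler(1000L), epochs = 25L)
    pretextAccuracy(m, fa$xs[!tr, ], fa$trial[!tr], fa$start[!tr],
                    fixtureSampler(2000L, seed = 99L))
  }
  expect_gt(heldOutAcc(structuredData(), trainRP), 0.55)
  expect_gt(heldOutAcc(structuredData(), trainTS), 0.55)
  expect_lt(abs(heldOutAcc(nullData(), trainRP) - 0.5), 0.05)
  expect_lt(abs(heldOutAcc(nullData(), trainTS) - 0.5), 0.05)
})
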