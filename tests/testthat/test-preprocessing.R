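makeRecording <- function(x, fs = 200) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  new("Recording", signal = x, samplingRateHz = fs, subjectId = 1L,
      trialId = 1L, label = 1L, t0 = 0L)
}

test_that("segmentation tiles the trial and drops the partial tail", {
  r <- makeRecording(matrix(rnorm(2000), 2, 1000))
  ws <- segmentRecording(r, 200L, 200L)
  expect_identical(ws@starts, as.integer(c(0, 200, 400, 600, 800)))
  expect_equal(dim(ws@windows), c(5L, 2L, 200L))
  expect_equal(ws@windows[3, 2, ], r@signal[2, 401:600])

  expect_equal(length(segmentRecording(r, 200L, 100L)@starts), 9L)
  expect_error(segmentRecording(makeRecording(rnorm(199)), 200L),
               "exceeds")
  expect_error(segmentRecording(r, 200L, 0L), "hop")
})

test_that("band-pass keeps in-band tones and rejects out-of-band tones", {
  tgrid <- seq_len(4000) / 200
  tone10 <- sin(2 * pi * 10 * tgrid)
  inBand <- bandpassFilter(tone10, c(8, 13), 200)
  expect_lt(abs(sd(inBand) - sd(tone10)) / sd(tone10), 0.05)
  outBand <- bandpassFilter(tone10, c(13, 30), 200)
  expect_lt(sd(outBand), 0.1 * sd(tone10))
  expect_equal(bandpassFilter(numeric(400), c(8, 13), 200), numeric(400))
  expect_warning(bandpassFilter(tone10, c(30, 100), 200), "Nyquist")
  expect_error(suppressWarnings(bandpassFilter(tone10, c(120, 150), 200)),
               "Nyquist")
})

test_that("Shannon entropy matches hand values and rejects bad inputs", {
  expect_equal(shannonEntropy(c(0.5, 0.5)), 1)
  expect_equal(shannonEntropy(c(1, 0, 0)), 0)
  expect_equal(shannonEntropy(rep(0.25, 4)), 2)
  expect_error(shannonEntropy(c(-0.1, 1.1)), "nonnegative")
  expect_error(shannonEntropy(c(0.5, 0.4)), "sum to 1")
})

test_that("Gaussian differential entropy matches the closed form", {
  set.seed(1)
  x <- rnorm(1e5)
  expect_lt(abs(differentialEntropyGaussian(x) - 0.5 * log(2 * pi * exp(1))),
            0.01)
  # variance chosen so the log argument is exactly 1
  y <- x / sd(x) * sqrt(1 / (2 * pi * exp(1)))
  expect_lt(abs(differentialEntropyGaussian(y)), 1e-6)
  z <- rnorm(1e5, sd = 2)
  expect_lt(abs(differentialEntropyGaussian(z) -
                0.5 * log(2 * pi * exp(1) * 4)), 0.01)
})

test_that("differential entropy is monotone in variance and scale-equivariant", {
  set.seed(2)
  x <- rnorm(500)
  des <- vapply(c(0.5, 1, 2, 4, 8),
                function(s) differentialEntropyGaussian(x * s), 1)
  expect_true(all(diff(des) > 0))
  k <- 3.7
  expect_equal(differentialEntropyGaussian(x * k),
               differentialEntropyGaussian(x) + log(k), tolerance = 1e-6)
})

test_that("degenerate zero-variance windows follow the configured policy", {
  expect_error(differentialEntropyGaussian(rep(1, 10)), "degenerate")
  expect_identical(differentialEntropyGaussian(rep(1, 10),
                                               degenerate = "neginf"), -Inf)
  flat <- makeRecording(matrix(0, 1, 400))
  expect_error(extractDEFeatures(flat), "window 1, channel 1")
})

test_that("STFT band power is Parseval-consistent", {
  tgrid <- seq_len(200) / 200
  tone <- sin(2 * pi * 10 * tgrid)
  bands <- eegBands()
  p <- vapply(seq_len(5), function(b)
    stftBandPower(tone, 200, bands[b, ]), 1)
  expect_equal(p[3], 0.5, tolerance = 0.02)       # alpha holds the tone
  expect_lt(sum(p[-3]), 0.01)
  set.seed(3)
  w <- rnorm(2000, sd = 1.5)
  tot <- sum(vapply(seq_len(5), function(b)
    stftBandPower(w, 200, bands[b, ]), 1))
  # bands cover 1-100 Hz; white-noise variance is spread uniformly to Nyquist
  expect_lt(abs(tot - var(w)) / var(w), 0.10)
  expect_equal(stftBandPower(numeric(200), 200, bands[1, ]), 0)
  expect_error(stftBandPower(tone, 200, c(1, 2), segmentLength = 50L),
               "no STFT bins")
})

test_that("DE extraction matches the generator's configured band variance", {
  profile <- matrix(1e-3, 1, 5)
  profile[1, 3] <- 2
  cfg <- synthConfig(nClasses = 2L,
                     bandPowerProfiles = rbind(profile, profile),
                     noiseSd = 0, modDepth = 0, trialDurationS = 60,
                     nChannels = 1L, seed = 4L)
  r <- generateTrial(cfg, 1L)
  fe <- extractDEFeatures(r)
  expect_equal(dim(deValues(fe)), c(60L, 1L, 5L))
  alphaDE <- mean(deValues(fe)[, 1, 3])
  expect_lt(abs(alphaDE - 0.5 * log(2 * pi * exp(1) * 4)), 0.15)
  expect_lt(mean(deValues(fe)[, 1, 1]), alphaDE - 3)

  fe2 <- extractDEFeatures(r)
  expect_identical(deValues(fe), deValues(fe2))
})

test_that("filter and STFT feature paths agree on band-limited signals", {
  # an alpha-band-limited signal: both variance estimates target the same
  # in-band content, so the two DE paths must agree in the occupied band
  prof <- matrix(1e-6, 2, 5)
  prof[, 3] <- 2
  cfg <- synthConfig(nClasses = 2L, bandPowerProfiles = prof, noiseSd = 0,
                     trialDurationS = 30, nChannels = 2L, seed = 6L)
  r <- generateTrial(cfg, 1L)
  a <- deValues(extractDEFeatures(r, method = "filter"))[, , 3]
  b <- deValues(extractDEFeatures(r, method = "stft"))[, , 3]
  expect_lt(max(abs(a - b)), 0.2)
  expect_lt(mean(abs(a - b)), 0.1)
})
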