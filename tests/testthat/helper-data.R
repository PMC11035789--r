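# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# A moderate structured dataset: 12 trials x 20 s x 4 channels, 3 classes.
# Big enough for pretext learning, small enough to keep unit tests quick.
structuredData <- function() {
  fixture("structured", function() {
    cfg <- synthConfig(nSubjects = 2L, nTrialsPerSubject = 6L,
                       trialDurationS = 20, nChannels = 4L, seed = 42L)
    recs <- generateDataset(cfg)
    fa <- assembleFeatures(lapply(recs, extractDEFeatures))
    fa$xs <- scale(fa$x)
    attr(fa$xs, "scaled:center") <- NULL
    attr(fa$xs, "scaled:scale") <- NULL
    fa$config <- cfg
    fa
  })
}

# Matching structure-free control data.
nullData <- function() {
  fixture("null", function() {
    cfg <- whiteNoiseConfig(nSubjects = 2L, nTrialsPerSubject = 6L,
                            trialDurationS = 20, nChannels = 4L, seed = 24L)
    recs <- generateDataset(cfg)
    fa <- assembleFeatures(lapply(recs, extractDEFeatures))
    fa$xs <- scale(fa$x)
    attr(fa$xs, "scaled:center") <- NULL
    attr(fa$xs, "scaled:scale") <- NULL
    fa$config <- cfg
    fa
  })
}

# Sampler configuration in window units for the 20-window fixture trials.
fixtureSampler <- function(nSamples = 400L, seed = 1L) {
  rpSamplerConfig(nSamples = nSamples, windowLength = 200L,
                  tauPos = 2L * 200L, tauNeg = 8L * 200L, seed = seed)
}

# Numerical gradient of f at x (central differences).
numGrad <- function(f, x, eps = 1e-5) {
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- x[i] + eps
    xm <- x; xm[i] <- x[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

# Full-scale study conditions: 30 structured trials (2 subjects x 15) of
# 60 s x 8 channels at 200 Hz, 3 classes; plus the matching structure-free
# control and its held-out replicate. Built lazily and cached: only the
# end-to-end acceptance checks request these.
studyData <- function() {
  fixture("study", function() {
    cfg <- synthConfig(nSubjects = 2L, nTrialsPerSubject = 15L,
                       trialDurationS = 60, nChannels = 8L, seed = 42L)
    fa <- assembleFeatures(lapply(generateDataset(cfg), extractDEFeatures))
    fa$xs <- unclass(scale(fa$x))
    fa
  })
}

studyCPC <- function() {
  fixture("studyCPC", function() {
    fa <- studyData()
    trainCPC(fa$xs, fa$trial, config = cpcConfig(epochs = 30L, seed = 7L))
  })
}

# Independent confusion-matrix oracle for accuracy and macro F1.
confusionOracle <- function(pred, truth, classes) {
  cm <- table(factor(pred, levels = classes), factor(truth, levels = classes))
  accO <- sum(diag(cm)) / sum(cm)
  f1s <- vapply(seq_along(classes), function(i) {
    tp <- cm[i, i]; fp <- sum(cm[i, -i]); fn <- sum(cm[-i, i])
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, 1)
  list(accuracy = accO, f1Macro = mean(f1s))
}

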