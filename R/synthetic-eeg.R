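# Synthetic multichannel EEG with known class-dependent band structure.
#
# Each trial is a sum over the five canonical bands of band-limited Gaussian
# noise, scaled so the trial-level SD in each band equals the class profile
# entry, amplitude-modulated by a slow log-normal envelope (so signal
# statistics drift on a ~10 s timescale), plus a 1/f pink-noise background,
# linearly mixed across channels. The per-band Gaussianity makes the
# closed-form differential entropy exact in expectation; the slow envelope
# makes temporal-continuity pseudo-labels learnable.

# Upper edge of the synthesized gamma content. The nominal gamma band tops
# out at 100 Hz, which equals Nyquist at 200 Hz sampling; synthesis caps the
# band strictly below Nyquist to avoid aliased edge content.
synthGammaHigh <- function(fs) min(95, 0.475 * fs)

#' Default class band-power profiles
#'
#' Each class elevates one signature band (SD 3) over a common floor (SD 1):
#' class 1 alpha, class 2 beta, class 3 theta, class 4 delta. Gamma stays at
#' the floor for every class. Chosen so classes are separable through DE
#' features yet overlap under the background noise.
#'
#' @param nClasses number of classes (2-4).
#' @return nClasses x 5 matrix (columns delta, theta, alpha, beta, gamma).
#' @export
defaultBandProfiles <- function(nClasses = 3L) {
  stopIfNot(nClasses >= 2L && nClasses <= 4L, "nClasses must be 2, 3 or 4")
  sig <- c(alpha = 3L, beta = 4L, theta = 2L, delta = 1L)  # band column index
  p <- matrix(1, nClasses, 5L,
              dimnames = list(NULL, c("delta", "theta", "alpha", "beta",
                                      "gamma")))
  for (k in seq_len(nClasses)) p[k, sig[k]] <- 3
  p
}

#' Build a synthetic-EEG generator configuration
#'
#' @param nSubjects,nTrialsPerSubject dataset size.
#' @param trialDurationS trial duration in seconds.
#' @param nChannels number of channels.
#' @param samplingRateHz sampling rate (Hz); must exceed twice the highest
#'   synthesized band edge.
#' @param nClasses number of emotion classes (3 SEED-like, 4 DEAP-like).
#' @param bandPowerProfiles nClasses x 5 nonnegative matrix of per-band SDs;
#'   defaults to [defaultBandProfiles()].
#' @param noiseSd SD of the pink-noise background.
#' @param modDepth depth of the slow log-amplitude envelope (0 = stationary).
#' @param modTimescaleS envelope correlation timescale in seconds.
#' @param mixing nChannels x nSources mixing matrix (identity by default).
#' @param seed RNG seed; same config + seed gives a bit-identical dataset.
#' @return a [SynthConfig-class].
#' @export
synthConfig <- function(nSubjects = 2L, nTrialsPerSubject = 15L,
                        trialDurationS = 60, nChannels = 8L,
                        samplingRateHz = 200, nClasses = 3L,
                        bandPowerProfiles = NULL, noiseSd = 1,
                        modDepth = 0.5, modTimescaleS = 10,
                        mixing = NULL, seed = 1L) {
  if (is.null(bandPowerProfiles))
    bandPowerProfiles <- defaultBandProfiles(nClasses)
  if (is.null(mixing)) mixing <- diag(nChannels)
  new("SynthConfig",
      nSubjects = as.integer(nSubjects),
      nTrialsPerSubject = as.integer(nTrialsPerSubject),
      trialDurationS = as.numeric(trialDurationS),
      nChannels = as.integer(nChannels),
      samplingRateHz = as.numeric(samplingRateHz),
      nClasses = as.integer(nClasses),
      bandPowerProfiles = bandPowerProfiles,
      noiseSd = as.numeric(noiseSd),
      modDepth = as.numeric(modDepth),
      modTimescaleS = as.numeric(modTimescaleS),
      mixing = mixing, seed = as.integer(seed))
}

#' Structure-free control configuration
#'
#' Every class shares a flat band profile, the envelope modulation is
#' switched off, and the 1/f background is removed (its slowly drifting
#' power would itself be temporal structure), so trials are stationary
#' band-limited noise with identical statistics: there is nothing for a
#' temporal pretext task to learn. Used as the null control for RP/TS/CPC.
#'
#' @param ... arguments passed to [synthConfig()].
#' @return a [SynthConfig-class].
#' @export
whiteNoiseConfig <- function(...) {
  args <- list(...)
  nClasses <- if (!is.null(args$nClasses)) as.integer(args$nClasses) else 3L
  args$nClasses <- nClasses
  args$bandPowerProfiles <- matrix(1, nClasses, 5L)
  args$modDepth <- 0
  if (is.null(args$noiseSd)) args$noiseSd <- 0
  do.call(synthConfig, args)
}

# Band-limited unit-SD Gaussian noise via spectral masking: FFT a white
# series, zero all bins outside [low, high), invert, rescale to sample SD 1.
bandNoise <- function(m, fs, low, high) {
  w <- rnorm(m)
  sp <- fft(w)
  freqs <- (seq_len(m) - 1) * fs / m
  freqs <- pmin(freqs, fs - freqs)  # two-sided -> folded frequency
  sp[freqs < low | freqs >= high] <- 0
  x <- Re(fft(sp, inverse = TRUE)) / m
  s <- sd(x)
  if (s > 0) x / s else x
}

# 1/f amplitude pink noise, unit SD.
pinkNoise <- function(m, fs) {
  w <- rnorm(m)
  sp <- fft(w)
  freqs <- (seq_len(m) - 1) * fs / m
  freqs <- pmin(freqs, fs - freqs)
  amp <- ifelse(freqs > 0, 1 / sqrt(pmax(freqs, fs / m)), 0)
  x <- Re(fft(sp * amp, inverse = TRUE)) / m
  s <- sd(x)
  if (s > 0) x / s else x
}

# Slowly varying positive envelope: Gaussian-kernel-smoothed white noise
# (circular, via FFT), standardized, exponentiated, normalized to unit RMS so
# modulation never changes the trial-level band SD.
slowEnvelope <- function(m, fs, depth, timescaleS) {
  if (depth <= 0) return(rep(1, m))
  u <- rnorm(m)
  tgrid <- (seq_len(m) - 1) / fs
  tgrid <- pmin(tgrid, max(tgrid) + 1 / fs - tgrid)  # circular lag
  kern <- exp(-0.5 * (tgrid / timescaleS)^2)
  sm <- Re(fft(fft(u) * fft(kern), inverse = TRUE)) / m
  sm <- (sm - mean(sm)) / sd(sm)
  a <- exp(depth * sm)
  a / sqrt(mean(a^2))
}

#' Generate one synthetic trial
#'
#' @param config a [SynthConfig-class].
#' @param classIdx class index in 1..nClasses.
#' @param subjectId,trialId metadata attached to the recording (they also
#'   select the trial's RNG substream, so generation order is irrelevant).
#' @return a [Recording-class].
#' @export
generateTrial <- function(config, classIdx, subjectId = 1L, trialId = 1L) {
  stopIfNot(classIdx >= 1L && classIdx <= config@nClasses,
            sprintf("classIdx must be in 1..%d", config@nClasses))
  profile <- config@bandPowerProfiles[classIdx, ]
  stopIfNot(all(profile >= 0), "band profile contains negative entries")
  fs <- config@samplingRateHz
  m <- as.integer(round(config@trialDurationS * fs))
  nSources <- ncol(config@mixing)
  bands <- eegBands()
  bands$high[bands$name == "gamma"] <- synthGammaHigh(fs)

  seed <- deriveSeed(config@seed, subjectId, trialId)
  sources <- withSeed(seed, {
    out <- matrix(0, nSources, m)
    for (s in seq_len(nSources)) {
      x <- numeric(m)
      for (b in seq_len(nrow(bands))) {
        if (profile[b] <= 0) next
        bn <- bandNoise(m, fs, bands$low[b], bands$high[b])
        env <- slowEnvelope(m, fs, config@modDepth, config@modTimescaleS)
        xb <- bn * env
        sdb <- sd(xb)
        if (sdb > 0) xb <- xb / sdb * profile[b]
        x <- x + xb
      }
      if (config@noiseSd > 0)
        x <- x + pinkNoise(m, fs) * config@noiseSd
      out[s, ] <- x
    }
    out
  })
  new("Recording", signal = config@mixing %*% sources,
      samplingRateHz = fs, subjectId = as.integer(subjectId),
      trialId = as.integer(trialId), label = as.integer(classIdx),
      t0 = 0L)
}

#' Generate a full synthetic dataset
#'
#' Class labels are assigned per subject as balanced as the trial count
#' allows (counts differ by at most one), in a deterministic seeded order.
#'
#' @param config a [SynthConfig-class].
#' @return a list of [Recording-class] objects.
#' @export
generateDataset <- function(config) {
  stopIfNot(config@nTrialsPerSubject >= 1L, "zero trials requested")
  recs <- vector("list", config@nSubjects * config@nTrialsPerSubject)
  i <- 0L
  for (subj in seq_len(config@nSubjects)) {
    classes <- rep(seq_len(config@nClasses),
                   length.out = config@nTrialsPerSubject)
    classes <- withSeed(deriveSeed(config@seed, subj, 0L), sample(classes))
    for (tr in seq_len(config@nTrialsPerSubject)) {
      i <- i + 1L
      recs[[i]] <- generateTrial(config, classes[tr], subj, tr)
    }
  }
  recs
}

#' Persist / load a dataset as a binary container plus JSON manifest
#'
#' Each trial is written as little-endian float32 (channel-major: channel 1's
#' samples, then channel 2's, ...) next to a `manifest.json` recording
#' dimensions, sampling rate, subject, trial and label.
#'
#' @param recordings list of [Recording-class] objects.
#' @param dir output directory (created if needed).
#' @return `writeDataset` returns the manifest invisibly; `readDataset`
#'   returns the list of recordings.
#' @export
writeDataset <- function(recordings, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- vector("list", length(recordings))
  for (i in seq_along(recordings)) {
    r <- recordings[[i]]
    fn <- sprintf("trial_%04d.bin", i)
    con <- file(file.path(dir, fn), "wb")
    writeBin(as.numeric(t(r@signal)), con, size = 4L, endian = "little")
    close(con)
    entries[[i]] <- list(file = fn, nChannels = nrow(r@signal),
      nSamples = ncol(r@signal), samplingRateHz = r@samplingRateHz,
      subjectId = r@subjectId, trialId = r@trialId,
      label = if (is.na(r@label)) NULL else r@label, t0 = r@t0)
  }
  manifest <- list(format = "ssleeg-dataset-v1", dtype = "float32le",
                   order = "channel-major", trials = entries)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' @rdname writeDataset
#' @export
readDataset <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = FALSE)
  stopIfNot(identical(manifest$format, "ssleeg-dataset-v1"),
            "unrecognized dataset manifest format")
  lapply(manifest$trials, function(e) {
    con <- file(file.path(dir, e$file), "rb")
    x <- readBin(con, numeric(), n = e$nChannels * e$nSamples,
                 size = 4L, endian = "little")
    close(con)
    new("Recording",
        signal = matrix(x, nrow = e$nChannels, byrow = TRUE),
        samplingRateHz = as.numeric(e$samplingRateHz),
        subjectId = as.integer(e$subjectId), trialId = as.integer(e$trialId),
        label = if (is.null(e$label)) NA_integer_ else as.integer(e$label),
        t0 = as.integer(e$t0))
  })
}
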