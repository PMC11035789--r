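# Windowing and differential-entropy band features.
#
# The feature of record is the per-window, per-channel, per-band differential
# entropy. For a Gaussian band-limited signal the differential entropy has
# the closed form (1/2) log(2 pi e sigma^2); the band variance sigma^2 is
# estimated either from a zero-phase band-passed time series ("filter") or
# from in-band spectral power ("stft"). All DE values are in nats.

#' Canonical EEG frequency bands
#'
#' delta 1-4 Hz, theta 4-8 Hz, alpha 8-13 Hz, beta 13-30 Hz, gamma 30-100 Hz.
#'
#' @return a data.frame with columns `name`, `low`, `high` (Hz).
#' @export
eegBands <- function() {
  data.frame(name = c("delta", "theta", "alpha", "beta", "gamma"),
             low = c(1, 4, 8, 13, 30),
             high = c(4, 8, 13, 30, 100),
             stringsAsFactors = FALSE)
}

#' Cut a recording into fixed-length windows
#'
#' Windows are 0-based half-open intervals [t, t+T) starting at multiples of
#' `hop`; a trailing partial window is discarded. The default tiles the trial
#' with non-overlapping 1-s windows.
#'
#' @param recording a [Recording-class].
#' @param windowLength window length T in samples (default 1 s).
#' @param hop hop between window starts in samples (default `windowLength`).
#' @return a [WindowSet-class] with floor((M - T)/hop) + 1 windows.
#' @export
segmentRecording <- function(recording,
                             windowLength = round(recording@samplingRateHz),
                             hop = windowLength) {
  m <- ncol(recording@signal)
  windowLength <- as.integer(windowLength)
  hop <- as.integer(hop)
  stopIfNot(hop >= 1L, "hop must be >= 1")
  stopIfNot(windowLength >= 1L && windowLength <= m,
            "window length exceeds recording length")
  starts <- seq.int(0L, m - windowLength, by = hop)
  nc <- nrow(recording@signal)
  w <- array(0, dim = c(length(starts), nc, windowLength))
  for (i in seq_along(starts))
    w[i, , ] <- recording@signal[, (starts[i] + 1L):(starts[i] + windowLength),
                                 drop = FALSE]
  new("WindowSet", windows = w, starts = as.integer(starts),
      windowLength = windowLength, samplingRateHz = recording@samplingRateHz,
      subjectId = recording@subjectId, trialId = recording@trialId,
      label = recording@label)
}

normalizeBand <- function(band) {
  if (is.data.frame(band)) {
    stopIfNot(nrow(band) == 1L, "band must be a single definition")
    c(low = band$low, high = band$high)
  } else {
    stopIfNot(length(band) == 2L, "band must be c(low, high)")
    c(low = band[[1]], high = band[[2]])
  }
}

#' Zero-phase band-pass filter
#'
#' Order-4 Butterworth applied forward and backward (`signal::filtfilt`), so
#' there is no group delay and window alignment is preserved. A band edge at
#' or above Nyquist is clipped just below it with a warning (the gamma band
#' at 200 Hz sampling); a band lying entirely above Nyquist is an error.
#'
#' @param x numeric vector or channels x samples matrix.
#' @param band a row of [eegBands()] or `c(low, high)` in Hz.
#' @param samplingRateHz sampling rate in Hz.
#' @return filtered signal, same shape as `x`.
#' @export
bandpassFilter <- function(x, band, samplingRateHz) {
  b <- normalizeBand(band)
  nyq <- samplingRateHz / 2
  stopIfNot(b["low"] > 0 && b["high"] > b["low"], "invalid band edges")
  if (b["low"] >= nyq)
    stop("band lies entirely above Nyquist", call. = FALSE)
  if (b["high"] >= nyq) {
    warning(sprintf("band upper edge %.4g Hz clipped below Nyquist (%.4g Hz)",
                    b["high"], nyq))
    b["high"] <- 0.99 * nyq
  }
  bf <- signal::butter(4, c(b["low"], b["high"]) / nyq, type = "pass")
  filt1 <- function(v) signal::filtfilt(bf, v)
  if (is.matrix(x)) t(apply(x, 1L, filt1)) else filt1(x)
}

#' Shannon entropy of a discrete distribution
#'
#' H = -sum p log2 p in bits, with 0 log 0 taken as 0.
#'
#' @param p nonnegative probability vector summing to 1 (tolerance 1e-9).
#' @return entropy in bits, between 0 and log2(length(p)).
#' @export
shannonEntropy <- function(p) {
  stopIfNot(all(p >= 0), "probabilities must be nonnegative")
  stopIfNot(abs(sum(p) - 1) <= 1e-9, "probabilities must sum to 1")
  nz <- p > 0
  -sum(p[nz] * log2(p[nz]))
}

#' Differential entropy of a Gaussian sample
#'
#' Returns (1/2) ln(2 pi e sigma^2) in nats, with sigma^2 the unbiased
#' (n - 1) sample variance. This is the closed form of the differential
#' entropy of a Gaussian and is exact in expectation when the band-limited
#' signal is Gaussian.
#'
#' @param x numeric vector, length >= 2.
#' @param degenerate what to do when the sample variance is zero: `"error"`
#'   (default) or `"neginf"` to return -Inf.
#' @return differential entropy in nats.
#' @export
differentialEntropyGaussian <- function(x, degenerate = c("error", "neginf")) {
  degenerate <- match.arg(degenerate)
  stopIfNot(length(x) >= 2L, "need at least 2 samples")
  v <- var(x)
  if (v <= 0) {
    if (degenerate == "error")
      stop("zero-variance (degenerate) window", call. = FALSE)
    return(-Inf)
  }
  0.5 * log(2 * pi * exp(1) * v)
}

# DE from a variance estimate (spectral path); shares the degenerate policy.
deFromVariance <- function(v, degenerate = "error", what = "") {
  if (v <= 0) {
    if (degenerate == "error")
      stop(sprintf("zero-variance (degenerate) window%s", what), call. = FALSE)
    return(-Inf)
  }
  0.5 * log(2 * pi * exp(1) * v)
}

#' In-band spectral power of a window
#'
#' Mean-removed Welch periodogram (rectangular segments, no overlap); the
#' returned value is the total spectral mass over bins whose center frequency
#' lies in [low, high), counting both spectral sides, so it is
#' Parseval-consistent with the time-domain variance of an in-band signal.
#'
#' @param window numeric vector or channels x T matrix (one window).
#' @param samplingRateHz sampling rate in Hz.
#' @param band a row of [eegBands()] or `c(low, high)` in Hz.
#' @param segmentLength STFT segment length in samples (default: the whole
#'   window, i.e. a single periodogram).
#' @return per-channel in-band power (variance units).
#' @export
stftBandPower <- function(window, samplingRateHz, band,
                          segmentLength = NULL) {
  b <- normalizeBand(band)
  x <- if (is.matrix(window)) window else matrix(window, nrow = 1L)
  tlen <- ncol(x)
  if (is.null(segmentLength)) segmentLength <- tlen
  segmentLength <- as.integer(segmentLength)
  stopIfNot(segmentLength >= 2L && segmentLength <= tlen,
            "window length must be >= STFT segment length")
  freqs <- (seq_len(segmentLength) - 1) * samplingRateHz / segmentLength
  folded <- pmin(freqs, samplingRateHz - freqs)
  inBand <- folded >= b["low"] & folded < b["high"]
  if (!any(inBand))
    stop("band contains no STFT bins at this resolution", call. = FALSE)
  nSeg <- tlen %/% segmentLength
  starts <- (seq_len(nSeg) - 1L) * segmentLength
  out <- numeric(nrow(x))
  for (ch in seq_len(nrow(x))) {
    p <- numeric(segmentLength)
    for (s in starts) {
      seg <- x[ch, (s + 1L):(s + segmentLength)]
      seg <- seg - mean(seg)
      p <- p + Mod(fft(seg))^2 / segmentLength^2
    }
    out[ch] <- sum(p[inBand]) / nSeg
  }
  out
}

#' Extract differential-entropy band features
#'
#' The pipeline's feature extractor: segment a recording into windows and
#' compute, for every window, channel and band, the Gaussian closed-form
#' differential entropy of the band-limited content. `method = "filter"`
#' band-passes the whole trial (zero-phase) and takes per-window sample
#' variances; `method = "stft"` uses in-band spectral power as the variance.
#'
#' @param recording a [Recording-class].
#' @param bands band definitions (default [eegBands()]).
#' @param windowLength,hop see [segmentRecording()].
#' @param method `"filter"` (default) or `"stft"`.
#' @param degenerate policy for zero-variance windows, see
#'   [differentialEntropyGaussian()].
#' @return a [DEFeatureMatrix-class] with dims (windows, channels, bands).
#' @export
extractDEFeatures <- function(recording, bands = eegBands(),
                              windowLength = round(recording@samplingRateHz),
                              hop = windowLength,
                              method = c("filter", "stft"),
                              degenerate = "error") {
  method <- match.arg(method)
  ws <- segmentRecording(recording, windowLength, hop)
  nW <- dim(ws@windows)[1]
  nC <- dim(ws@windows)[2]
  nB <- nrow(bands)
  vals <- array(NA_real_, dim = c(nW, nC, nB))
  fs <- recording@samplingRateHz
  for (b in seq_len(nB)) {
    if (method == "filter") {
      filtered <- suppressWarnings(
        bandpassFilter(recording@signal, bands[b, ], fs))
      if (!is.matrix(filtered)) filtered <- matrix(filtered, nrow = 1L)
      for (i in seq_len(nW)) {
        seg <- filtered[, (ws@starts[i] + 1L):(ws@starts[i] + ws@windowLength),
                        drop = FALSE]
        for (ch in seq_len(nC)) {
          v <- var(seg[ch, ])
          vals[i, ch, b] <- deFromVariance(
            v, degenerate,
            sprintf(" (window %d, channel %d, band %s)", i, ch,
                    bands$name[b]))
        }
      }
    } else {
      for (i in seq_len(nW)) {
        pw <- stftBandPower(ws@windows[i, , , drop = TRUE], fs, bands[b, ])
        for (ch in seq_len(nC))
          vals[i, ch, b] <- deFromVariance(
            pw[ch], degenerate,
            sprintf(" (window %d, channel %d, band %s)", i, ch,
                    bands$name[b]))
      }
    }
  }
  new("DEFeatureMatrix", values = vals, bands = bands, starts = ws@starts,
      windowLength = ws@windowLength, samplingRateHz = fs,
      subjectId = recording@subjectId, trialId = recording@trialId,
      label = recording@label, method = method)
}

#' Assemble per-trial feature matrices into one design matrix
#'
#' Flattens a list of [DEFeatureMatrix-class] objects into an
#' nWindows x (channels * bands) matrix plus aligned window metadata, the
#' input format expected by the pretext trainers and the evaluation harness.
#'
#' @param feList list of [DEFeatureMatrix-class] objects.
#' @return list with `x` (matrix), `trial` (integer trial index per window,
#'   unique across subjects), `label`, `subject`, `start` vectors.
#' @export
assembleFeatures <- function(feList) {
  xs <- list(); trial <- label <- subject <- start <- integer(0)
  for (i in seq_along(feList)) {
    fe <- feList[[i]]
    d <- dim(fe@values)
    xs[[i]] <- matrix(fe@values, nrow = d[1])  # channel-major then band
    trial <- c(trial, rep.int(i, d[1]))
    label <- c(label, rep.int(fe@label, d[1]))
    subject <- c(subject, rep.int(fe@subjectId, d[1]))
    start <- c(start, fe@starts)
  }
  list(x = do.call(rbind, xs), trial = trial, label = label,
       subject = subject, start = start)
}
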