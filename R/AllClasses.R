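#' Configuration for the synthetic EEG generator
#'
#' Describes a synthetic multichannel EEG dataset: how many subjects and
#' trials, the sampling rate, how many emotion classes, and — the scientific
#' core — a per-class profile of band-limited signal standard deviations.
#' Each class expresses its identity as a distinct pattern of power across
#' the five canonical EEG bands (delta, theta, alpha, beta, gamma), and the
#' band amplitudes drift slowly in time so that the temporal-continuity
#' assumption behind relative-position / temporal-shuffling pseudo-labels
#' holds by construction.
#'
#' @slot nSubjects number of subjects.
#' @slot nTrialsPerSubject trials recorded per subject.
#' @slot trialDurationS trial duration in seconds.
#' @slot nChannels number of channels.
#' @slot samplingRateHz sampling rate in Hz (default 200).
#' @slot nClasses number of emotion classes (3 or 4).
#' @slot bandPowerProfiles nClasses x 5 matrix of per-band signal standard
#'   deviations (columns follow [eegBands()]).
#' @slot noiseSd standard deviation of the 1/f background noise.
#' @slot modDepth log-amplitude depth of the slow envelope modulation.
#' @slot modTimescaleS timescale (s) of the envelope modulation.
#' @slot mixing nChannels x nSources channel mixing matrix.
#' @slot seed integer RNG seed; identical config + seed gives a bit-identical
#'   dataset.
#' @export
setClass("SynthConfig",
  representation(
    nSubjects = "integer", nTrialsPerSubject = "integer",
    trialDurationS = "numeric", nChannels = "integer",
    samplingRateHz = "numeric", nClasses = "integer",
    bandPowerProfiles = "matrix", noiseSd = "numeric",
    modDepth = "numeric", modTimescaleS = "numeric",
    mixing = "matrix", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@nSubjects < 1L) msg <- c(msg, "nSubjects must be >= 1")
    if (object@nTrialsPerSubject < 1L)
      msg <- c(msg, "nTrialsPerSubject must be >= 1")
    if (!(object@nClasses %in% c(2L, 3L, 4L)))
      msg <- c(msg, "nClasses must be 2, 3 or 4")
    if (nrow(object@bandPowerProfiles) != object@nClasses ||
        ncol(object@bandPowerProfiles) != 5L)
      msg <- c(msg, "bandPowerProfiles must be nClasses x 5")
    if (any(object@bandPowerProfiles < 0))
      msg <- c(msg, "bandPowerProfiles entries must be >= 0")
    if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
    if (object@samplingRateHz <= 0) msg <- c(msg, "samplingRateHz must be > 0")
    # Nyquist check against the highest band actually synthesized (gamma is
    # capped strictly below Nyquist at synthesis time).
    if (object@samplingRateHz < 2 * synthGammaHigh(object@samplingRateHz))
      msg <- c(msg, "sampling rate too low for the synthesized gamma band")
    if (nrow(object@mixing) != object@nChannels)
      msg <- c(msg, "mixing must have nChannels rows")
    if (length(msg)) msg else TRUE
  })

#' A single multichannel recording (one trial)
#'
#' @slot signal channels x samples real matrix, all finite.
#' @slot samplingRateHz sampling rate in Hz.
#' @slot subjectId integer subject identifier.
#' @slot trialId integer trial identifier.
#' @slot label emotion class index (1-based) or NA when unlabeled.
#' @slot t0 start offset of the first sample (0-based).
#' @export
setClass("Recording",
  representation(signal = "matrix", samplingRateHz = "numeric",
    subjectId = "integer", trialId = "integer",
    label = "integer", t0 = "integer"),
  validity = function(object) {
    msg <- character()
    if (!all(is.finite(object@signal)))
      msg <- c(msg, "signal contains non-finite values")
    if (ncol(object@signal) < 1L) msg <- c(msg, "signal has no samples")
    if (object@samplingRateHz <= 0) msg <- c(msg, "samplingRateHz must be > 0")
    if (length(msg)) msg else TRUE
  })

#' Fixed-length windows cut from one recording
#'
#' Windows are indexed 0-based with half-open extent [t, t+T); by default they
#' tile the trial without overlap (hop = window length) and any trailing
#' partial window is discarded.
#'
#' @slot windows nWindows x channels x T array.
#' @slot starts 0-based start sample of each window.
#' @slot windowLength window length T in samples.
#' @slot samplingRateHz sampling rate in Hz.
#' @slot subjectId,trialId,label metadata carried from the recording.
#' @export
setClass("WindowSet",
  representation(windows = "array", starts = "integer",
    windowLength = "integer", samplingRateHz = "numeric",
    subjectId = "integer", trialId = "integer", label = "integer"),
  validity = function(object) {
    msg <- character()
    d <- dim(object@windows)
    if (length(d) != 3L) msg <- c(msg, "windows must be a 3-d array")
    else {
      if (d[3] != object@windowLength)
        msg <- c(msg, "third dim must equal windowLength")
      if (d[1] != length(object@starts))
        msg <- c(msg, "starts length must match window count")
    }
    if (any(object@starts < 0L)) msg <- c(msg, "starts must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' Per-window, per-channel, per-band differential-entropy features
#'
#' Values are in nats: each entry is (1/2) log(2 pi e sigma^2) with sigma^2
#' the band-limited sample variance of one window/channel.
#'
#' @slot values nWindows x channels x nBands array, finite.
#' @slot bands band definition data.frame (see [eegBands()]).
#' @slot starts 0-based window start samples.
#' @slot windowLength window length in samples.
#' @slot samplingRateHz sampling rate in Hz.
#' @slot subjectId,trialId,label metadata carried from the recording.
#' @slot method "filter" or "stft".
#' @export
setClass("DEFeatureMatrix",
  representation(values = "array", bands = "data.frame", starts = "integer",
    windowLength = "integer", samplingRateHz = "numeric",
    subjectId = "integer", trialId = "integer", label = "integer",
    method = "character"),
  validity = function(object) {
    msg <- character()
    d <- dim(object@values)
    if (length(d) != 3L) msg <- c(msg, "values must be a 3-d array")
    else if (d[3] != nrow(object@bands))
      msg <- c(msg, "third dim must match number of bands")
    if (!all(is.finite(object@values)))
      msg <- c(msg, "values contain non-finite entries")
    if (length(msg)) msg else TRUE
  })

#' A small fully-connected encoder
#'
#' Maps one window representation (a DE feature vector or a flattened raw
#' window) to a D-dimensional embedding. Hidden layers use tanh; the output
#' layer is linear. This is the trainable feature extractor shared by all
#' three pretext tasks.
#'
#' @slot inputDim input dimensionality.
#' @slot hiddenSizes hidden layer widths.
#' @slot embeddingDim embedding dimensionality D.
#' @slot weights list of layers, each list(W, b).
#' @slot seed seed used for initialization.
#' @export
setClass("Encoder",
  representation(inputDim = "integer", hiddenSizes = "integer",
    embeddingDim = "integer", weights = "list", seed = "integer"),
  validity = function(object) {
    if (object@embeddingDim < 1L) "embeddingDim must be >= 1" else TRUE
  })

#' Causal autoregressive context model
#'
#' A single-layer tanh recurrence c_t = tanh(U z_t + V c_{t-1} + b) run from a
#' zero state, so the context at time t depends only on embeddings up to t.
#'
#' @slot U contextDim x inputDim input weights.
#' @slot V contextDim x contextDim recurrent weights.
#' @slot b bias vector.
#' @slot seed seed used for initialization.
#' @export
setClass("ContextModel",
  representation(U = "matrix", V = "matrix", b = "numeric", seed = "integer"),
  validity = function(object) {
    if (nrow(object@V) != ncol(object@V)) return("V must be square")
    if (nrow(object@U) != nrow(object@V)) return("U/V row mismatch")
    if (length(object@b) != nrow(object@U)) return("b length mismatch")
    TRUE
  })

#' A trained self-supervised model
#'
#' Bundles the encoder with the task-specific head: a logistic head (w, w0)
#' for relative-position and temporal-shuffling, or a context model plus
#' per-step bilinear matrices W_k for contrastive predictive coding.
#'
#' @slot task "rp", "ts" or "cpc".
#' @slot encoder the trained [Encoder-class].
#' @slot context the [ContextModel-class] (CPC only) or NULL.
#' @slot head task head parameters.
#' @slot history per-epoch training loss data.frame.
#' @slot config training configuration snapshot.
#' @export
setClass("SSLModel",
  representation(task = "character", encoder = "Encoder", context = "ANY",
    head = "list", history = "data.frame", config = "list"),
  validity = function(object) {
    if (!object@task %in% c("rp", "ts", "cpc"))
      "task must be rp, ts or cpc" else TRUE
  })

#' Cross-validated evaluation report for one method
#'
#' @slot method method name.
#' @slot foldAccuracy per-fold accuracy, percent.
#' @slot foldF1 per-fold macro F1, percent.
#' @slot nFolds number of folds.
#' @slot labelFraction fraction of training labels used by the probe.
#' @slot seed evaluation seed.
#' @slot fingerprint md5 fingerprint of the evaluation configuration.
#' @export
setClass("EvalReport",
  representation(method = "character", foldAccuracy = "numeric",
    foldF1 = "numeric", nFolds = "integer", labelFraction = "numeric",
    seed = "integer", fingerprint = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@foldAccuracy) != object@nFolds ||
        length(object@foldF1) != object@nFolds)
      msg <- c(msg, "fold metric lengths must equal nFolds")
    if (any(object@foldAccuracy < 0 | object@foldAccuracy > 100) ||
        any(object@foldF1 < 0 | object@foldF1 > 100))
      msg <- c(msg, "metrics must lie in [0, 100]")
    if (length(msg)) msg else TRUE
  })
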