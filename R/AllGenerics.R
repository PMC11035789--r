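#' Encode window representations into embeddings
#'
#' @param encoder an [Encoder-class].
#' @param x a numeric vector (one window) or an n x inputDim matrix.
#' @return an embedding vector, or an n x D matrix for matrix input.
#' @export
setGeneric("encode", function(encoder, x) standardGeneric("encode"))

#' Run the causal context model over an embedding sequence
#'
#' @param model a [ContextModel-class].
#' @param z an L x D matrix of embeddings ordered in time.
#' @return an L x contextDim matrix of context vectors; row t depends only on
#'   rows 1..t of `z`.
#' @export
setGeneric("contextualize", function(model, z) standardGeneric("contextualize"))

#' @rdname accessors
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname accessors
#' @export
setGeneric("trialLabel", function(x) standardGeneric("trialLabel"))

#' @rdname accessors
#' @export
setGeneric("deValues", function(x) standardGeneric("deValues"))

#' @rdname accessors
#' @export
setGeneric("foldScores", function(x) standardGeneric("foldScores"))

#' Accessors for ssleeg classes
#'
#' `nChannels()` and `samplingRate()` work on recordings, window sets and
#' feature matrices; `trialLabel()` returns the attached class index (NA when
#' unlabeled); `deValues()` returns the windows x channels x bands feature
#' array; `foldScores()` returns a data.frame of per-fold metrics from an
#' [EvalReport-class].
#'
#' @param x object to access.
#' @name accessors
NULL

setMethod("nChannels", "Recording", function(x) nrow(x@signal))
setMethod("nChannels", "WindowSet", function(x) dim(x@windows)[2])
setMethod("nChannels", "DEFeatureMatrix", function(x) dim(x@values)[2])
setMethod("samplingRate", "Recording", function(x) x@samplingRateHz)
setMethod("samplingRate", "WindowSet", function(x) x@samplingRateHz)
setMethod("samplingRate", "DEFeatureMatrix", function(x) x@samplingRateHz)
setMethod("trialLabel", "Recording", function(x) x@label)
setMethod("trialLabel", "WindowSet", function(x) x@label)
setMethod("trialLabel", "DEFeatureMatrix", function(x) x@label)
setMethod("deValues", "DEFeatureMatrix", function(x) x@values)
setMethod("foldScores", "EvalReport", function(x)
  data.frame(fold = seq_len(x@nFolds), accuracy = x@foldAccuracy,
             f1Macro = x@foldF1))

setMethod("show", "SynthConfig", function(object) {
  cat(sprintf(
    "SynthConfig: %d subject(s) x %d trial(s), %g s @ %g Hz, %d channel(s), %d classes\n",
    object@nSubjects, object@nTrialsPerSubject, object@trialDurationS,
    object@samplingRateHz, object@nChannels, object@nClasses))
  cat("band SD profiles (classes x bands):\n")
  print(round(object@bandPowerProfiles, 3))
  cat(sprintf("noise sd %.3g, envelope depth %.2g @ %.3g s, seed %d\n",
              object@noiseSd, object@modDepth, object@modTimescaleS,
              object@seed))
})

setMethod("show", "Recording", function(object) {
  cat(sprintf(
    "Recording: %d ch x %d samples @ %g Hz (%.1f s), subject %d trial %d, label %s\n",
    nrow(object@signal), ncol(object@signal), object@samplingRateHz,
    ncol(object@signal) / object@samplingRateHz,
    object@subjectId, object@trialId,
    ifelse(is.na(object@label), "<none>", object@label)))
})

setMethod("show", "WindowSet", function(object) {
  d <- dim(object@windows)
  cat(sprintf("WindowSet: %d window(s) of %d samples x %d ch @ %g Hz\n",
              d[1], object@windowLength, d[2], object@samplingRateHz))
})

setMethod("show", "DEFeatureMatrix", function(object) {
  d <- dim(object@values)
  cat(sprintf(
    "DEFeatureMatrix: %d window(s) x %d ch x %d band(s) [nats, method=%s]\n",
    d[1], d[2], d[3], object@method))
})

setMethod("show", "Encoder", function(object) {
  cat(sprintf("Encoder: %d -> %s -> %d (tanh hidden, linear output)\n",
              object@inputDim,
              if (length(object@hiddenSizes))
                paste(object@hiddenSizes, collapse = " -> ") else "(none)",
              object@embeddingDim))
})

setMethod("show", "ContextModel", function(object) {
  cat(sprintf("ContextModel: single tanh recurrence, %d -> %d\n",
              ncol(object@U), nrow(object@U)))
})

setMethod("show", "SSLModel", function(object) {
  cat(sprintf("SSLModel: task=%s, D=%d, %d training epoch(s)\n",
              object@task, object@encoder@embeddingDim,
              nrow(object@history)))
  if (nrow(object@history))
    cat(sprintf("  loss: %.4f (first) -> %.4f (final)\n",
                object@history$loss[1],
                object@history$loss[nrow(object@history)]))
})

setMethod("show", "EvalReport", function(object) {
  cat(sprintf(
    "EvalReport [%s]: %d-fold CV, label fraction %.2f\n  accuracy %.2f%% (sd %.2f), macro F1 %.2f%% (sd %.2f)\n",
    object@method, object@nFolds, object@labelFraction,
    mean(object@foldAccuracy), stats::sd(object@foldAccuracy),
    mean(object@foldF1), stats::sd(object@foldF1)))
})
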