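# End-to-end orchestration: generate -> features -> pretrain -> evaluate ->
# compare, driven by one configuration (R list or YAML file), with per-stage
# seeds derived from one master seed and a JSON run manifest hashing every
# artifact.

pipelineSchema <- list(
  top = c("seed", "outDir", "dataset", "features", "pretrain", "evaluate",
          "compare"),
  dataset = c("type", "nSubjects", "nTrialsPerSubject", "trialDurationS",
              "nChannels", "samplingRateHz", "nClasses", "noiseSd",
              "modDepth", "modTimescaleS"),
  features = c("windowLength", "method"),
  pretrain = c("task", "epochs", "lr", "embeddingDim", "hiddenSizes",
               "contextLength", "predictionSteps", "negatives",
               "tauPosWindows", "tauNegWindows", "nSamples"),
  evaluate = c("nFolds", "labelFraction", "mode", "includeRandomInit",
               "includeChance"),
  compare = c("enabled"))

checkSchema <- function(config) {
  bad <- setdiff(names(config), pipelineSchema$top)
  if (length(bad))
    stop(sprintf("unknown config field: %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  for (sec in intersect(names(config), names(pipelineSchema)[-1])) {
    bad <- setdiff(names(config[[sec]]), pipelineSchema[[sec]])
    if (length(bad))
      stop(sprintf("unknown config field: %s.%s", sec,
                   paste(bad, collapse = ", ")), call. = FALSE)
  }
  task <- config$pretrain$task
  if (!is.null(task) && !task %in% c("rp", "ts", "cpc"))
    stop(sprintf("unknown task name in pretrain.task: '%s'", task),
         call. = FALSE)
  dtype <- config$dataset$type
  if (!is.null(dtype) && !dtype %in% c("structured", "whitenoise"))
    stop(sprintf("unknown dataset type in dataset.type: '%s'", dtype),
         call. = FALSE)
  invisible(TRUE)
}

#' A small demonstration configuration
#'
#' Two subjects, nine 20-s trials each over three classes, CPC pretraining
#' and a 6-fold probe evaluation on 30% of the labels; runs in about a
#' minute on one CPU.
#'
#' @return a pipeline configuration list for [runPipeline()].
#' @export
demoConfig <- function() {
  list(seed = 1L,
       dataset = list(type = "structured", nSubjects = 2L,
                      nTrialsPerSubject = 9L, trialDurationS = 20,
                      nChannels = 4L, nClasses = 3L),
       features = list(method = "filter"),
       pretrain = list(task = "cpc", epochs = 8L, embeddingDim = 8L,
                       contextLength = 6L, predictionSteps = 2L,
                       negatives = 7L),
       evaluate = list(nFolds = 6L, labelFraction = 0.3,
                       includeRandomInit = TRUE, includeChance = TRUE),
       compare = list(enabled = TRUE))
}

scaleColumns <- function(x) {
  mu <- colMeans(x)
  sg <- apply(x, 2L, sd)
  sg[sg == 0 | !is.finite(sg)] <- 1
  sweep(sweep(x, 2L, mu), 2L, sg, "/")
}

writeFeatureContainer <- function(fa, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  con <- file(file.path(dir, "features.bin"), "wb")
  writeBin(as.numeric(t(fa$x)), con, size = 4L, endian = "little")
  close(con)
  jsonlite::write_json(
    list(format = "ssleeg-features-v1", dtype = "float32le",
         order = "row-major", nWindows = nrow(fa$x), nFeatures = ncol(fa$x),
         trial = fa$trial, label = fa$label, subject = fa$subject,
         start = fa$start),
    file.path(dir, "features_manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Run the full self-supervised pipeline
#'
#' Executes, in order: synthetic dataset generation, DE feature extraction,
#' pretext pretraining (rp / ts / cpc), downstream probe evaluation (with
#' optional random-initialization and chance baselines) and pairwise method
#' comparison. Artifacts are written under `outDir` and hashed into the run
#' manifest (`manifest.json`); rerunning an identical config reproduces
#' identical hashes for every deterministic artifact.
#'
#' @param config a configuration list (see [demoConfig()]) or the path to a
#'   YAML file holding one. Unknown fields are rejected.
#' @param outDir output directory (overrides `config$outDir`; default a
#'   fresh temporary directory).
#' @return the run manifest, invisibly; its `reports` element carries the
#'   [EvalReport-class] objects and `comparison` the Wilcoxon table.
#' @export
runPipeline <- function(config, outDir = NULL) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  checkSchema(config)
  seed <- as.integer(config$seed %||% 1L)
  if (is.null(outDir)) outDir <- config$outDir %||% tempfile("ssleeg_run_")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(started = format(Sys.time(), tz = "UTC"),
                   config = config, seeds = list(master = seed),
                   versions = list(
                     R = paste(R.version$major, R.version$minor, sep = "."),
                     ssleeg = as.character(utils::packageVersion("ssleeg"))),
                   artifacts = list())
  addArtifact <- function(name, path) {
    files <- if (dir.exists(path))
      list.files(path, full.names = TRUE) else path
    manifest$artifacts[[name]] <<- list(
      path = path, md5 = unname(tools::md5sum(sort(files))))
  }
  stageMsg <- function(s) message(sprintf("[ssleeg:%s] running", s))

  # -- stage 1: generate ----------------------------------------------------
  stageMsg("generate")
  ds <- config$dataset %||% list()
  dsType <- ds$type %||% "structured"
  ds$type <- NULL
  ds$seed <- deriveSeed(seed, 1L)
  manifest$seeds$generate <- ds$seed
  scfg <- do.call(if (dsType == "whitenoise") whiteNoiseConfig
                  else synthConfig, ds)
  recordings <- generateDataset(scfg)
  writeDataset(recordings, file.path(outDir, "dataset"))
  addArtifact("dataset", file.path(outDir, "dataset"))

  # -- stage 2: features ----------------------------------------------------
  stageMsg("features")
  fcfg <- config$features %||% list()
  wl <- as.integer(fcfg$windowLength %||% round(scfg@samplingRateHz))
  method <- fcfg$method %||% "filter"
  feList <- lapply(recordings, extractDEFeatures, windowLength = wl,
                   method = method)
  fa <- assembleFeatures(feList)
  xScaled <- scaleColumns(fa$x)
  writeFeatureContainer(fa, file.path(outDir, "features"))
  addArtifact("features", file.path(outDir, "features"))

  # -- stage 3: pretrain ----------------------------------------------------
  pcfg <- config$pretrain %||% list()
  task <- pcfg$task %||% "cpc"
  stageMsg(paste0("pretrain:", task))
  embeddingDim <- as.integer(pcfg$embeddingDim %||% 16L)
  hiddenSizes <- as.integer(pcfg$hiddenSizes %||% 32L)
  preSeed <- deriveSeed(seed, 3L)
  manifest$seeds$pretrain <- preSeed
  encoder <- initEncoder(ncol(fa$x), hiddenSizes, embeddingDim,
                         seed = preSeed)
  if (task == "cpc") {
    ccfg <- cpcConfig(
      predictionSteps = as.integer(pcfg$predictionSteps %||% 4L),
      negatives = as.integer(pcfg$negatives %||% 7L),
      contextLength = as.integer(pcfg$contextLength %||% 16L),
      epochs = as.integer(pcfg$epochs %||% 30L),
      lr = pcfg$lr %||% 5e-3, seed = preSeed)
    model <- trainCPC(xScaled, fa$trial, encoder, config = ccfg)
  } else {
    scfg2 <- rpSamplerConfig(
      nSamples = as.integer(pcfg$nSamples %||% 2000L), windowLength = wl,
      tauPos = as.integer(pcfg$tauPosWindows %||% 3L) * wl,
      tauNeg = as.integer(pcfg$tauNegWindows %||% 15L) * wl,
      seed = preSeed)
    trainer <- if (task == "rp") trainRP else trainTS
    model <- trainer(xScaled, fa$trial, fa$start, encoder, scfg2,
                     epochs = as.integer(pcfg$epochs %||% 30L),
                     lr = pcfg$lr %||% 0.01)
  }
  saveCheckpoint(model, file.path(outDir, "model.rds"))
  addArtifact("model", file.path(outDir, "model.rds"))

  # -- stage 4: evaluate ----------------------------------------------------
  stageMsg("evaluate")
  ecfg <- config$evaluate %||% list()
  nFolds <- as.integer(ecfg$nFolds %||% 10L)
  labelFraction <- ecfg$labelFraction %||% 1
  mode <- ecfg$mode %||% "probe"
  evalSeed <- deriveSeed(seed, 4L)
  manifest$seeds$evaluate <- evalSeed
  zPre <- encode(model@encoder, xScaled)
  reports <- list(crossvalEvaluate(zPre, fa$label, fa$trial, method = mode,
                                   encoder = if (mode == "finetune")
                                     model@encoder else NULL,
                                   nFolds = nFolds,
                                   labelFraction = labelFraction,
                                   seed = evalSeed,
                                   methodName = paste0(task, "_probe")))
  if (isTRUE(ecfg$includeRandomInit %||% TRUE)) {
    rnd <- initEncoder(ncol(fa$x), hiddenSizes, embeddingDim,
                       seed = deriveSeed(seed, 5L))
    reports <- c(reports, list(
      crossvalEvaluate(encode(rnd, xScaled), fa$label, fa$trial,
                       method = "probe", nFolds = nFolds,
                       labelFraction = labelFraction, seed = evalSeed,
                       methodName = "randominit_probe")))
  }
  if (isTRUE(ecfg$includeChance %||% TRUE)) {
    reports <- c(reports, list(
      crossvalEvaluate(zPre, fa$label, fa$trial, method = "random",
                       nFolds = nFolds, seed = evalSeed,
                       methodName = "chance")))
  }
  reportJson <- lapply(reports, function(r)
    list(method = r@method, foldAccuracy = r@foldAccuracy,
         foldF1 = r@foldF1, meanAccuracy = mean(r@foldAccuracy),
         meanF1 = mean(r@foldF1), labelFraction = r@labelFraction,
         seed = r@seed, fingerprint = r@fingerprint))
  jsonlite::write_json(reportJson, file.path(outDir, "reports.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  addArtifact("reports", file.path(outDir, "reports.json"))

  # -- stage 5: compare -----------------------------------------------------
  comparison <- NULL
  if (isTRUE((config$compare %||% list())$enabled %||% TRUE) &&
      length(reports) >= 2L) {
    stageMsg("compare")
    comparison <- tryCatch(compareMethods(reports),
                           error = function(e) {
                             message("[ssleeg:compare] skipped: ",
                                     conditionMessage(e))
                             NULL
                           })
    if (!is.null(comparison)) {
      utils::write.csv(comparison, file.path(outDir, "comparison.csv"),
                       row.names = FALSE)
      addArtifact("comparison", file.path(outDir, "comparison.csv"))
    }
  }

  manifest$finished <- format(Sys.time(), tz = "UTC")
  core <- manifest[c("config", "seeds", "versions", "artifacts")]
  jsonlite::write_json(core, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest$reports <- reports
  manifest$comparison <- comparison
  manifest$outDir <- outDir
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
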