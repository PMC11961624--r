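# Orchestration: one configuration drives simulate -> localize/crop ->
# preprocess -> train (anomaly, then origin/risk by transfer) ->
# predict -> evaluate, with per-stage artifact caching so a deleted
# stage re-executes and downstream results are reproducible from
# (config, masterSeed).

#' Pipeline configuration
#'
#' Nested configuration for the full phantom-to-report pipeline. Any
#' subset can be overridden; unspecified fields keep their defaults.
#' Every stochastic stage derives its seed deterministically from
#' masterSeed.
#'
#' @param nCases cohort size.
#' @param classMix named stratum proportions (see [cohortConfigs()]).
#' @param phantom a [phantomConfig()] template.
#' @param testFraction patient-wise held-out test fraction.
#' @param prep a [preprocessConfig()]; its targetDims must match the
#'   network input.
#' @param net a [networkConfig()].
#' @param train a [trainConfig()].
#' @param tasks which tasks to train ("anomaly" always; "origin"/"risk"
#'   fine-tuned from the anomaly backbone).
#' @param cutoff decision cutoff for reports.
#' @param nBoot bootstrap iterations for report CIs.
#' @param outputRoot artifact directory (NULL: nothing written).
#' @param runId run identifier.
#' @param masterSeed master seed.
#' @return list of class "PipelineConfig".
#' @export
pipelineConfig <- function(nCases = 60L,
                           classMix = c(normal = 0.5,
                                        `R-AAOCA/interarterial` = 0.1,
                                        `L-AAOCA/subpulmonic` = 0.1,
                                        `R-AAOCA/prepulmonic` = 0.1,
                                        `L-AAOCA/retroaortic` = 0.1,
                                        `R-AAOCA/high_takeoff` = 0.1),
                           phantom = phantomConfig(),
                           testFraction = 0.25,
                           prep = preprocessConfig(targetDims = c(64L, 64L, 48L),
                                                   splineOrder = 1L),
                           net = networkConfig("tiny"),
                           train = trainConfig(totalEpochs = 15L,
                                               patience = 15L,
                                               nMembers = 3L),
                           tasks = c("anomaly", "origin", "risk"),
                           cutoff = 0.5, nBoot = 200L,
                           outputRoot = NULL, runId = "run1",
                           masterSeed = 1L) {
  structure(list(nCases = as.integer(nCases), classMix = classMix,
                 phantom = phantom, testFraction = testFraction,
                 prep = prep, net = net, train = train, tasks = tasks,
                 cutoff = cutoff, nBoot = as.integer(nBoot),
                 outputRoot = outputRoot, runId = runId,
                 masterSeed = as.integer(masterSeed)),
            class = "PipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields override [pipelineConfig()] defaults; nested blocks
#' (phantom, prep, net, train) are passed to their constructors.
#'
#' @param path YAML file.
#' @return a "PipelineConfig".
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  for (nm in c("nCases", "testFraction", "tasks", "cutoff", "nBoot",
               "outputRoot", "runId", "masterSeed"))
    if (!is.null(y[[nm]])) args[[nm]] <- y[[nm]]
  if (!is.null(y$classMix)) args$classMix <- unlist(y$classMix)
  if (!is.null(y$phantom)) args$phantom <- do.call(phantomConfig, y$phantom)
  if (!is.null(y$prep)) args$prep <- do.call(preprocessConfig, y$prep)
  if (!is.null(y$net)) args$net <- do.call(networkConfig, y$net)
  if (!is.null(y$train)) args$train <- do.call(trainConfig, y$train)
  do.call(pipelineConfig, args)
}

#' Build the preprocessed tensor dataset for a phantom cohort
#'
#' For each generated case: locate the aortic root (from the ground-truth
#' label map, or [naiveSegment()] when useNaiveSegmentation), crop the
#' physical box from every phase, preprocess to the network input tensor.
#' Full-resolution volumes are discarded case by case, keeping memory at
#' the crop scale.
#'
#' @param config a "PipelineConfig".
#' @param useNaiveSegmentation segment with [naiveSegment()] instead of
#'   the ground-truth label map.
#' @return dataset list(tensors, caseId, manifest) as consumed by
#'   [trainTask()], with the tensor spacing attached as an attribute.
#' @export
cohortTensors <- function(config, useNaiveSegmentation = FALSE) {
  cfgs <- cohortConfigs(config$nCases, config$classMix, config$phantom,
                        seed = .deriveSeed(config$masterSeed, 1L))
  tensors <- list(); caseId <- character(0); rows <- list()
  for (cc in cfgs) {
    rec <- generatePhantom(cc$config)
    lm <- if (useNaiveSegmentation) naiveSegment(rec@volumes[[1]])
          else rec@labelMap
    rp <- findRootPoint(structureMask(lm, "aorta"),
                        structureMask(lm, "lv_myocardium") |
                          structureMask(lm, "lv_cavity"),
                        spacing = spacing(lm), origin = origin(lm))
    box <- computeCropBox(rp, lm)
    for (v in rec@volumes) {
      crop <- cropVolume(v, box)
      tensors[[length(tensors) + 1L]] <- preprocessVolume(crop, config$prep)
      caseId <- c(caseId, cc$caseId)
    }
    rows[[length(rows) + 1L]] <-
      data.frame(case_id = cc$caseId, y_anomaly = rec@yAnomaly,
                 y_origin = rec@yOrigin, y_risk = rec@yRisk,
                 course = rec@course, group = cc$group$sex,
                 stringsAsFactors = FALSE)
  }
  ds <- list(tensors = tensors, caseId = caseId,
             manifest = do.call(rbind, rows))
  cropSpacing <- dim(tensors[[1]])
  attr(ds, "spacingMm") <- c(80, 80, 60) / cropSpacing
  ds
}

.subsetDataset <- function(ds, ids) {
  sel <- ds$caseId %in% ids
  out <- list(tensors = ds$tensors[sel], caseId = ds$caseId[sel],
              manifest = ds$manifest[ds$manifest$case_id %in% ids, ])
  attr(out, "spacingMm") <- attr(ds, "spacingMm")
  out
}

.stageCached <- function(dir, name, expr) {
  if (is.null(dir)) return(expr)
  f <- file.path(dir, paste0(name, ".rds"))
  if (file.exists(f)) return(readRDS(f))
  val <- expr
  saveRDS(val, f)
  val
}

#' Run the full phantom pipeline end to end
#'
#' Generates the phantom cohort, holds out a patient-wise test set, trains
#' the anomaly-detection ensemble (and fine-tunes the origin/risk models
#' from its backbone on the AAOCA-positive subset), predicts the test set
#' and writes metric reports. All artifacts are reproducible from
#' (config, masterSeed); with an outputRoot each stage's artifact is
#' cached and re-executed only when missing.
#'
#' @param config a [pipelineConfig()] or a YAML path.
#' @param verbose print training progress.
#' @return list with dataset manifest, split, trained tasks, prediction
#'   sets, metric reports, and the run summary.
#' @export
runEndToEnd <- function(config = pipelineConfig(), verbose = FALSE) {
  if (is.character(config)) config <- readPipelineConfig(config)
  outDir <- if (!is.null(config$outputRoot))
    file.path(config$outputRoot, config$runId) else NULL
  if (!is.null(outDir)) dir.create(outDir, recursive = TRUE,
                                   showWarnings = FALSE)
  stage <- function(name, expr) {
    t0 <- Sys.time()
    val <- tryCatch(.stageCached(outDir, name, expr),
                    error = function(e)
                      stop("pipeline stage '", name, "' failed: ",
                           conditionMessage(e), call. = FALSE))
    if (verbose)
      message(sprintf("[%s] %.1fs", name,
                      as.numeric(Sys.time() - t0, units = "secs")))
    val
  }

  ds <- stage("cohort", cohortTensors(config))
  allIds <- unique(ds$caseId)
  holdout <- stage("split", splitPatientwise(
    allIds, 1 - config$testFraction,
    seed = .deriveSeed(config$masterSeed, 2L)))
  trainDs <- .subsetDataset(ds, holdout$train)
  testDs <- .subsetDataset(ds, holdout$val)

  trained <- list()
  tc <- config$train
  tc$seed <- .deriveSeed(config$masterSeed, 3L)
  trained$anomaly <- stage("train_anomaly",
    trainTask(trainDs, "anomaly", config$net, tc, verbose = verbose))
  for (task in intersect(config$tasks, c("origin", "risk"))) {
    tcf <- config$train
    tcf$seed <- .deriveSeed(config$masterSeed, 4L + match(task, config$tasks))
    trained[[task]] <- stage(paste0("train_", task),
      fineTune(trained$anomaly, trainDs, task, tcf, verbose = verbose))
  }

  predictions <- list(); reports <- list(); sweeps <- list()
  for (task in names(trained)) {
    labs <- taskLabels(testDs$manifest, task)
    keep <- names(labs)[!is.na(labs)]
    sel <- testDs$caseId %in% keep
    probs <- predictTensors(trained[[task]], testDs$tensors[sel])
    # aggregate phases per case, then ensemble over members
    agg <- rowsum(probs, testDs$caseId[sel]) /
      as.vector(table(testDs$caseId[sel])[sort(unique(testDs$caseId[sel]))])
    ps <- predictionSet(agg, rownames(agg), task = task,
                        yTrue = labs[rownames(agg)])
    predictions[[task]] <- ps
    reports[[task]] <- metricsReport(ps@ensembleProb, ps@yTrue,
                                     cutoff = config$cutoff,
                                     nBoot = config$nBoot,
                                     seed = .deriveSeed(config$masterSeed, 9L))
    sweeps[[task]] <- cutoffSweep(ps@ensembleProb, ps@yTrue)
  }

  summary <- list(runId = config$runId, masterSeed = config$masterSeed,
                  nCases = config$nCases,
                  configHash = .configHash(config),
                  rVersion = as.character(getRversion()),
                  layerCount = trained$anomaly$members[[1]]$layerCount,
                  metrics = lapply(reports, function(r)
                    setNames(r$value, r$metric)))
  if (!is.null(outDir)) {
    write.csv(ds$manifest, file.path(outDir, "manifest.csv"),
              row.names = FALSE)
    write.csv(trained$anomaly$history,
              file.path(outDir, "history_anomaly.csv"), row.names = FALSE)
    for (task in names(reports)) {
      write.csv(reports[[task]],
                file.path(outDir, sprintf("metrics_%s.csv", task)),
                row.names = FALSE)
      write.csv(sweeps[[task]],
                file.path(outDir, sprintf("cutoff_sweep_%s.csv", task)),
                row.names = FALSE)
    }
    jsonlite::write_json(summary, file.path(outDir, "run_summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  list(config = config, manifest = ds$manifest, split = holdout,
       trained = trained, predictions = predictions, reports = reports,
       sweeps = sweeps, summary = summary)
}

.configHash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(unclass(config)[setdiff(names(config), "outputRoot")], f)
  unname(tools::md5sum(f))
}

#' Screen a cohort for coronary anomalies
#'
#' Mirrors the conditional task cascade: every case gets an anomaly
#' probability; cases flagged at the cutoff (default 0.5) additionally
#' get origin and risk probabilities, and a ranked review list for human
#' confirmation is emitted. Set alwaysEvaluate to score all heads on all
#' cases.
#'
#' @param trained named list of "TrainedTask" objects; "anomaly" is
#'   required, "origin"/"risk" optional.
#' @param cases list of [CaseRecord-class] to screen.
#' @param prepConfig a [preprocessConfig()] matching the network input.
#' @param cutoff flag threshold on the ensemble anomaly probability.
#' @param alwaysEvaluate evaluate origin/risk heads on unflagged cases
#'   too.
#' @return data.frame sorted by descending anomaly probability with
#'   columns caseId, pAnomaly, flagged, pLeftOrigin, pHighRisk.
#' @export
runScreening <- function(trained, cases, prepConfig,
                         cutoff = 0.5, alwaysEvaluate = FALSE) {
  if (is.null(trained$anomaly))
    stop("missing checkpoint for the anomaly task")
  psA <- predictCases(trained$anomaly, cases, prepConfig)
  flagged <- psA@ensembleProb >= cutoff
  out <- data.frame(caseId = psA@caseId, pAnomaly = psA@ensembleProb,
                    flagged = flagged,
                    pLeftOrigin = NA_real_, pHighRisk = NA_real_)
  sel <- if (alwaysEvaluate) rep(TRUE, length(cases)) else flagged
  if (any(sel)) {
    for (task in intersect(names(trained), c("origin", "risk"))) {
      ps <- predictCases(trained[[task]], cases[sel], prepConfig)
      col <- if (task == "origin") "pLeftOrigin" else "pHighRisk"
      out[[col]][sel] <- ps@ensembleProb
    }
  }
  out[order(-out$pAnomaly), ]
}
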