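# Training: cosine-annealed Adam on binary cross entropy with early
# stopping, patient-wise 90:10 splitting, a 5-member seed ensemble sharing
# one split, transfer from the anomaly-detection backbone for the origin
# and risk tasks, and phase/member-averaged prediction.

#' Cosine annealing learning-rate schedule
#'
#' lr(epoch) = lr0 * (1 + cos(pi * epoch / totalEpochs)) / 2, so training
#' starts at lr0 (default 0.001) and anneals to 0 at totalEpochs.
#'
#' @param epoch current epoch, 0 <= epoch <= totalEpochs.
#' @param totalEpochs schedule length.
#' @param lr0 initial learning rate.
#' @return the learning rate.
#' @export
cosineLR <- function(epoch, totalEpochs, lr0 = 0.001) {
  if (any(epoch < 0 | epoch > totalEpochs))
    stop("epoch must lie in [0, totalEpochs]")
  lr0 * (1 + cos(pi * epoch / totalEpochs)) / 2
}

#' Patient-wise train/validation split
#'
#' Splits patients (not images) so all phases of one patient fall on one
#' side; |validation| = round((1 - ratio) * nPatients).
#'
#' @param caseIds character vector of case ids (one per patient, or with
#'   repeats which are collapsed).
#' @param ratio training fraction (default 0.9).
#' @param seed RNG seed; same seed gives the identical split.
#' @param strata optional per-patient class labels (named by case id);
#'   when given, the validation draw is stratified so each class with at
#'   least two patients is represented on both sides.
#' @return list(train, val) of case ids.
#' @export
splitPatientwise <- function(caseIds, ratio = 0.9, seed = 1L,
                             strata = NULL) {
  ids <- unique(caseIds)
  if (length(ids) < 2L) stop("need at least 2 patients to split")
  nVal <- round((1 - ratio) * length(ids))
  nVal <- min(max(nVal, 1L), length(ids) - 1L)
  val <- .withSeed(seed, {
    if (is.null(strata)) sample(ids, nVal)
    else {
      groups <- split(ids, as.character(strata[ids]))
      sizes <- vapply(groups, length, 0L)
      take <- pmin(pmax(.largestRemainder(nVal, sizes),
                        ifelse(sizes >= 2L, 1L, 0L)),
                   pmax(sizes - 1L, 0L))
      unlist(Map(function(g, k) if (k > 0) sample(g, k) else character(0),
                 groups, take), use.names = FALSE)
    }
  })
  list(train = setdiff(ids, val), val = val)
}

#' Training configuration
#'
#' @param lr0 initial learning rate (default 0.001).
#' @param totalEpochs cosine schedule length and maximum epochs (full-scale
#'   setting 300; reduce for desk-scale runs).
#' @param patience early-stopping patience on validation loss (epochs).
#' @param splitRatio patient-wise train fraction (default 0.9).
#' @param nMembers ensemble members sharing one split, differing only in
#'   their initialisation seed (default 5).
#' @param memberSeeds optional explicit member seeds.
#' @param batchSize minibatch size.
#' @param seed master seed for the split and epoch shuffles.
#' @param augment optional [augmentationConfig()] applied to training
#'   tensors.
#' @param pretrainedFrom optional trained task (see [trainTask()]) whose
#'   member backbones initialise this task's members (task cascade).
#' @param weightDecay L2 penalty on weight matrices.
#' @return list of class "TrainConfig".
#' @export
trainConfig <- function(lr0 = 0.001, totalEpochs = 300L, patience = 20L,
                        splitRatio = 0.9, nMembers = 5L, memberSeeds = NULL,
                        batchSize = 8L, seed = 1L, augment = NULL,
                        pretrainedFrom = NULL, weightDecay = 0) {
  if (is.null(memberSeeds))
    memberSeeds <- vapply(seq_len(nMembers), function(m)
      .deriveSeed(seed, 5000L + m), 0L)
  if (length(memberSeeds) != nMembers)
    stop("memberSeeds must have nMembers entries")
  structure(list(lr0 = lr0, totalEpochs = as.integer(totalEpochs),
                 patience = as.integer(patience), splitRatio = splitRatio,
                 nMembers = as.integer(nMembers),
                 memberSeeds = as.integer(memberSeeds),
                 batchSize = as.integer(batchSize), seed = as.integer(seed),
                 augment = augment, pretrainedFrom = pretrainedFrom,
                 weightDecay = weightDecay),
            class = "TrainConfig")
}

#' Per-case labels for one classification task
#'
#' anomaly: 1 = AAOCA, 0 = normal. origin: 1 = left (L-AAOCA),
#' 0 = right (R-AAOCA), NA for normals. risk: 1 = high, 0 = low, NA for
#' normals. Cases with NA are excluded from the task, restricting the
#' origin/risk tasks to the AAOCA-positive subset.
#'
#' @param manifest data.frame with case_id, y_anomaly, y_origin, y_risk.
#' @param task "anomaly", "origin" or "risk".
#' @return named integer vector over manifest$case_id.
#' @export
taskLabels <- function(manifest, task = c("anomaly", "origin", "risk")) {
  task <- match.arg(task)
  y <- switch(task,
    anomaly = as.integer(manifest$y_anomaly),
    origin = ifelse(is.na(manifest$y_origin), NA_integer_,
                    as.integer(manifest$y_origin == "left")),
    risk = ifelse(is.na(manifest$y_risk), NA_integer_,
                  as.integer(manifest$y_risk == "high")))
  setNames(y, manifest$case_id)
}

# checkpoint selection: lowest validation loss, ties broken by higher
# validation accuracy, then by the earlier epoch.
.selectCheckpoint <- function(valLoss, valAcc) {
  ord <- order(valLoss, -valAcc, seq_along(valLoss))
  ord[1]
}

# early stopping: TRUE once the best validation loss is `patience` epochs
# in the past.
.shouldStop <- function(valLoss, patience) {
  length(valLoss) - which.min(valLoss) >= patience
}

.evalSet <- function(model, tensors, y, batchSize = 16L) {
  n <- length(tensors)
  probs <- numeric(n)
  for (b in split(seq_len(n), ceiling(seq_len(n) / batchSize))) {
    f <- netForward(model, stackTensors(tensors[b]), training = FALSE,
                    keepCaches = FALSE)
    probs[b] <- f$prob
  }
  list(probs = probs, loss = bceLoss(probs, y)$loss,
       acc = mean((probs >= 0.5) == (y == 1)))
}

# initialise a member model: fresh Kaiming build, or the pretrained
# backbone with a re-initialised classification head.
.initMember <- function(netConfig, seed, pretrained = NULL, member = 1L) {
  if (is.null(pretrained)) return(buildNetwork(netConfig, seed))
  src <- pretrained$members[[min(member, length(pretrained$members))]]
  if (!identical(src$config$blocksPerStage, netConfig$blocksPerStage) ||
      !identical(src$config$baseChannels, netConfig$baseChannels))
    stop("pretrained network architecture does not match netConfig")
  model <- src
  set.seed(seed)
  cin <- model$featureWidth
  model$layers$fc <- .newFC(cin, netConfig$nOutputs)
  model
}

#' Fit a network on a fixed tensor set (no splitting, no early stopping)
#'
#' Minimal training loop used for overfit sanity checks and toy
#' experiments: Adam on BCE under the cosine schedule over all provided
#' tensors.
#'
#' @param model a [buildNetwork()] model.
#' @param tensors list of 3D tensors.
#' @param y binary labels, one per tensor.
#' @param epochs training epochs (cosine schedule length).
#' @param lr0 initial learning rate.
#' @param batchSize minibatch size.
#' @param seed RNG seed for shuffling.
#' @return list(model, loss = per-epoch mean training loss).
#' @export
fitNetwork <- function(model, tensors, y, epochs = 50L, lr0 = 0.001,
                       batchSize = 8L, seed = 1L) {
  state <- list()
  losses <- numeric(epochs)
  for (epoch in seq_len(epochs)) {
    lr <- cosineLR(epoch - 1L, epochs, lr0)
    set.seed(.deriveSeed(seed, epoch))
    ord <- sample(length(tensors))
    tot <- 0; nb <- 0L
    for (b in split(ord, ceiling(seq_along(ord) / batchSize))) {
      f <- netForward(model, stackTensors(tensors[b]), training = TRUE)
      model <- f$model
      l <- bceLoss(f$prob, y[b])
      bw <- netBackward(model, f$caches, l$dlogit)
      st <- .adamStep(model, bw$grads, state, lr)
      model <- st$model; state <- st$state
      tot <- tot + l$loss; nb <- nb + 1L
    }
    losses[epoch] <- tot / nb
  }
  list(model = model, loss = losses)
}

#' Train one classification task
#'
#' Trains nMembers networks on the patient-wise split (shared by all
#' members; members differ only in their initialisation seed), with BCE
#' loss, Adam under the cosine schedule, optional augmentation, early
#' stopping on validation loss, and checkpoint selection by lowest
#' validation loss with validation accuracy as the tie-break.
#'
#' @param dataset list(tensors = list of 3D arrays, caseId = character
#'   per tensor, manifest = per-case data.frame with case_id, y_anomaly,
#'   y_origin, y_risk).
#' @param task "anomaly", "origin" or "risk"; origin/risk are trained on
#'   the AAOCA-positive subset only.
#' @param netConfig a [networkConfig()].
#' @param config a [trainConfig()].
#' @param verbose print per-epoch progress.
#' @return list of class "TrainedTask": members (best models), history
#'   (data.frame), split, task, netConfig, trainConfig.
#' @export
trainTask <- function(dataset, task, netConfig = networkConfig(),
                      config = trainConfig(), verbose = FALSE) {
  task <- match.arg(task, c("anomaly", "origin", "risk"))
  labs <- taskLabels(dataset$manifest, task)
  keep <- names(labs)[!is.na(labs)]
  sel <- dataset$caseId %in% keep
  tensors <- dataset$tensors[sel]
  caseId <- dataset$caseId[sel]
  split <- splitPatientwise(keep, config$splitRatio,
                            seed = .deriveSeed(config$seed, 11L),
                            strata = labs[keep])
  y <- as.numeric(labs[caseId])
  isTrain <- caseId %in% split$train
  for (part in list(y[isTrain], y[!isTrain]))
    if (length(unique(part)) < 2L)
      stop("stratification error: a split partition has a single class for task '",
           task, "'")
  trX <- tensors[isTrain]; trY <- y[isTrain]
  vaX <- tensors[!isTrain]; vaY <- y[!isTrain]
  sp <- attr(dataset, "spacingMm") %||% c(1, 1, 1)

  members <- vector("list", config$nMembers)
  hist <- list()
  for (m in seq_len(config$nMembers)) {
    model <- .initMember(netConfig, config$memberSeeds[m],
                         config$pretrainedFrom, m)
    state <- list()
    best <- NULL; valLoss <- valAcc <- numeric(0)
    if (config$totalEpochs == 0L) best <- model
    for (epoch in seq_len(config$totalEpochs)) {
      lr <- cosineLR(epoch - 1L, config$totalEpochs, config$lr0)
      set.seed(.deriveSeed(config$seed, m * 100000L + epoch))
      ord <- sample(length(trX))
      epochLoss <- 0; nb <- 0L
      for (b in split(ord, ceiling(seq_along(ord) / config$batchSize))) {
        bx <- trX[b]
        if (!is.null(config$augment))
          bx <- lapply(bx, augmentTensor, config = config$augment,
                       spacingMm = sp)
        f <- netForward(model, stackTensors(bx), training = TRUE)
        model <- f$model
        l <- bceLoss(f$prob, trY[b])
        bw <- netBackward(model, f$caches, l$dlogit)
        st <- .adamStep(model, bw$grads, state, lr,
                        weightDecay = config$weightDecay)
        model <- st$model; state <- st$state
        epochLoss <- epochLoss + l$loss; nb <- nb + 1L
      }
      ev <- .evalSet(model, vaX, vaY, config$batchSize)
      valLoss <- c(valLoss, ev$loss); valAcc <- c(valAcc, ev$acc)
      if (.selectCheckpoint(valLoss, valAcc) == epoch) best <- model
      hist[[length(hist) + 1L]] <-
        data.frame(member = m, epoch = epoch, lr = lr,
                   trainLoss = epochLoss / nb, valLoss = ev$loss,
                   valAcc = ev$acc)
      if (verbose)
        message(sprintf("member %d epoch %3d lr %.5f train %.4f val %.4f acc %.3f",
                        m, epoch, lr, epochLoss / nb, ev$loss, ev$acc))
      if (.shouldStop(valLoss, config$patience)) break
    }
    members[[m]] <- best
  }
  structure(list(task = task, members = members,
                 history = do.call(rbind, hist), split = split,
                 netConfig = netConfig, trainConfig = config),
            class = "TrainedTask")
}

#' Fine-tune a pretrained task on another task (cascade transfer)
#'
#' Initialises every member from the corresponding anomaly-detection
#' member's backbone with a freshly initialised classification head, then
#' trains exactly as [trainTask()]. With totalEpochs = 0 the returned
#' members are the pretrained backbones with fresh heads (no training).
#'
#' @param pretrained a "TrainedTask" (typically the anomaly model).
#' @param dataset as in [trainTask()].
#' @param task target task ("origin" or "risk").
#' @param config a [trainConfig()].
#' @param verbose print progress.
#' @return a "TrainedTask".
#' @export
fineTune <- function(pretrained, dataset, task, config = trainConfig(),
                     verbose = FALSE) {
  stopifnot(inherits(pretrained, "TrainedTask"))
  config$pretrainedFrom <- pretrained
  if (config$totalEpochs == 0L) {
    members <- lapply(seq_len(config$nMembers), function(m)
      .initMember(pretrained$netConfig, config$memberSeeds[m], pretrained, m))
    return(structure(list(task = task, members = members, history = NULL,
                          split = NULL, netConfig = pretrained$netConfig,
                          trainConfig = config), class = "TrainedTask"))
  }
  trainTask(dataset, task, pretrained$netConfig, config, verbose)
}

#' Member probabilities for a list of tensors
#' @param trained a "TrainedTask" (or list of member models).
#' @param tensors list of 3D tensors.
#' @param batchSize forward batch size.
#' @return n x nMembers matrix of probabilities.
#' @export
predictTensors <- function(trained, tensors, batchSize = 16L) {
  members <- if (inherits(trained, "TrainedTask")) trained$members else trained
  vapply(members, function(mod)
    .evalSet(mod, tensors, rep(0, length(tensors)), batchSize)$probs,
    numeric(length(tensors)))
}

#' Assemble a PredictionSet from member probabilities
#' @param memberProbs cases x members probability matrix.
#' @param caseId case identifiers.
#' @param task task name.
#' @param yTrue optional labels.
#' @return a [PredictionSet-class]; ensembleProb is the member mean.
#' @export
predictionSet <- function(memberProbs, caseId, task = "anomaly",
                          yTrue = NULL) {
  memberProbs <- rbind(memberProbs)
  if (is.null(yTrue)) yTrue <- rep(NA_integer_, length(caseId))
  new("PredictionSet", task = task, caseId = as.character(caseId),
      memberProbs = memberProbs, ensembleProb = rowMeans(memberProbs),
      yTrue = as.integer(yTrue))
}

#' End-to-end per-case ensemble prediction
#'
#' For each case: locate the aortic root from its label map, crop the
#' fixed physical box from every phase volume, preprocess, and run all
#' ensemble members. Per member, multi-phase probabilities are aggregated
#' per case (mean by default); the ensemble probability is the arithmetic
#' mean over members.
#'
#' @param trained a "TrainedTask".
#' @param cases list of [CaseRecord-class].
#' @param prepConfig a [preprocessConfig()] (dims must match the network).
#' @param extentMm crop box physical extent.
#' @param offsetMm root-point offset.
#' @param aggregate multi-phase aggregation, "mean" (default) or "max".
#' @return a [PredictionSet-class].
#' @export
predictCases <- function(trained, cases, prepConfig, extentMm = c(80, 80, 60),
                         offsetMm = c(10, 0, 10),
                         aggregate = c("mean", "max")) {
  aggregate <- match.arg(aggregate)
  stopifnot(length(cases) >= 1)
  tensors <- list(); owner <- integer(0)
  for (i in seq_along(cases)) {
    case <- cases[[i]]
    if (length(case@volumes) < 1L) stop("case ", case@caseId, " has no phases")
    lm <- case@labelMap
    rp <- findRootPoint(structureMask(lm, "aorta"),
                        structureMask(lm, "lv_myocardium") |
                          structureMask(lm, "lv_cavity"),
                        spacing = spacing(lm), origin = origin(lm),
                        offsetMm = offsetMm)
    box <- computeCropBox(rp, lm, extentMm)
    for (v in case@volumes) {
      tensors[[length(tensors) + 1L]] <-
        preprocessVolume(cropVolume(v, box), prepConfig)
      owner <- c(owner, i)
    }
  }
  phaseProbs <- predictTensors(trained, tensors)
  agg <- if (aggregate == "mean") colMeans else function(m) apply(m, 2, max)
  memberProbs <- vapply(seq_along(cases), function(i)
    agg(phaseProbs[owner == i, , drop = FALSE]),
    numeric(ncol(phaseProbs)))
  memberProbs <- if (is.null(dim(memberProbs)))
    matrix(memberProbs, ncol = 1L) else t(memberProbs)
  labs <- vapply(cases, function(cs) switch(trained$task,
    anomaly = cs@yAnomaly,
    origin = if (is.na(cs@yOrigin)) NA_integer_
             else as.integer(cs@yOrigin == "left"),
    risk = if (is.na(cs@yRisk)) NA_integer_
           else as.integer(cs@yRisk == "high")), 0L)
  predictionSet(memberProbs, vapply(cases, function(cs) cs@caseId, ""),
                task = trained$task, yTrue = labs)
}

#' Save / load a trained task checkpoint
#'
#' Weights are serialised per member alongside a JSON sidecar recording
#' the architecture and training configuration.
#'
#' @param trained a "TrainedTask".
#' @param dir checkpoint directory (created).
#' @return the directory, invisibly.
#' @export
saveCheckpoint <- function(trained, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(trained, file.path(dir, "members.rds"))
  sidecar <- list(task = trained$task,
                  netConfig = unclass(trained$netConfig),
                  trainConfig = unclass(trained$trainConfig[
                    setdiff(names(trained$trainConfig), "pretrainedFrom")]),
                  layerCount = trained$members[[1]]$layerCount,
                  nMembers = length(trained$members))
  jsonlite::write_json(sidecar, file.path(dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(dir) readRDS(file.path(dir, "members.rds"))
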