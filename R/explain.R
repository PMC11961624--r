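# Interpretability: Grad-CAM++ volumetric saliency at a selectable
# network stage, penultimate-layer embedding extraction, and 2D t-SNE
# maps of the embedding space. t-SNE is the exact O(n^2) formulation
# (perplexity calibration by binary search, early exaggeration, momentum
# gradient descent), sufficient for cohort-scale embedding sets.

#' SaliencyMap: a Grad-CAM++ volume aligned to the network input
#'
#' Values are non-negative, min-max normalised to [0, 1], on the input
#' tensor grid.
#'
#' @slot sourceBlock the network stage the map was computed from.
#' @export
setClass("SaliencyMap", contains = "ImageVolume",
         representation(sourceBlock = "integer"))

#' Grad-CAM++ saliency for a 3D input
#'
#' Implements the positive higher-order gradient weighting: with A the
#' chosen block's activations and G the gradient of the target logit,
#' alpha = G^2 / (2 G^2 + sum_spatial(A * G^3)), channel weights
#' w_c = sum_spatial(alpha * relu(G)), and the map is
#' relu(sum_c w_c A_c), trilinearly upsampled to the input grid and
#' min-max normalised. A zero-gradient input yields an all-zero map (with
#' a warning).
#'
#' @param model a [buildNetwork()] model (e.g. one ensemble member).
#' @param inputTensor 3D tensor in [0, 1].
#' @param blockIndex network stage (1..nStages) whose last residual block
#'   output is used.
#' @param targetClass 1 (default) explains the positive class, 0 the
#'   negative.
#' @return a [SaliencyMap-class] with the input tensor's shape.
#' @export
gradCamPP <- function(model, inputTensor, blockIndex = 2L, targetClass = 1L) {
  nm <- names(model$layers)
  stage <- grep(sprintf("^stage%d_block", blockIndex), nm)
  if (length(stage) == 0) stop("no such block: ", blockIndex)
  idx <- max(stage)
  f <- netForward(model, inputTensor, training = FALSE, keepCaches = TRUE,
                  keepOuts = TRUE)
  bw <- netBackward(f$model, f$caches, if (targetClass == 1) 1 else -1,
                    captureAt = idx)
  A <- f$outs[[idx]]; G <- bw$captured
  d <- dim(A); S <- prod(d[1:3]); C <- d[4]
  dim(A) <- c(S, C); dim(G) <- c(S, C)
  denom <- 2 * G^2 + rep(colSums(A * G^3), each = S)
  alpha <- ifelse(denom == 0, 0, G^2 / denom)
  w <- colSums(alpha * pmax(G, 0))
  cam <- pmax(as.vector(A %*% w), 0)
  dim(cam) <- d[1:3]
  target <- dim(inputTensor)
  for (a in 1:3)
    cam <- .applyAxis(cam, .interpMatrix(d[a], target[a], order = 1L), a)
  mx <- max(cam)
  if (mx > 0) cam <- pmax(cam, 0) / mx
  else if (all(G == 0))
    warning("zero gradient everywhere: saliency map is all zero")
  new("SaliencyMap", data = cam, spacing = c(1, 1, 1), origin = c(0, 0, 0),
      sourceBlock = as.integer(blockIndex))
}

#' Extract penultimate-layer embeddings
#'
#' Deterministic forward-pass features from the global-average-pooling
#' layer (the last layer before the classification head); labels and
#' metadata are attached only as plotting annotation, never used in the
#' computation.
#'
#' @param model a model or "TrainedTask" (uses `member`).
#' @param tensors list of 3D tensors.
#' @param caseId optional identifiers.
#' @param meta optional data.frame of annotation (labels, dataset tag,
#'   group), one row per tensor.
#' @param member ensemble member index when `model` is a TrainedTask.
#' @param batchSize forward batch size.
#' @return list of class "EmbeddingSet": features (n x width), caseId,
#'   meta.
#' @export
extractEmbeddings <- function(model, tensors, caseId = NULL, meta = NULL,
                              member = 1L, batchSize = 16L) {
  if (inherits(model, "TrainedTask")) model <- model$members[[member]]
  n <- length(tensors)
  feats <- NULL
  for (b in split(seq_len(n), ceiling(seq_len(n) / batchSize))) {
    f <- netForward(model, stackTensors(tensors[b]), training = FALSE,
                    keepCaches = FALSE)
    feats <- rbind(feats, t(f$features))
  }
  structure(list(features = feats,
                 caseId = caseId %||% sprintf("img_%04d", seq_len(n)),
                 meta = meta),
            class = "EmbeddingSet")
}

#' 2D t-SNE map of an embedding set
#'
#' Exact t-SNE: per-point bandwidths calibrated to the target perplexity
#' by binary search, symmetrised affinities, early exaggeration, and
#' momentum gradient descent; deterministic given the seed. Feature sets
#' wider than `pcaDims` are first reduced by PCA.
#'
#' @param embeddings an "EmbeddingSet" or an n x p matrix.
#' @param perplexity target perplexity; requires n > 3 * perplexity.
#' @param seed RNG seed for the initial layout.
#' @param nIter gradient-descent iterations.
#' @param pcaDims PCA pre-reduction width.
#' @return n x 2 matrix of coordinates.
#' @export
tsneMap <- function(embeddings, perplexity = 30, seed = 1L, nIter = 500L,
                    pcaDims = 50L) {
  X <- if (inherits(embeddings, "EmbeddingSet")) embeddings$features
       else as.matrix(embeddings)
  n <- nrow(X)
  if (n <= 3 * perplexity)
    stop("too few points: need n > 3 * perplexity (n = ", n, ")")
  if (ncol(X) > pcaDims)
    X <- prcomp(X, rank. = pcaDims, center = TRUE)$x
  D2 <- as.matrix(dist(X))^2
  # per-point precision via binary search on perplexity
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1; lo <- -Inf; hi <- Inf
    di <- D2[i, -i]
    for (it in seq_len(50L)) {
      p <- exp(-di * beta)
      sp <- sum(p)
      if (sp == 0) { H <- 0; p <- p } else {
        H <- log(sp) + beta * sum(di * p) / sp
        p <- p / sp
      }
      if (abs(H - logU) < 1e-5) break
      if (H > logU) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  Y <- .withSeed(seed, matrix(rnorm(n * 2, 0, 1e-4), n, 2))
  dY <- matrix(0, n, 2)
  momentum <- 0.5
  for (it in seq_len(nIter)) {
    ex <- if (it <= 100L) 4 else 1
    sumY <- rowSums(Y^2)
    num <- 1 / (1 + outer(sumY, sumY, "+") - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    W <- (ex * P - Q) * num
    grad <- 4 * (diag(rowSums(W)) - W) %*% Y
    momentum <- if (it <= 250L) 0.5 else 0.8
    dY <- momentum * dY - 200 * grad
    Y <- Y + dY
    Y <- sweep(Y, 2, colMeans(Y))
  }
  Y
}
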