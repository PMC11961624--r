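# Training-time stochastic augmentation on preprocessed [0,1] tensors:
# intensity perturbations (noise, blur, gamma contrast) plus two
# acquisition-artifact emulations — cardiac-motion ghosting (weighted sum
# of shifted copies) and the step-and-shoot slab misregistration of
# non-helical scanners. Every transform maps [0,1] tensors to [0,1]
# tensors of identical shape; transforms with zero magnitude or
# probability are bitwise identities and consume no randomness.

#' Augmentation configuration
#'
#' @param pNoise,pBlur,pContrast,pMotion,pStep per-transform application
#'   probabilities in [0, 1].
#' @param noiseSigma Gaussian noise scale on the [0,1] intensity scale.
#' @param blurSigmaMm Gaussian blur sigma in mm.
#' @param contrastGammaRange range the gamma exponent is drawn from.
#' @param motionNGhosts number of motion ghosts (>= 1; the first is the
#'   unshifted image).
#' @param motionMaxShiftMm maximum per-axis ghost displacement (mm).
#' @param motionWeights optional mixing weights (non-negative, sum 1);
#'   default geometric decay favouring the unshifted image.
#' @param stepMaxShiftMm maximum in-plane step displacement (mm).
#' @param stepAxis slab axis of the step artifact (default 3 = z).
#' @return list of class "AugmentationConfig".
#' @export
augmentationConfig <- function(pNoise = 0.3, pBlur = 0.3, pContrast = 0.3,
                               pMotion = 0.2, pStep = 0.2,
                               noiseSigma = 0.03, blurSigmaMm = 1,
                               contrastGammaRange = c(0.7, 1.4),
                               motionNGhosts = 3L, motionMaxShiftMm = 3,
                               motionWeights = NULL, stepMaxShiftMm = 4,
                               stepAxis = 3L) {
  p <- c(pNoise, pBlur, pContrast, pMotion, pStep)
  if (any(p < 0 | p > 1)) stop("probabilities must be in [0, 1]")
  if (noiseSigma < 0 || blurSigmaMm < 0 || motionMaxShiftMm < 0 ||
      stepMaxShiftMm < 0)
    stop("magnitudes must be >= 0")
  if (any(contrastGammaRange <= 0)) stop("gamma range must be positive")
  if (!is.null(motionWeights)) {
    if (any(motionWeights < 0) ||
        abs(sum(motionWeights) - 1) > 1e-8)
      stop("motionWeights must be non-negative and sum to 1")
  }
  structure(list(pNoise = pNoise, pBlur = pBlur, pContrast = pContrast,
                 pMotion = pMotion, pStep = pStep, noiseSigma = noiseSigma,
                 blurSigmaMm = blurSigmaMm,
                 contrastGammaRange = contrastGammaRange,
                 motionNGhosts = as.integer(motionNGhosts),
                 motionMaxShiftMm = motionMaxShiftMm,
                 motionWeights = motionWeights,
                 stepMaxShiftMm = stepMaxShiftMm,
                 stepAxis = as.integer(stepAxis)),
            class = "AugmentationConfig")
}

#' Additive Gaussian noise, clamped back to [0, 1]
#' @param tensor numeric 3D array in [0, 1].
#' @param sigma noise standard deviation (>= 0); 0 is the identity.
#' @return tensor of the same shape in [0, 1].
#' @export
addNoise <- function(tensor, sigma) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(tensor)
  out <- tensor + rnorm(length(tensor), 0, sigma)
  dim(out) <- dim(tensor)
  pmin(pmax(out, 0), 1)
}

#' Gaussian blur with a physical-units kernel
#'
#' Separable per-axis convolution with a unit-sum kernel, so the mean of a
#' periodically padded tensor is preserved.
#'
#' @param tensor numeric 3D array.
#' @param sigmaMm blur sigma in mm; 0 is the identity.
#' @param spacingMm voxel spacing (mm) of the tensor grid.
#' @param mode boundary handling, "replicate" (default) or "periodic".
#' @return blurred tensor.
#' @export
blurTensor <- function(tensor, sigmaMm, spacingMm = c(1, 1, 1),
                       mode = c("replicate", "periodic")) {
  if (sigmaMm < 0) stop("sigmaMm must be >= 0")
  if (sigmaMm == 0) return(tensor)
  mode <- match.arg(mode)
  d <- dim(tensor)
  for (a in 1:3) {
    k <- .gaussKernel(sigmaMm / spacingMm[a])
    if (length(k) > 1)
      tensor <- .applyAxis(tensor, .convMatrix(d[a], k, mode), a)
  }
  pmin(pmax(tensor, 0), 1)
}

#' Gamma contrast adjustment on the [0, 1] scale
#' @param tensor numeric array in [0, 1].
#' @param gamma exponent (> 0); 1 is the identity.
#' @export
adjustContrast <- function(tensor, gamma) {
  if (gamma <= 0) stop("gamma must be > 0")
  if (gamma == 1) return(tensor)
  tensor^gamma
}

#' Cardiac-motion ghosting
#'
#' The output is a convex combination of shifted copies of the tensor:
#' sum_k w_k * shift(tensor, d_k), with d_0 = 0 and random sub-maximal
#' integer-voxel displacements for the remaining ghosts, emulating the
#' ghosting/blur of cardiac motion during acquisition.
#'
#' @param tensor numeric 3D array in [0, 1].
#' @param nGhosts number of terms (>= 1); 1 is the identity.
#' @param maxShiftMm maximum per-axis displacement (mm).
#' @param weights mixing weights (non-negative, sum 1); default geometric
#'   decay. A weight vector c(1, 0, ...) is the identity.
#' @param spacingMm voxel spacing (mm).
#' @param shifts optional nGhosts x 3 integer matrix of voxel shifts
#'   (first row forced to 0), randomised when NULL.
#' @return tensor of the same shape in [0, 1].
#' @export
simulateMotion <- function(tensor, nGhosts = 3L, maxShiftMm = 3,
                           weights = NULL, spacingMm = c(1, 1, 1),
                           shifts = NULL) {
  if (nGhosts < 1) stop("nGhosts must be >= 1")
  if (is.null(weights)) {
    weights <- 0.5^(0:(nGhosts - 1))
    weights <- weights / sum(weights)
  }
  if (length(weights) != nGhosts || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-8)
    stop("weights must be length nGhosts, non-negative, summing to 1")
  if (nGhosts == 1L) return(tensor)
  if (is.null(shifts)) {
    m <- floor(maxShiftMm / spacingMm)
    shifts <- t(vapply(seq_len(nGhosts), function(k) {
      if (k == 1) c(0L, 0L, 0L)
      else vapply(1:3, function(a)
        if (m[a] < 1) 0L else sample(c(-m[a]:m[a]), 1L), 0L)
    }, integer(3)))
  }
  shifts[1, ] <- 0L
  active <- which(weights > 0)
  if (identical(active, 1L)) return(tensor)
  out <- array(0, dim(tensor))
  for (k in active)
    out <- out + weights[k] * .shiftArray(tensor, shifts[k, ], fill = 0)
  out
}

#' Step-and-shoot slab misregistration artifact
#'
#' Picks a slab boundary slice s (0-based) along the slab axis and rigidly
#' translates all slices at index >= s in-plane by a random integer-voxel
#' offset of at most maxShiftMm, emulating table-position misregistration
#' between sequential acquisitions; slices below s are untouched.
#'
#' @param tensor numeric 3D array in [0, 1] with >= 2 slices on slabAxis.
#' @param slabAxis axis of the slab boundary (default 3).
#' @param maxShiftMm maximum in-plane displacement (mm); 0 is the identity.
#' @param spacingMm voxel spacing (mm).
#' @param s optional 0-based boundary slice (0 shifts the whole volume,
#'   s = depth is the identity); randomised in 1..depth-1 when NULL.
#' @param shiftVox optional in-plane integer shift (length 2); randomised
#'   when NULL.
#' @return tensor of the same shape.
#' @export
simulateStepArtifact <- function(tensor, slabAxis = 3L, maxShiftMm = 4,
                                 spacingMm = c(1, 1, 1), s = NULL,
                                 shiftVox = NULL) {
  d <- dim(tensor)
  if (d[slabAxis] < 2) stop("need >= 2 slices along slabAxis")
  if (maxShiftMm == 0) return(tensor)
  inplane <- setdiff(1:3, slabAxis)
  if (is.null(s)) s <- sample(seq_len(d[slabAxis] - 1L), 1L)
  if (s >= d[slabAxis]) return(tensor)
  if (is.null(shiftVox)) {
    m <- floor(maxShiftMm / spacingMm[inplane])
    shiftVox <- vapply(seq_along(inplane), function(a)
      if (m[a] < 1) 0L else sample(c(-m[a]:m[a]), 1L), 0L)
  }
  if (all(shiftVox == 0L)) return(tensor)
  sl3 <- function(arr, idx) {
    ix <- list(quote(arr), TRUE, TRUE, TRUE)
    ix[[slabAxis + 1L]] <- idx
    do.call(`[`, ix)
  }
  shift3 <- rep(0L, 3); shift3[inplane] <- shiftVox
  moved <- .shiftArray(tensor, shift3, fill = 0)
  out <- tensor
  idx <- (s + 1L):d[slabAxis]
  ass <- list(quote(`[<-`), quote(out), TRUE, TRUE, TRUE,
              value = sl3(moved, idx))
  ass[[slabAxis + 2L]] <- idx
  eval(as.call(ass))
}

#' Compose the stochastic augmentation pipeline
#'
#' Applies each transform independently with its configured probability in
#' the fixed order contrast -> blur -> noise -> motion -> step (intensity
#' before geometric, keeping the noise statistics interpretable).
#' Transforms with probability 0 are skipped without consuming randomness,
#' so the all-zero configuration is a bitwise identity and a probability-1
#' single transform reproduces that transform alone under the same seed.
#'
#' @param tensor numeric 3D array in [0, 1].
#' @param config an [augmentationConfig()].
#' @param spacingMm voxel spacing (mm) of the tensor grid.
#' @param seed optional seed; when given the call is deterministic.
#' @return augmented tensor, same shape, values in [0, 1].
#' @export
augmentTensor <- function(tensor, config = augmentationConfig(),
                          spacingMm = c(1, 1, 1), seed = NULL) {
  stopifnot(inherits(config, "AugmentationConfig"))
  if (!is.null(seed)) set.seed(seed)
  if (config$pContrast > 0 && runif(1) < config$pContrast)
    tensor <- adjustContrast(tensor, runif(1, config$contrastGammaRange[1],
                                           config$contrastGammaRange[2]))
  if (config$pBlur > 0 && runif(1) < config$pBlur)
    tensor <- blurTensor(tensor, config$blurSigmaMm, spacingMm)
  if (config$pNoise > 0 && runif(1) < config$pNoise)
    tensor <- addNoise(tensor, config$noiseSigma)
  if (config$pMotion > 0 && runif(1) < config$pMotion)
    tensor <- simulateMotion(tensor, config$motionNGhosts,
                             config$motionMaxShiftMm, config$motionWeights,
                             spacingMm)
  if (config$pStep > 0 && runif(1) < config$pStep)
    tensor <- simulateStepArtifact(tensor, config$stepAxis,
                                   config$stepMaxShiftMm, spacingMm)
  tensor
}
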