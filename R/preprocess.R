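# Deterministic intensity/geometry normalisation of cropped volumes into
# fixed-size network input tensors: resample -> clip -> discretize ->
# min-max normalise, in that order.

#' Preprocessing configuration
#'
#' @param targetDims output grid shape (default 215 x 215 x 85).
#' @param huClip Hounsfield clip window, default c(-1024, 1024).
#' @param nLevels number of discrete intensity levels (default 256;
#'   integer levels 0..nLevels-1, the top edge mapping to nLevels-1).
#' @param splineOrder interpolation order for resampling: 0 nearest,
#'   1 trilinear, 3 cubic (Catmull-Rom), the default.
#' @return list of class "PreprocessConfig".
#' @export
preprocessConfig <- function(targetDims = c(215L, 215L, 85L),
                             huClip = c(-1024, 1024), nLevels = 256L,
                             splineOrder = 3L) {
  if (huClip[1] >= huClip[2]) stop("huClip must satisfy lo < hi")
  if (nLevels < 2) stop("nLevels must be >= 2")
  if (any(targetDims < 2)) stop("targetDims must all be >= 2")
  structure(list(targetDims = as.integer(targetDims), huClip = huClip,
                 nLevels = as.integer(nLevels),
                 splineOrder = as.integer(splineOrder)),
            class = "PreprocessConfig")
}

.asArray3 <- function(x) if (is(x, "ImageVolume")) x@data else x

#' Resample a volume to target dimensions
#'
#' Separable spline interpolation per axis; the output spacing is rescaled
#' so the physical extent of the grid is preserved
#' (newSpacing = shape * spacing / targetDims).
#'
#' @param volume an [ImageVolume-class].
#' @param targetDims output shape (3 counts, each >= 2).
#' @param splineOrder 0, 1 or 3.
#' @return resampled [ImageVolume-class].
#' @export
resampleVolume <- function(volume, targetDims, splineOrder = 3L) {
  if (any(targetDims < 2)) stop("targetDims must all be >= 2")
  d <- dim(volume@data)
  arr <- volume@data
  for (a in 1:3)
    if (targetDims[a] != d[a] || splineOrder == 0)
      arr <- .applyAxis(arr, .interpMatrix(d[a], targetDims[a], splineOrder), a)
  newSp <- d * volume@spacing / targetDims
  newOrig <- volume@origin - volume@spacing / 2 + newSp / 2
  ImageVolume(arr, spacing = newSp, origin = newOrig)
}

#' Clip intensities to a Hounsfield window
#' @param volume ImageVolume or array.
#' @param lo,hi clip bounds (lo < hi).
#' @return same type as the input, values in [lo, hi].
#' @export
clipHU <- function(volume, lo = -1024, hi = 1024) {
  if (lo >= hi) stop("clip bounds must satisfy lo < hi")
  if (is(volume, "ImageVolume")) {
    volume@data <- pmin(pmax(volume@data, lo), hi)
    volume
  } else pmin(pmax(volume, lo), hi)
}

#' Discretize clipped intensities into integer levels
#'
#' level(v) = floor((v - lo) / (hi - lo) * nLevels), with v = hi mapped to
#' nLevels - 1, so output levels are integers in 0..nLevels-1.
#'
#' @param volume ImageVolume or array, already clipped to [lo, hi].
#' @param lo,hi the clip window the input was clipped to.
#' @param nLevels number of levels.
#' @return same type as the input, integer-valued.
#' @export
discretizeLevels <- function(volume, lo = -1024, hi = 1024, nLevels = 256L) {
  v <- .asArray3(volume)
  if (any(v < lo - 1e-9) || any(v > hi + 1e-9))
    stop("input must be clipped to [lo, hi] before discretization")
  lev <- pmin(floor((v - lo) / (hi - lo) * nLevels), nLevels - 1)
  if (is(volume, "ImageVolume")) { volume@data <- lev; volume } else lev
}

#' Per-volume min-max normalisation to [0, 1]
#'
#' Constant volumes (max == min) map to all zeros by contract.
#'
#' @param volume ImageVolume or array.
#' @return numeric array in [0, 1] (a plain tensor).
#' @export
minmaxNormalize <- function(volume) {
  v <- .asArray3(volume)
  rng <- range(v)
  if (rng[1] == rng[2]) array(0, dim(v)) else (v - rng[1]) / (rng[2] - rng[1])
}

#' Full preprocessing pipeline: resample, clip, discretize, normalise
#'
#' @param volume a cropped [ImageVolume-class] in HU.
#' @param config a [preprocessConfig()].
#' @return numeric tensor of shape config$targetDims with values in [0, 1].
#' @export
preprocessVolume <- function(volume, config = preprocessConfig()) {
  stopifnot(inherits(config, "PreprocessConfig"))
  v <- resampleVolume(volume, config$targetDims, config$splineOrder)
  v <- clipHU(v, config$huClip[1], config$huClip[2])
  v <- discretizeLevels(v, config$huClip[1], config$huClip[2], config$nLevels)
  minmaxNormalize(v)
}
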