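#' @import methods
#' @importFrom stats rnorm runif quantile sd prcomp setNames aggregate
#' @importFrom utils write.csv read.csv head tail
#' @importFrom tools md5sum
#' @useDynLib coroscreen, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' ImageVolume: a 3D scalar grid in a canonical patient frame
#'
#' The universal currency of the pipeline: a 3D array of scalar values
#' (Hounsfield units upstream, normalized intensities downstream) together
#' with its voxel spacing (mm) and the world coordinate of the centre of
#' voxel (1,1,1). The canonical patient frame is +x = patient right,
#' +y = anterior, +z = superior.
#'
#' @slot data 3D numeric array.
#' @slot spacing numeric(3), voxel size in mm, strictly positive.
#' @slot origin numeric(3), world coordinate (mm) of the first voxel centre.
#' @export
setClass("ImageVolume",
  representation(data = "array", spacing = "numeric", origin = "numeric"),
  prototype(data = array(0, c(1, 1, 1)), spacing = c(1, 1, 1),
            origin = c(0, 0, 0)))

setValidity("ImageVolume", function(object) {
  if (length(dim(object@data)) != 3L)
    return("data must be a 3D array")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    return("spacing must be 3 strictly positive finite values (mm)")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    return("origin must be 3 finite values (mm)")
  TRUE
})

#' LabelMap: integer anatomical labels on an image grid
#'
#' Extends [ImageVolume-class] with a label dictionary mapping structure
#' names to integer codes (0 = background).
#'
#' @slot labels named integer vector, e.g. c(aorta = 1, ...).
#' @export
setClass("LabelMap", contains = "ImageVolume",
  representation(labels = "integer"),
  prototype(labels = c(aorta = 1L, lv_myocardium = 2L, lv_cavity = 3L,
                       pulmonary_artery = 4L, coronary = 5L)))

setValidity("LabelMap", function(object) {
  if (is.null(names(object@labels)) || any(names(object@labels) == ""))
    return("labels must be a named integer vector")
  if (anyDuplicated(object@labels) || anyDuplicated(names(object@labels)))
    return("label codes and names must be unique")
  TRUE
})

#' CaseRecord: one patient of the cohort
#'
#' One or more reconstruction-phase volumes on a shared grid, the
#' ground-truth label map, the three task labels, and free-form group
#' metadata. The unit of patient-wise splitting.
#'
#' @slot caseId unique case identifier.
#' @slot volumes list of [ImageVolume-class], one per phase.
#' @slot labelMap a [LabelMap-class].
#' @slot yAnomaly integer 0/1 (normal vs AAOCA).
#' @slot yOrigin "right"/"left" when yAnomaly == 1, otherwise NA.
#' @slot yRisk "low"/"high" when yAnomaly == 1, otherwise NA.
#' @slot course coronary course realised by the phantom generator.
#' @slot group named list of group metadata (e.g. sex).
#' @slot centerline n x 3 matrix of coronary centerline points (mm), kept as
#'   generator provenance so geometric course predicates can be audited.
#' @export
setClass("CaseRecord",
  representation(caseId = "character", volumes = "list",
                 labelMap = "LabelMap", yAnomaly = "integer",
                 yOrigin = "character", yRisk = "character",
                 course = "character", group = "list",
                 centerline = "matrix"),
  prototype(yOrigin = NA_character_, yRisk = NA_character_,
            course = "normal", group = list(),
            centerline = matrix(numeric(0), ncol = 3)))

setValidity("CaseRecord", function(object) {
  if (length(object@caseId) != 1L || is.na(object@caseId))
    return("caseId must be a single string")
  if (length(object@volumes) < 1L)
    return("at least one phase volume is required")
  if (!all(vapply(object@volumes, is, TRUE, "ImageVolume")))
    return("volumes must all be ImageVolume objects")
  d0 <- dim(object@volumes[[1]]@data); s0 <- object@volumes[[1]]@spacing
  for (v in object@volumes)
    if (!identical(dim(v@data), d0) || any(v@spacing != s0))
      return("all phase volumes must share grid shape and spacing")
  if (!object@yAnomaly %in% c(0L, 1L))
    return("yAnomaly must be 0 or 1")
  if (object@yAnomaly == 0L) {
    if (!is.na(object@yOrigin) || !is.na(object@yRisk))
      return("yOrigin/yRisk must be absent (NA) for normal cases")
  } else {
    if (is.na(object@yOrigin) || !object@yOrigin %in% c("right", "left"))
      return("yOrigin must be 'right' or 'left' for anomalous cases")
    if (is.na(object@yRisk) || !object@yRisk %in% c("low", "high"))
      return("yRisk must be 'low' or 'high' for anomalous cases")
  }
  TRUE
})

#' CropBox: a physical-space axis-aligned region of interest
#'
#' A box defined by its centre and extent in mm in the patient frame, plus
#' its voxel realisation on a specific grid as 0-based half-open index
#' ranges [voxelStart, voxelStop).
#'
#' @slot centerMm numeric(3) box centre (mm).
#' @slot extentMm numeric(3) box edge lengths (mm), default 80 x 80 x 60.
#' @slot voxelStart integer(3), 0-based inclusive start indices.
#' @slot voxelStop integer(3), 0-based exclusive stop indices.
#' @export
setClass("CropBox",
  representation(centerMm = "numeric", extentMm = "numeric",
                 voxelStart = "integer", voxelStop = "integer"))

setValidity("CropBox", function(object) {
  if (any(object@extentMm <= 0)) return("extentMm must be strictly positive")
  if (any(object@voxelStop <= object@voxelStart))
    return("voxel ranges must be non-empty (stop > start)")
  TRUE
})

#' PredictionSet: per-case ensemble predictions for one task
#'
#' @slot task one of "anomaly", "origin", "risk".
#' @slot caseId character vector of case ids.
#' @slot memberProbs cases x members matrix of probabilities.
#' @slot ensembleProb numeric vector, arithmetic mean over members.
#' @slot yTrue optional integer labels (NA when unknown).
#' @export
setClass("PredictionSet",
  representation(task = "character", caseId = "character",
                 memberProbs = "matrix", ensembleProb = "numeric",
                 yTrue = "integer"))

setValidity("PredictionSet", function(object) {
  n <- length(object@caseId)
  if (nrow(object@memberProbs) != n || length(object@ensembleProb) != n ||
      length(object@yTrue) != n)
    return("caseId, memberProbs rows, ensembleProb and yTrue must align")
  if (any(object@memberProbs < 0 | object@memberProbs > 1, na.rm = TRUE))
    return("probabilities must lie in [0, 1]")
  mu <- rowMeans(object@memberProbs)
  if (max(abs(mu - object@ensembleProb)) > 1e-8)
    return("ensembleProb must equal the mean of memberProbs")
  TRUE
})

## ---- constructors -------------------------------------------------------

#' Create an ImageVolume
#' @param data 3D numeric array.
#' @param spacing voxel size (mm), length 3.
#' @param origin world coordinate (mm) of the first voxel centre.
#' @return an [ImageVolume-class]
#' @export
ImageVolume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  new("ImageVolume", data = data, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' Create a LabelMap
#' @inheritParams ImageVolume
#' @param labels named integer vector mapping structure names to codes.
#' @return a [LabelMap-class]
#' @export
LabelMap <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                     labels = c(aorta = 1L, lv_myocardium = 2L,
                                lv_cavity = 3L, pulmonary_artery = 4L,
                                coronary = 5L)) {
  storage.mode(data) <- "integer"
  new("LabelMap", data = data, spacing = as.numeric(spacing),
      origin = as.numeric(origin),
      labels = setNames(as.integer(labels), names(labels)))
}

## ---- generics & accessors ----------------------------------------------

#' @describeIn ImageVolume voxel array dimensions
#' @param x,object an ImageVolume
#' @export
setMethod("dim", "ImageVolume", function(x) dim(x@data))

#' Voxel spacing in mm
#' @param x an object with a grid
#' @param ... unused
#' @export
setGeneric("spacing", function(x, ...) standardGeneric("spacing"))

#' @rdname spacing
#' @export
setMethod("spacing", "ImageVolume", function(x, ...) x@spacing)

#' World origin (mm) of the first voxel centre
#' @param x an object with a grid
#' @param ... unused
#' @export
setGeneric("origin", function(x, ...) standardGeneric("origin"))

#' @rdname origin
#' @export
setMethod("origin", "ImageVolume", function(x, ...) x@origin)

#' Raw voxel values
#' @param x an ImageVolume
#' @param ... unused
#' @export
setGeneric("voxels", function(x, ...) standardGeneric("voxels"))

#' @rdname voxels
#' @export
setMethod("voxels", "ImageVolume", function(x, ...) x@data)

#' Extract the binary mask of one labeled structure
#' @param x a LabelMap
#' @param structure structure name, one of names(labelCodes(x))
#' @return logical 3D array
#' @export
setGeneric("structureMask", function(x, structure)
  standardGeneric("structureMask"))

#' @rdname structureMask
#' @export
setMethod("structureMask", "LabelMap", function(x, structure) {
  structure <- match.arg(structure, names(x@labels))
  x@data == x@labels[[structure]]
})

#' Label dictionary of a LabelMap
#' @param x a LabelMap
#' @export
setGeneric("labelCodes", function(x) standardGeneric("labelCodes"))

#' @rdname labelCodes
#' @export
setMethod("labelCodes", "LabelMap", function(x) x@labels)

#' Convert voxel indices (1-based) to world mm
#' @param x an ImageVolume
#' @param ijk n x 3 matrix (or length-3 vector) of 1-based voxel indices
#' @return n x 3 matrix of world coordinates (mm)
#' @export
setGeneric("voxelToWorld", function(x, ijk) standardGeneric("voxelToWorld"))

#' @rdname voxelToWorld
#' @export
setMethod("voxelToWorld", "ImageVolume", function(x, ijk) {
  ijk <- rbind(ijk)
  sweep(sweep(ijk - 1, 2, x@spacing, "*"), 2, x@origin, "+")
})

#' Convert world mm to (fractional, 1-based) voxel indices
#' @param x an ImageVolume
#' @param mm n x 3 matrix (or length-3 vector) of world coordinates
#' @export
setGeneric("worldToVoxel", function(x, mm) standardGeneric("worldToVoxel"))

#' @rdname worldToVoxel
#' @export
setMethod("worldToVoxel", "ImageVolume", function(x, mm) {
  mm <- rbind(mm)
  sweep(sweep(mm, 2, x@origin, "-"), 2, x@spacing, "/") + 1
})

setMethod("show", "ImageVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("%s %d x %d x %d @ (%.3g, %.3g, %.3g) mm\n",
              class(object), d[1], d[2], d[3],
              object@spacing[1], object@spacing[2], object@spacing[3]))
  cat(sprintf("  origin (mm): %.1f %.1f %.1f; range [%.4g, %.4g]\n",
              object@origin[1], object@origin[2], object@origin[3],
              min(object@data), max(object@data)))
})

setMethod("show", "LabelMap", function(object) {
  callNextMethod()
  tab <- tabulate(object@data + 1L, nbins = max(object@labels) + 1L)
  for (nm in names(object@labels))
    cat(sprintf("  %-18s code %d: %d voxels\n", nm, object@labels[[nm]],
                tab[object@labels[[nm]] + 1L]))
})

setMethod("show", "CaseRecord", function(object) {
  cat(sprintf("CaseRecord %s: %d phase(s), y_anomaly=%d, origin=%s, risk=%s, course=%s\n",
              object@caseId, length(object@volumes), object@yAnomaly,
              object@yOrigin, object@yRisk, object@course))
})

setMethod("show", "CropBox", function(object) {
  cat(sprintf("CropBox centre (%.1f, %.1f, %.1f) mm, extent (%g, %g, %g) mm\n",
              object@centerMm[1], object@centerMm[2], object@centerMm[3],
              object@extentMm[1], object@extentMm[2], object@extentMm[3]))
  cat(sprintf("  voxels [%d,%d) x [%d,%d) x [%d,%d) (0-based half-open)\n",
              object@voxelStart[1], object@voxelStop[1],
              object@voxelStart[2], object@voxelStop[2],
              object@voxelStart[3], object@voxelStop[3]))
})

setMethod("show", "PredictionSet", function(object) {
  cat(sprintf("PredictionSet task=%s: %d cases x %d members\n",
              object@task, length(object@caseId), ncol(object@memberProbs)))
})
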