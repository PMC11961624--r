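# Stage 1: locate the aortic-root reference point from aorta/LV
# segmentations and crop the fixed-size physical box around it.
#
# The reference point is the centroid of the aorto-ventricular contact
# set. Because label maps assign one label per voxel, aorta and LV
# usually abut rather than overlap: the contact set is defined as aorta
# voxels whose dilation overlaps the LV, union the symmetric LV-side set,
# with the literal shared-voxel intersection taking precedence when
# non-empty. The point is then moved 1 cm to the patient's right and 1 cm
# superior (offset (+10, 0, +10) mm, configurable) so more of the curved
# ascending aorta falls inside the 8 x 8 x 6 cm^3 crop.

#' Locate the aortic-root reference point
#'
#' @param aortaMask logical 3D array (aorta segmentation).
#' @param lvMask logical 3D array (LV = myocardium + cavity), same grid.
#' @param spacing voxel spacing (mm).
#' @param origin world coordinate of the first voxel centre (mm).
#' @param offsetMm offset applied to the contact centroid; default
#'   c(10, 0, 10) mm = 1 cm right + 1 cm superior.
#' @param maxDilate maximum dilation radius (voxels) when searching for
#'   contact between abutting masks.
#' @return list of class "RootPoint" with pointMm and adjustedPointMm.
#' @export
findRootPoint <- function(aortaMask, lvMask, spacing = c(1, 1, 1),
                          origin = c(0, 0, 0), offsetMm = c(10, 0, 10),
                          maxDilate = 3L) {
  if (!identical(dim(aortaMask), dim(lvMask)))
    stop("masks must share one grid")
  if (!any(aortaMask) || !any(lvMask)) stop("masks must be non-empty")
  contact <- aortaMask & lvMask
  if (!any(contact)) {
    for (r in seq_len(maxDilate)) {
      contact <- (aortaMask & .dilateMask(lvMask, r)) |
                 (lvMask & .dilateMask(aortaMask, r))
      if (any(contact)) break
    }
  }
  if (!any(contact))
    stop("no aorto-ventricular contact within dilation radius ", maxDilate)
  p <- .maskCentroidMm(contact, spacing, origin)
  structure(list(pointMm = p, adjustedPointMm = p + offsetMm,
                 offsetMm = offsetMm),
            class = "RootPoint")
}

#' @export
print.RootPoint <- function(x, ...) {
  cat(sprintf("RootPoint (%.1f, %.1f, %.1f) mm -> adjusted (%.1f, %.1f, %.1f) mm\n",
              x$pointMm[1], x$pointMm[2], x$pointMm[3],
              x$adjustedPointMm[1], x$adjustedPointMm[2],
              x$adjustedPointMm[3]))
  invisible(x)
}

#' Compute the physical crop box around the adjusted root point
#'
#' The box is centred on the adjusted root point with a fixed physical
#' extent (default 80 x 80 x 60 mm, i.e. 8 x 8 x 6 cm^3). Its voxel
#' realisation uses 0-based half-open index ranges; the voxel count per
#' axis is ceiling(extent / spacing), so the realised physical size equals
#' the requested extent to within one voxel per axis. Ranges may extend
#' beyond the image; [cropVolume()] pads.
#'
#' @param root a RootPoint from [findRootPoint()].
#' @param grid an [ImageVolume-class] (or LabelMap) defining the grid.
#' @param extentMm box edge lengths (mm).
#' @return a [CropBox-class].
#' @export
computeCropBox <- function(root, grid, extentMm = c(80, 80, 60)) {
  if (any(extentMm <= 0)) stop("extentMm must be strictly positive")
  center <- root$adjustedPointMm
  sp <- spacing(grid); org <- origin(grid)
  n <- as.integer(ceiling(extentMm / sp - 1e-9))
  start <- as.integer(round((center - extentMm / 2 - org) / sp))
  new("CropBox", centerMm = as.numeric(center),
      extentMm = as.numeric(extentMm),
      voxelStart = start, voxelStop = start + n)
}

#' Crop a volume to a box, padding out-of-field voxels
#'
#' @param volume an [ImageVolume-class] on the grid the box was computed
#'   on (a LabelMap input yields a LabelMap output).
#' @param box a [CropBox-class].
#' @param padValue fill for portions outside the image (default -1024 HU,
#'   the clip floor, so padding is neutral after preprocessing).
#' @return the cropped volume with updated origin and unchanged spacing.
#' @export
cropVolume <- function(volume, box, padValue = -1024) {
  d <- dim(volume@data)
  n <- box@voxelStop - box@voxelStart
  lo <- pmax(box@voxelStart, 0L)            # 0-based clamp to image
  hi <- pmin(box@voxelStop, d)
  if (any(hi <= lo)) stop("crop box lies entirely outside the image")
  out <- array(padValue, n)
  dst <- Map(function(a, b, s) (a + 1):b - s,
             lo, hi, box@voxelStart)
  out[dst[[1]], dst[[2]], dst[[3]]] <-
    volume@data[(lo[1] + 1):hi[1], (lo[2] + 1):hi[2], (lo[3] + 1):hi[3]]
  newOrigin <- volume@origin + box@voxelStart * volume@spacing
  if (is(volume, "LabelMap"))
    LabelMap(out, spacing = volume@spacing, origin = newOrigin,
             labels = volume@labels)
  else
    ImageVolume(out, spacing = volume@spacing, origin = newOrigin)
}

#' Rough threshold-based segmentation of phantom images
#'
#' A deliberately naive stand-in segmenter sufficient for crop-point
#' location on phantom images (only a rough segmentation is needed for
#' cropping): contrast-range thresholding with morphological closing
#' isolates the blood pool; erosion splits it at the narrow
#' aorto-ventricular junction into aorta and LV-cavity seeds (the seed
#' with the higher centroid is the aorta), which are grown back
#' geodesically inside the blood-pool mask; the myocardium is the largest
#' muscle-range component. Intended for phantom pipelines only — it is not
#' a clinical segmenter.
#'
#' @param volume an [ImageVolume-class] in HU.
#' @param huThresholds list with elements blood = c(lo, hi) and
#'   muscle = c(lo, hi).
#' @param erodeRadius erosion radius (voxels) used to split the blood pool.
#' @return a [LabelMap-class] with aorta, lv_myocardium, lv_cavity.
#' @export
naiveSegment <- function(volume,
                         huThresholds = list(blood = c(320, 520),
                                             muscle = c(55, 115)),
                         erodeRadius = 5L, smoothSigmaMm = 1.5,
                         maxGrowIter = 12L) {
  v <- volume@data
  d <- dim(v)
  blood <- v >= huThresholds$blood[1] & v <= huThresholds$blood[2]
  blood <- .erodeMask(.dilateMask(blood, 1L), 1L)   # closing
  if (!any(blood)) stop("no contrast-range component found")
  comp <- .label_components(blood)
  sizes <- tabulate(comp)
  blood <- comp == which.max(sizes)
  # work inside the blood-pool bounding box
  bb <- which(blood, arr.ind = TRUE)
  lo <- pmax(apply(bb, 2, min) - 2L, 1L)
  hi <- pmin(apply(bb, 2, max) + 2L, d)
  sub <- blood[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  core <- .erodeMask(sub, erodeRadius)
  ccore <- .label_components(core)
  csz <- tabulate(ccore)
  keep <- order(csz, decreasing = TRUE)[seq_len(min(2L, sum(csz > 0)))]
  if (length(keep) < 2L || csz[keep[2]] < 50L)
    stop("could not split blood pool into aorta and LV cavity")
  zc <- vapply(keep, function(k) mean(which(ccore == k, arr.ind = TRUE)[, 3]),
               0)
  aortaSeed <- ccore == keep[which.max(zc)]
  cavSeed <- ccore == keep[which.min(zc)]
  # capped geodesic growth of the two seeds inside the blood-pool mask
  # (the cap deliberately leaves far-away thin attachments, such as the
  # coronary lumen, unassigned)
  for (it in seq_len(maxGrowIter)) {
    grewA <- .dilateMask(aortaSeed, 1L) & sub & !aortaSeed & !cavSeed
    grewC <- .dilateMask(cavSeed, 1L) & sub & !aortaSeed & !cavSeed
    grewC <- grewC & !grewA       # ties go to the aorta, deterministically
    if (!any(grewA) && !any(grewC)) break
    aortaSeed <- aortaSeed | grewA
    cavSeed <- cavSeed | grewC
  }
  vs <- .blur3d(v, smoothSigmaMm / volume@spacing)
  muscle <- vs >= huThresholds$muscle[1] & vs <= huThresholds$muscle[2]
  # opening strips the thin partial-volume halos that blur creates around
  # contrast-filled vessels; the myocardial wall is thick enough to survive
  muscle <- .dilateMask(.erodeMask(muscle, 2L), 2L) & muscle
  lab <- array(0L, d)
  if (any(muscle)) {
    mcomp <- .label_components(muscle)
    lab[mcomp == which.max(tabulate(mcomp))] <- 2L
  }
  put <- function(lab, m, code) {
    full <- array(FALSE, d)
    full[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- m
    lab[full] <- code
    lab
  }
  lab <- put(lab, cavSeed, 3L)
  lab <- put(lab, aortaSeed, 1L)
  LabelMap(lab, spacing = volume@spacing, origin = volume@origin,
           labels = c(aorta = 1L, lv_myocardium = 2L, lv_cavity = 3L))
}
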