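# NIfTI I/O. Volumes live in a canonical RAS-like patient frame
# (+x = patient right, +y = anterior, +z = superior); the affine written is
# diag(spacing) with the translation set to the world coordinate of the
# first voxel centre, so cropped outputs stay spatially registered.

#' Write an ImageVolume (or LabelMap) to NIfTI
#' @param vol an [ImageVolume-class].
#' @param path output path (.nii or .nii.gz).
#' @return the path, invisibly.
#' @export
writeVolume <- function(vol, path) {
  stopifnot(is(vol, "ImageVolume"))
  img <- RNifti::asNifti(vol@data)
  aff <- diag(c(vol@spacing, 1))
  aff[1:3, 4] <- vol@origin
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a cohort written by generateCohort back into CaseRecords
#' @param dir directory containing manifest.csv and the NIfTI files.
#' @return list(manifest, cases).
#' @export
readCohort <- function(dir) {
  manifest <- read.csv(file.path(dir, "manifest.csv"),
                       stringsAsFactors = FALSE)
  cases <- lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    vols <- lapply(strsplit(row$phase_paths, ";")[[1]], readVolume)
    lm <- readVolume(row$label_path,
                     labels = c(aorta = 1L, lv_myocardium = 2L,
                                lv_cavity = 3L, pulmonary_artery = 4L,
                                coronary = 5L))
    new("CaseRecord", caseId = row$case_id, volumes = vols, labelMap = lm,
        yAnomaly = as.integer(row$y_anomaly),
        yOrigin = if (is.na(row$y_origin)) NA_character_ else row$y_origin,
        yRisk = if (is.na(row$y_risk)) NA_character_ else row$y_risk,
        course = row$course, group = list(sex = row$group),
        centerline = matrix(numeric(0), ncol = 3))
  })
  list(manifest = manifest, cases = cases)
}

#' Read a NIfTI file as an ImageVolume or LabelMap
#' @param path NIfTI file path.
#' @param labels optional named integer vector; when given the result is a
#'   [LabelMap-class] with that dictionary.
#' @return an [ImageVolume-class] or [LabelMap-class].
#' @export
readVolume <- function(path, labels = NULL) {
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  sp <- sqrt(colSums(aff[1:3, 1:3]^2))
  orig <- aff[1:3, 4]
  dat <- array(as.numeric(img), dim(img))
  if (is.null(labels)) ImageVolume(dat, spacing = sp, origin = orig)
  else LabelMap(dat, spacing = sp, origin = orig, labels = labels)
}
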