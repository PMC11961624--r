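# Procedural cardiac CCTA phantoms.
#
# Anatomy is built from analytic primitives in a canonical patient frame
# (+x = patient right, +y = anterior, +z = superior): elliptical-cylinder
# body, ellipsoidal lungs and LV (myocardial shell + contrast-filled
# cavity), vertical cylinders with a root sphere for the ascending aorta
# and for the pulmonary artery (PA), and a Catmull-Rom spline tube for the
# coronary artery whose origin and proximal course realise the anomaly
# taxonomy: normal; low-risk {prepulmonic, retroaortic, high_takeoff};
# high-risk {interarterial, subpulmonic}. Closed-form geometry gives exact
# oracles for crop and course tests.

.PHANTOM_COURSES <- c("normal", "interarterial", "prepulmonic", "retroaortic",
                      "high_takeoff", "subpulmonic")
.PHANTOM_CLASSES <- c("normal", "R-AAOCA", "L-AAOCA")

#' Map a coronary course to its anatomical risk label
#'
#' Interarterial and sub-pulmonic courses are high anatomical risk;
#' pre-pulmonic, retro-aortic and high take-off are low risk. The normal
#' course has no risk label.
#'
#' @param course one of "normal", "interarterial", "prepulmonic",
#'   "retroaortic", "high_takeoff", "subpulmonic".
#' @return "high", "low", or NA for the normal course.
#' @export
courseRisk <- function(course) {
  course <- match.arg(course, .PHANTOM_COURSES)
  switch(course,
         normal = NA_character_,
         interarterial = "high", subpulmonic = "high",
         prepulmonic = "low", retroaortic = "low", high_takeoff = "low")
}

#' Phantom generator configuration
#'
#' @param gridShape voxels per axis (default 128 x 128 x 96).
#' @param spacingMm voxel size in mm (default 1.25 isotropic); the default
#'   grid therefore spans 160 x 160 x 120 mm.
#' @param tissueHu named mean Hounsfield units for each tissue compartment.
#' @param noiseSigmaHu additive Gaussian noise scale in HU.
#' @param coronaryRadiusMm coronary tube radius (mm).
#' @param anomalyClass "normal", "R-AAOCA" or "L-AAOCA".
#' @param course coronary course; must be "normal" iff anomalyClass is
#'   "normal".
#' @param nPhases number of pseudo-reconstruction phases to simulate.
#' @param highTakeoffMm ostium height above the sinotubular junction for
#'   the high take-off course.
#' @param jitterMm half-width of the uniform random translation applied to
#'   the whole heart complex (anatomical variability).
#' @param phaseAmplitudeMm max deformation (mm) between pseudo-phases.
#' @param seed RNG seed; identical (config, seed) give bitwise-identical
#'   phantoms.
#' @return a validated list of class "PhantomConfig".
#' @export
phantomConfig <- function(gridShape = c(128L, 128L, 96L),
                          spacingMm = c(1.25, 1.25, 1.25),
                          tissueHu = c(air = -1000, lung = -800,
                                       soft_tissue = 40, myocardium = 80,
                                       blood_pool_contrast = 400,
                                       pa_blood = 150,
                                       coronary_contrast = 350),
                          noiseSigmaHu = 25,
                          coronaryRadiusMm = 3,
                          anomalyClass = c("normal", "R-AAOCA", "L-AAOCA"),
                          course = "normal",
                          nPhases = 1L,
                          highTakeoffMm = 12,
                          jitterMm = 4,
                          phaseAmplitudeMm = 1.5,
                          seed = 1L) {
  anomalyClass <- match.arg(anomalyClass)
  course <- match.arg(course, .PHANTOM_COURSES)
  if (any(spacingMm <= 0)) stop("spacingMm must be strictly positive")
  if (length(gridShape) != 3L || any(gridShape < 4))
    stop("gridShape must be 3 counts >= 4")
  if ((course == "normal") != (anomalyClass == "normal"))
    stop("course must be 'normal' iff anomalyClass is 'normal'")
  need <- c("air", "lung", "soft_tissue", "myocardium",
            "blood_pool_contrast", "pa_blood", "coronary_contrast")
  if (!all(need %in% names(tissueHu)))
    stop("tissueHu must name: ", paste(need, collapse = ", "))
  if (noiseSigmaHu < 0) stop("noiseSigmaHu must be >= 0")
  if (nPhases < 1) stop("nPhases must be >= 1")
  structure(list(gridShape = as.integer(gridShape),
                 spacingMm = as.numeric(spacingMm),
                 tissueHu = tissueHu, noiseSigmaHu = noiseSigmaHu,
                 coronaryRadiusMm = coronaryRadiusMm,
                 anomalyClass = anomalyClass, course = course,
                 nPhases = as.integer(nPhases),
                 highTakeoffMm = highTakeoffMm, jitterMm = jitterMm,
                 phaseAmplitudeMm = phaseAmplitudeMm,
                 seed = as.integer(seed)),
            class = "PhantomConfig")
}

#' Realised phantom geometry for a configuration
#'
#' Deterministically derives (config + seed, including the random
#' anatomical jitter) the analytic geometry of every structure: centres,
#' radii, semiaxes and the coronary ostium frame. Exposed so tests can
#' evaluate course predicates independently of the voxel rasterisation.
#'
#' @param config a [phantomConfig()].
#' @param side which coronary territory the distal vessel supplies
#'   ("right"/"left"); defaults to the origin implied by anomalyClass.
#' @return list with elements extent, body, lungs, lv, aorta, pa, coronary.
#' @export
phantomGeometry <- function(config, side = NULL) {
  extent <- config$gridShape * config$spacingMm
  C <- extent / 2
  rng <- .withSeed(.deriveSeed(config$seed, 101L), {
    list(gshift = runif(3, -config$jitterMm, config$jitterMm),
         pashift = runif(2, -1, 1),
         rscale = runif(1, 0.9, 1.1),
         normside = sample(c("right", "left"), 1))
  })
  if (is.null(side))
    side <- switch(config$anomalyClass, `R-AAOCA` = "right",
                   `L-AAOCA` = "left", normal = rng$normside)
  g <- rng$gshift
  lvC <- C + c(-18, -12, -24) + g
  aortaXY <- C[1:2] + c(4, -4) + g[1:2]
  aortaR <- 13
  zRoot <- C[3] + 4 + g[3]
  zTop <- extent[3] - 5
  stjZ <- zRoot + 14
  paXY <- aortaXY + c(-25, 19) + rng$pashift
  paR <- 12
  paZ <- c(zRoot + 6, zTop)
  geom <- list(
    extent = extent,
    body = list(center = C[1:2], semi = c(0.45, 0.41) * extent[1:2]),
    lungs = list(centers = rbind(c(C[1] - 52, C[2] + 5, C[3]),
                                 c(C[1] + 52, C[2] + 5, C[3])),
                 semi = c(24, 45, 0.43 * extent[3])),
    lv = list(center = lvC, cavitySemi = c(22, 22, 24),
              wallMm = 8, lvotRadius = 5),
    aorta = list(axisXY = aortaXY, radius = aortaR,
                 zRange = c(zRoot, zTop), stjZ = stjZ,
                 rootCenter = c(aortaXY, zRoot + 2), rootRadius = aortaR + 2),
    pa = list(axisXY = paXY, radius = paR, zRange = paZ),
    coronary = list(radius = config$coronaryRadiusMm * rng$rscale,
                    side = side, ostiumZ = zRoot + 8,
                    highTakeoffMm = config$highTakeoffMm))
  geom$coronary$control <- .coronaryControlPoints(geom, config$course, side)
  geom
}

# Evaluate an expression with a temporary RNG state.
.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  expr
}

# Control points (n x 3, mm) of the coronary centerline for each course.
.coronaryControlPoints <- function(geom, course, side) {
  A <- geom$aorta$axisXY; Ra <- geom$aorta$radius
  P <- geom$pa$axisXY; Rp <- geom$pa$radius
  zO <- geom$coronary$ostiumZ
  u <- (P - A) / sqrt(sum((P - A)^2))       # aorta -> PA direction
  v <- c(u[2], -u[1])                        # perpendicular, towards right
  dAP <- sqrt(sum((P - A)^2))
  gap <- dAP - Ra - Rp
  wR <- c(1, 0.35) / sqrt(1 + 0.35^2)        # right sinus direction
  wL <- c(-1, -0.1) / sqrt(1 + 0.01)         # left sinus direction
  p2 <- function(xy, z) c(xy, z)
  endR <- p2(A + c(21, 7), zO - 26)
  endL <- p2(A + c(-31, 3), zO - 22)
  pts <- switch(course,
    normal = if (side == "right")
      rbind(p2(A + Ra * wR, zO), p2(A + (Ra + 7) * wR + c(2, 3), zO - 6),
            p2(A + c(18, 10), zO - 16), endR)
    else
      rbind(p2(A + Ra * wL, zO), p2(A + (Ra + 8) * wL + c(-2, 4), zO - 4),
            p2(A + c(-25, 6), zO - 12), endL),
    interarterial = {
      M <- A + (Ra + gap / 2) * u
      dv <- if (side == "right") v else -v
      base <- rbind(p2(A + Ra * u, zO), p2(M, zO - 1), p2(M + 8 * dv, zO - 3),
                    p2(M + 18 * dv, zO - 6))
      if (side == "right")
        rbind(base, p2(M + 30 * dv, zO - 13), endR)
      else  # ride the epicardial surface left of the aorta
        rbind(base, p2(A + c(-26, 8), zO - 8), p2(A + c(-31, 10), zO - 14))
    },
    prepulmonic = {
      # crossing segment stays at ostium height (inside the PA z-span) and
      # strictly anterior to the PA; descents start only after leaving the
      # PA's sagittal slab
      front <- P[2] + Rp + 4
      base <- rbind(p2(A + Ra * c(0.15, 0.99) / sqrt(0.15^2 + 0.99^2), zO),
                    p2(c((A[1] + P[1]) / 2 + 4, front - 2), zO),
                    p2(c(P[1] - 2, front + 1), zO))
      if (side == "left")
        rbind(base, p2(c(P[1] - 4, front - 2), zO - 8),
              p2(c(P[1] - 2, P[2] - 4), zO - 14),
              p2(A + c(-27, -2), zO - 18))
      else
        rbind(base, p2(c(P[1] - 3, front - 3), zO - 8),
              p2(c(A[1] - 6, P[2] - 2), zO - 15),
              p2(A + c(19, 6), zO - 24))
    },
    retroaortic = {
      s <- if (side == "right") 1 else -1
      rbind(p2(A + Ra * c(-0.2 * s, -0.98) / sqrt(0.04 + 0.9604), zO),
            p2(A + c(8 * s, -Ra - 6), zO - 3),
            p2(A + c((Ra + 9) * s, -6), zO - 10),
            if (side == "right") endR + c(0, 0, 6) else endL + c(0, 0, 4))
    },
    high_takeoff = {
      zH <- geom$aorta$stjZ + geom$coronary$highTakeoffMm
      w <- if (side == "right") wR else wL
      rbind(p2(A + Ra * w, zH), p2(A + (Ra + 6) * w, geom$aorta$stjZ - 2),
            p2(A + c(if (side == "right") 18 else -18, 9), zO - 12),
            if (side == "right") endR else endL)
    },
    subpulmonic = {
      zLow <- geom$aorta$zRange[1] + 2
      base <- rbind(p2(A + Ra * c(-0.1, 0.995) / sqrt(0.01 + 0.995^2), zLow + 2),
                    p2(c(P[1] + 5, P[2] - 2), geom$pa$zRange[1] - 5),
                    p2(c(P[1] - 5, P[2] + 1), geom$pa$zRange[1] - 5))
      if (side == "right")
        rbind(base, p2(c(P[1] + 2, P[2] + 6), zLow - 8),
              p2(A + c(17, 12), zLow - 14))
      else
        rbind(base, p2(c(P[1], P[2] + 5), zLow - 8),
              p2(A + c(-27, 5), zLow - 14))
    })
  unname(pts)
}

# Densely sample a Catmull-Rom spline through control points.
.splineCurve <- function(ctrl, stepMm = 0.5) {
  n <- nrow(ctrl)
  if (n < 2) return(ctrl)
  ext <- rbind(ctrl[1, ], ctrl, ctrl[n, ])
  out <- list()
  for (i in seq_len(n - 1)) {
    p0 <- ext[i, ]; p1 <- ext[i + 1, ]; p2 <- ext[i + 2, ]; p3 <- ext[i + 3, ]
    len <- sqrt(sum((p2 - p1)^2))
    m <- max(2L, ceiling(len / stepMm))
    t <- seq(0, 1, length.out = m + 1)[-(m + 1)]
    w0 <- (-t^3 + 2 * t^2 - t) / 2
    w1 <- (3 * t^3 - 5 * t^2 + 2) / 2
    w2 <- (-3 * t^3 + 4 * t^2 + t) / 2
    w3 <- (t^3 - t^2) / 2
    out[[i]] <- outer(w0, p0) + outer(w1, p1) + outer(w2, p2) + outer(w3, p3)
  }
  rbind(do.call(rbind, out), ctrl[n, ])
}

# Rasterise a tube of given radius around a sampled centerline.
.stampTube <- function(mask, centerline, radiusMm, spacing) {
  d <- dim(mask)
  r <- radiusMm
  for (i in seq_len(nrow(centerline))) {
    p <- centerline[i, ]
    lo <- pmax(floor((p - r) / spacing) + 1, 1)
    hi <- pmin(ceiling((p + r) / spacing) + 1, d)
    if (any(lo > hi)) next
    xs <- (lo[1]:hi[1] - 1) * spacing[1] - p[1]
    ys <- (lo[2]:hi[2] - 1) * spacing[2] - p[2]
    zs <- (lo[3]:hi[3] - 1) * spacing[3] - p[3]
    d2 <- outer(outer(xs^2, ys^2, "+"), zs^2, "+")
    sub <- mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- sub | (d2 <= r^2)
  }
  mask
}

# Ellipsoid mask from per-axis coordinate vectors.
.ellipsoidMask <- function(xs, ys, zs, center, semi) {
  outer(outer(((xs - center[1]) / semi[1])^2,
              ((ys - center[2]) / semi[2])^2, "+"),
        ((zs - center[3]) / semi[3])^2, "+") <= 1
}

# Check every structure fits inside the grid; error names the first that
# does not.
.checkPhantomFits <- function(geom) {
  ext <- geom$extent
  need <- list(
    lv_myocardium = cbind(geom$lv$center - geom$lv$cavitySemi - geom$lv$wallMm,
                          geom$lv$center + geom$lv$cavitySemi + geom$lv$wallMm),
    aorta = cbind(c(geom$aorta$axisXY - geom$aorta$radius, geom$aorta$zRange[1]),
                  c(geom$aorta$axisXY + geom$aorta$radius, geom$aorta$zRange[1] + 10)),
    pulmonary_artery = cbind(c(geom$pa$axisXY - geom$pa$radius, geom$pa$zRange[1]),
                             c(geom$pa$axisXY + geom$pa$radius, geom$pa$zRange[1] + 10)))
  for (nm in names(need)) {
    b <- need[[nm]]
    if (any(b[, 1] < -2) || any(b[, 2] > ext + 2))
      stop("grid too small to contain structure '", nm,
           "' at the configured spacing")
  }
  invisible(TRUE)
}

#' Generate one labeled synthetic CCTA phantom
#'
#' Rasterises the analytic anatomy of [phantomGeometry()] onto the
#' configured grid, assigns the five-structure label map (aorta, LV
#' myocardium, LV cavity, pulmonary artery, coronary), composes the image
#' as tissue mean HU plus Gaussian noise, and derives the three task labels
#' from the configured class and course. Deterministic given (config, seed).
#'
#' @param config a [phantomConfig()].
#' @return a [CaseRecord-class] with ground-truth label map and the sampled
#'   coronary centerline attached as provenance.
#' @export
generatePhantom <- function(config) {
  stopifnot(inherits(config, "PhantomConfig"))
  geom <- phantomGeometry(config)
  .checkPhantomFits(geom)
  d <- config$gridShape; sp <- config$spacingMm; hu <- config$tissueHu
  xs <- (seq_len(d[1]) - 1) * sp[1]
  ys <- (seq_len(d[2]) - 1) * sp[2]
  zs <- (seq_len(d[3]) - 1) * sp[3]

  img <- array(hu[["air"]], d)
  lab <- array(0L, d)

  bodyXY <- outer(((xs - geom$body$center[1]) / geom$body$semi[1])^2,
                  ((ys - geom$body$center[2]) / geom$body$semi[2])^2,
                  "+") <= 1
  body <- array(bodyXY, d)   # elliptical cylinder along z
  img[body] <- hu[["soft_tissue"]]
  for (i in 1:2) {
    lung <- .ellipsoidMask(xs, ys, zs, geom$lungs$centers[i, ], geom$lungs$semi)
    img[lung & body] <- hu[["lung"]]
  }

  outerLV <- .ellipsoidMask(xs, ys, zs, geom$lv$center,
                            geom$lv$cavitySemi + geom$lv$wallMm)
  cavity <- .ellipsoidMask(xs, ys, zs, geom$lv$center, geom$lv$cavitySemi)
  lab[outerLV] <- 2L; img[outerLV] <- hu[["myocardium"]]
  lab[cavity] <- 3L; img[cavity] <- hu[["blood_pool_contrast"]]
  # LV outflow tract: a narrow contrast channel joining the cavity to the
  # aortic root (its intra-root portion is overwritten by the aorta below,
  # leaving the two structures abutting at the valve plane)
  lvotLine <- sweep(outer(seq(0.3, 1, length.out = 30),
                          geom$aorta$rootCenter - geom$lv$center),
                    2, geom$lv$center, "+")
  lvot <- .stampTube(array(FALSE, d), lvotLine, geom$lv$lvotRadius, sp)
  lab[lvot] <- 3L; img[lvot] <- hu[["blood_pool_contrast"]]

  paXY <- outer((xs - geom$pa$axisXY[1])^2, (ys - geom$pa$axisXY[2])^2,
                "+") <= geom$pa$radius^2
  paM <- array(paXY, d) &
    array(rep(zs >= geom$pa$zRange[1] & zs <= geom$pa$zRange[2],
              each = d[1] * d[2]), d)
  lab[paM] <- 4L; img[paM] <- hu[["pa_blood"]]

  aoXY <- outer((xs - geom$aorta$axisXY[1])^2, (ys - geom$aorta$axisXY[2])^2,
                "+") <= geom$aorta$radius^2
  aoM <- array(aoXY, d) &
    array(rep(zs >= geom$aorta$zRange[1] & zs <= geom$aorta$zRange[2],
              each = d[1] * d[2]), d)
  root <- .ellipsoidMask(xs, ys, zs, geom$aorta$rootCenter,
                         rep(geom$aorta$rootRadius, 3))
  aoM <- aoM | root
  lab[aoM] <- 1L; img[aoM] <- hu[["blood_pool_contrast"]]

  centerline <- .splineCurve(geom$coronary$control)
  tube <- .stampTube(array(FALSE, d), centerline, geom$coronary$radius, sp)
  # carve against the eroded vessel cores so the ostium crescent stays
  # 6-connected to the rest of the tube (erosion restricted to the tube's
  # bounding box for speed)
  tb <- which(tube, arr.ind = TRUE)
  lo <- pmax(apply(tb, 2, min) - 2L, 1L); hi <- pmin(apply(tb, 2, max) + 2L, d)
  ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
  tube[ix, iy, iz] <- tube[ix, iy, iz, drop = FALSE] &
    !.erodeMask(aoM[ix, iy, iz, drop = FALSE], 1L) &
    !.erodeMask(paM[ix, iy, iz, drop = FALSE], 1L)
  lab[tube] <- 5L; img[tube] <- hu[["coronary_contrast"]]

  img <- .withSeed(.deriveSeed(config$seed, 202L), {
    img + rnorm(length(img), 0, config$noiseSigmaHu)
  })
  dim(img) <- d

  vol <- ImageVolume(img, spacing = sp, origin = c(0, 0, 0))
  lm <- LabelMap(lab, spacing = sp, origin = c(0, 0, 0))
  rec <- new("CaseRecord",
             caseId = sprintf("phantom_seed%d", config$seed),
             volumes = list(vol), labelMap = lm,
             yAnomaly = if (config$anomalyClass == "normal") 0L else 1L,
             yOrigin = if (config$anomalyClass == "normal") NA_character_
                       else geom$coronary$side,
             yRisk = courseRisk(config$course),
             course = config$course,
             group = list(), centerline = centerline)
  if (config$nPhases > 1L)
    rec <- simulatePhases(rec, config$nPhases, config$phaseAmplitudeMm,
                          seed = .deriveSeed(config$seed, 303L))
  rec
}

#' Smooth random deformation field for pseudo-phase simulation
#'
#' A per-axis displacement field is drawn on a coarse control grid,
#' trilinearly upsampled to the image grid, and scaled so the maximum
#' displacement norm equals the requested amplitude. Because trilinear
#' interpolation is a convex combination, the upsampled field's maximum
#' norm never exceeds the amplitude.
#'
#' @param dims image grid shape.
#' @param spacing voxel spacing (mm).
#' @param amplitudeMm maximum displacement norm (mm).
#' @param seed RNG seed.
#' @return list of three arrays (dx, dy, dz) in mm on the image grid.
#' @export
phaseDeformationField <- function(dims, spacing, amplitudeMm, seed) {
  if (amplitudeMm < 0) stop("amplitudeMm must be >= 0")
  nc <- c(5L, 5L, 4L)
  comps <- .withSeed(seed, {
    lapply(1:3, function(a) array(rnorm(prod(nc)), nc))
  })
  nrm <- sqrt(comps[[1]]^2 + comps[[2]]^2 + comps[[3]]^2)
  scale <- if (max(nrm) > 0) amplitudeMm / max(nrm) else 0
  Ms <- lapply(1:3, function(a) .interpMatrix(nc[a], dims[a], order = 1))
  lapply(comps, function(cmp) {
    f <- cmp * scale
    f <- .applyAxis(f, Ms[[1]], 1)
    f <- .applyAxis(f, Ms[[2]], 2)
    .applyAxis(f, Ms[[3]], 3)
  })
}

#' Append pseudo-reconstruction phases to a case
#'
#' Emulates multi-phase cardiac reconstructions by warping phase 0 with
#' small smooth random deformations (max displacement <= amplitudeMm);
#' labels are unchanged.
#'
#' @param case a [CaseRecord-class] with at least one volume.
#' @param nPhases total number of phases after the call.
#' @param amplitudeMm maximum displacement (mm); 0 duplicates phase 0.
#' @param seed RNG seed.
#' @return the case with nPhases volumes.
#' @export
simulatePhases <- function(case, nPhases, amplitudeMm = 1.5, seed = 1L) {
  stopifnot(is(case, "CaseRecord"))
  if (amplitudeMm < 0) stop("amplitudeMm must be >= 0")
  if (nPhases <= length(case@volumes)) return(case)
  v0 <- case@volumes[[1]]
  d <- dim(v0@data); sp <- v0@spacing
  base <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]), z = seq_len(d[3]))
  base <- as.matrix(base)
  for (k in (length(case@volumes) + 1L):nPhases) {
    fld <- phaseDeformationField(d, sp, amplitudeMm, .deriveSeed(seed, k))
    coords <- base
    coords[, 1] <- pmin(pmax(base[, 1] + fld[[1]] / sp[1], 1), d[1])
    coords[, 2] <- pmin(pmax(base[, 2] + fld[[2]] / sp[2], 1), d[2])
    coords[, 3] <- pmin(pmax(base[, 3] + fld[[3]] / sp[3], 1), d[3])
    warped <- .sampleTrilinear(v0@data, coords)
    dim(warped) <- d
    case@volumes[[length(case@volumes) + 1L]] <-
      ImageVolume(warped, spacing = sp, origin = v0@origin)
  }
  validObject(case)
  case
}

#' Per-case configurations for a cohort
#'
#' Apportions nCases among the requested (class, course) strata with
#' largest-remainder rounding and derives one deterministic sub-seed per
#' case from the master seed.
#'
#' @param nCases number of cases (>= 1).
#' @param classMix named proportions (summing to 1) over strata named
#'   either "normal" or "<class>/<course>", e.g. "R-AAOCA/interarterial".
#' @param baseConfig template [phantomConfig()].
#' @param seed master seed.
#' @return list of per-case lists (caseId, config, group).
#' @export
cohortConfigs <- function(nCases, classMix, baseConfig = phantomConfig(),
                          seed = 1L) {
  if (nCases < 1) stop("nCases must be >= 1")
  if (abs(sum(classMix) - 1) > 1e-8) stop("classMix must sum to 1")
  counts <- .largestRemainder(nCases, classMix)
  strata <- rep(names(classMix), counts)
  sex <- .withSeed(.deriveSeed(seed, 7L),
                   sample(c("F", "M"), nCases, replace = TRUE))
  lapply(seq_len(nCases), function(i) {
    parts <- strsplit(strata[i], "/", fixed = TRUE)[[1]]
    cls <- parts[1]
    crs <- if (length(parts) > 1) parts[2] else "normal"
    cfg <- baseConfig
    cfg$anomalyClass <- cls
    cfg$course <- crs
    cfg$seed <- .deriveSeed(seed, i)
    list(caseId = sprintf("case_%04d", i), config = cfg,
         group = list(sex = sex[i]))
  })
}

#' Generate a phantom cohort (and optionally write it to disk)
#'
#' @inheritParams cohortConfigs
#' @param outDir optional directory; when given, one NIfTI per phase plus a
#'   label-map NIfTI and a manifest CSV are written.
#' @param keepCases keep the CaseRecord objects in the return value
#'   (disable for large cohorts).
#' @return list(manifest = data.frame, cases = list or NULL).
#' @export
generateCohort <- function(nCases, classMix, baseConfig = phantomConfig(),
                           seed = 1L, outDir = NULL, keepCases = TRUE) {
  cfgs <- cohortConfigs(nCases, classMix, baseConfig, seed)
  if (!is.null(outDir) && !dir.exists(outDir) &&
      !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", outDir)
  rows <- vector("list", length(cfgs))
  cases <- if (keepCases) vector("list", length(cfgs)) else NULL
  for (i in seq_along(cfgs)) {
    cc <- cfgs[[i]]
    rec <- generatePhantom(cc$config)
    rec@caseId <- cc$caseId
    rec@group <- cc$group
    phasePaths <- labelPath <- NA_character_
    if (!is.null(outDir)) {
      phasePaths <- vapply(seq_along(rec@volumes), function(p) {
        f <- file.path(outDir, sprintf("%s_phase%d.nii.gz", cc$caseId, p))
        writeVolume(rec@volumes[[p]], f)
        f
      }, "")
      labelPath <- file.path(outDir, sprintf("%s_labels.nii.gz", cc$caseId))
      writeVolume(rec@labelMap, labelPath)
      phasePaths <- paste(phasePaths, collapse = ";")
    }
    rows[[i]] <- data.frame(case_id = cc$caseId, phase_paths = phasePaths,
                            label_path = labelPath,
                            y_anomaly = rec@yAnomaly,
                            y_origin = rec@yOrigin, y_risk = rec@yRisk,
                            course = rec@course, group = cc$group$sex,
                            seed = cc$config$seed,
                            stringsAsFactors = FALSE)
    if (keepCases) cases[[i]] <- rec
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(outDir))
    write.csv(manifest, file.path(outDir, "manifest.csv"), row.names = FALSE)
  list(manifest = manifest, cases = cases)
}
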