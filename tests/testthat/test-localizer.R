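# Root-point location and fixed-size physical cropping.

# analytic mask helpers on a unit-spacing grid
sphereMask <- function(dims, center, r) {
  xs <- seq_len(dims[1]) - 1; ys <- seq_len(dims[2]) - 1
  zs <- seq_len(dims[3]) - 1
  outer(outer((xs - center[1])^2, (ys - center[2])^2, "+"),
        (zs - center[3])^2, "+") <= r^2
}

test_that("two tangent spheres locate the contact voxel exactly", {
  dims <- c(40L, 40L, 40L)
  # spheres of radius 5 centred 11 apart along x: tangent gap at x = 20,
  # contact found by 1-voxel dilation symmetric about the gap
  a <- sphereMask(dims, c(14, 20, 20), 5.2)
  b <- sphereMask(dims, c(26, 20, 20), 5.2)
  expect_false(any(a & b))
  rp <- findRootPoint(a, b, spacing = c(1, 1, 1))
  expect_equal(unname(rp$pointMm), c(20, 20, 20), tolerance = 1e-8)
  expect_equal(unname(rp$adjustedPointMm), c(30, 20, 30), tolerance = 1e-8)
})

test_that("literal mask intersection takes precedence and degenerates sanely", {
  dims <- c(30L, 30L, 30L)
  a <- sphereMask(dims, c(15, 15, 15), 6)
  rp <- findRootPoint(a, a, spacing = c(1, 1, 1), offsetMm = c(0, 0, 0))
  idx <- which(a, arr.ind = TRUE) - 1
  expect_equal(unname(rp$pointMm), unname(colMeans(idx)), tolerance = 1e-8)
  b <- sphereMask(dims, c(15, 15, 28), 2)   # 5-voxel surface gap: no contact
  expect_error(findRootPoint(a, b, maxDilate = 3L), "no aorto-ventricular")
  expect_error(findRootPoint(a, array(FALSE, dims)), "non-empty")
})

test_that("crop box realises the 8 x 8 x 6 cm physical extent", {
  rp <- structure(list(pointMm = c(90, 90, 60),
                       adjustedPointMm = c(100, 90, 70)),
                  class = "RootPoint")
  grid1 <- ImageVolume(array(0, c(200, 200, 140)), spacing = c(1, 1, 1))
  box <- computeCropBox(rp, grid1)
  expect_equal(box@extentMm, c(80, 80, 60))
  expect_equal(box@voxelStop - box@voxelStart, c(80L, 80L, 60L))
  grid2 <- ImageVolume(array(0, c(400, 400, 140)),
                       spacing = c(0.5, 0.5, 1.0))
  box2 <- computeCropBox(rp, grid2)
  expect_equal(box2@voxelStop - box2@voxelStart, c(160L, 160L, 60L))
  # physical size within one voxel of the request on anisotropic grids
  grid3 <- ImageVolume(array(0, c(300, 300, 100)), spacing = c(0.7, 0.9, 1.3))
  box3 <- computeCropBox(rp, grid3)
  size <- (box3@voxelStop - box3@voxelStart) * spacing(grid3)
  expect_true(all(size >= c(80, 80, 60) - 1e-9))
  expect_true(all(size < c(80, 80, 60) + spacing(grid3)))
})

test_that("offset defaults to 1 cm right + 1 cm superior, applied once", {
  dims <- c(40L, 40L, 40L)
  a <- sphereMask(dims, c(14, 20, 20), 5.2)
  b <- sphereMask(dims, c(26, 20, 20), 5.2)
  rp <- findRootPoint(a, b)
  expect_equal(rp$adjustedPointMm - rp$pointMm, c(10, 0, 10))
  rp0 <- findRootPoint(a, b, offsetMm = c(0, 0, 0))
  expect_equal(rp0$adjustedPointMm, rp0$pointMm)
})

test_that("cropping indexes interior boxes and pads exterior ones", {
  vol <- ImageVolume(array(rnorm(40 * 40 * 40), c(40, 40, 40)))
  boxIn <- new("CropBox", centerMm = c(20, 20, 20),
               extentMm = c(10, 10, 10), voxelStart = c(15L, 15L, 15L),
               voxelStop = c(25L, 25L, 25L))
  crop <- cropVolume(vol, boxIn)
  expect_equal(dim(crop@data), c(10, 10, 10))
  expect_equal(crop@data, vol@data[16:25, 16:25, 16:25])
  expect_equal(crop@origin, c(15, 15, 15))
  # box centred on the image corner: exactly the out-of-image 7/8 padded
  boxCorner <- new("CropBox", centerMm = c(0, 0, 0),
                   extentMm = c(10, 10, 10),
                   voxelStart = c(-5L, -5L, -5L), voxelStop = c(5L, 5L, 5L))
  cc <- cropVolume(vol, boxCorner, padValue = -1024)
  expect_equal(sum(cc@data == -1024) >= 1000 - 125, TRUE)
  expect_equal(cc@data[6:10, 6:10, 6:10], vol@data[1:5, 1:5, 1:5])
  # analytic padded-fraction arithmetic on a zero volume, half-out box
  zero <- ImageVolume(array(0, c(40, 40, 40)))
  boxHalf <- new("CropBox", centerMm = c(0, 20, 20),
                 extentMm = c(10, 10, 10),
                 voxelStart = c(-5L, 15L, 15L), voxelStop = c(5L, 25L, 25L))
  ch <- cropVolume(zero, boxHalf, padValue = -1024)
  expect_equal(mean(ch@data), -1024 * 0.5)
  expect_error(cropVolume(vol, new("CropBox", centerMm = c(-90, 0, 0),
                                   extentMm = c(10, 10, 10),
                                   voxelStart = c(-99L, 0L, 0L),
                                   voxelStop = c(-89L, 10L, 10L))),
               "outside")
})

test_that("crop location is translation-equivariant on phantoms", {
  rec <- fixturePhantom(seed = 21L)
  lm <- rec@labelMap
  rp <- findRootPoint(structureMask(lm, "aorta"), lvMask(lm),
                      spacing = spacing(lm))
  box <- computeCropBox(rp, lm)
  shift <- c(3L, -2L, 2L)
  shifted <- coroscreen:::.shiftArray(lm@data, shift, fill = 0L)
  lm2 <- LabelMap(shifted, spacing = spacing(lm))
  rp2 <- findRootPoint(structureMask(lm2, "aorta"), lvMask(lm2),
                       spacing = spacing(lm2))
  box2 <- computeCropBox(rp2, lm2)
  expect_equal(box2@voxelStart, box@voxelStart + shift)
})

test_that("naive segmentation supports cropping on phantom images", {
  rec <- fixturePhantom(seed = 3L)
  seg <- naiveSegment(rec@volumes[[1]])
  dice <- coroscreen:::.dice(structureMask(seg, "aorta"),
                             structureMask(rec@labelMap, "aorta"))
  expect_gte(dice, 0.95)
  expect_error(naiveSegment(ImageVolume(array(-1000, c(30, 30, 30)))),
               "no contrast-range component")
  # noise-free phantom: crop box from the naive segmentation agrees with
  # the ground-truth-label crop box to within the rounding granularity
  rec0 <- fixturePhantom(seed = 3L, noise = 0)
  seg0 <- naiveSegment(rec0@volumes[[1]])
  rpGT <- findRootPoint(structureMask(rec0@labelMap, "aorta"),
                        lvMask(rec0@labelMap),
                        spacing = spacing(rec0@labelMap))
  rpSeg <- findRootPoint(structureMask(seg0, "aorta"), lvMask(seg0),
                         spacing = spacing(seg0))
  bGT <- computeCropBox(rpGT, rec0@labelMap)
  bSeg <- computeCropBox(rpSeg, rec0@labelMap)
  expect_true(all(abs(bGT@voxelStart - bSeg@voxelStart) <= 2L))
})
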