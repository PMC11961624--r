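# Augmentation transforms: identities, statistical contracts, artifact
# locality, and pipeline composition.

rt <- function(d = c(12, 10, 8), seed = 1) {
  set.seed(seed)
  array(runif(prod(d)), d)
}

test_that("zero-magnitude transforms are bitwise identities", {
  x <- rt()
  expect_identical(addNoise(x, 0), x)
  expect_identical(blurTensor(x, 0), x)
  expect_identical(adjustContrast(x, 1), x)
  expect_identical(simulateMotion(x, nGhosts = 1L), x)
  expect_identical(simulateMotion(x, nGhosts = 4L,
                                  weights = c(1, 0, 0, 0)), x)
  expect_identical(simulateStepArtifact(x, maxShiftMm = 0), x)
  cfg0 <- augmentationConfig(pNoise = 0, pBlur = 0, pContrast = 0,
                             pMotion = 0, pStep = 0)
  expect_identical(augmentTensor(x, cfg0, seed = 1L), x)
})

test_that("every transform maps [0,1] tensors to [0,1], same shape", {
  x <- rt()
  set.seed(5)
  outs <- list(addNoise(x, 0.3),
               blurTensor(x, 2, c(1, 1, 1)),
               adjustContrast(x, 0.4),
               simulateMotion(x, 3L, 4),
               simulateStepArtifact(x, maxShiftMm = 5))
  for (o in outs) {
    expect_equal(dim(o), dim(x))
    expect_true(all(o >= 0 & o <= 1))
  }
})

test_that("noise is zero-mean at the CLT scale and clamps to [0,1]", {
  x <- array(0.5, c(20, 20, 20))
  set.seed(7)
  sigma <- 0.05
  y <- addNoise(x, sigma)
  expect_lt(abs(mean(y) - 0.5), 3 * sigma / sqrt(length(x)))
})

test_that("blur uses a unit-sum kernel: periodic padding preserves the mean", {
  x <- rt(c(16, 16, 12), seed = 3)
  y <- blurTensor(x, sigmaMm = 1.2, spacingMm = c(1, 1, 1),
                  mode = "periodic")
  expect_lt(abs(mean(y) - mean(x)), 1e-6)
})

test_that("motion ghosting is a convex combination of shifts", {
  x <- rt()
  # all shifts equal to d collapses to a single shifted copy
  d <- c(2L, -1L, 0L)
  shifts <- rbind(d, d, d)
  y <- simulateMotion(x, 3L, 5, weights = c(0.2, 0.3, 0.5), shifts = shifts)
  # the first row is forced to zero shift; use identical non-first shifts
  y2 <- simulateMotion(x, 3L, 5, weights = c(0, 0.4, 0.6),
                       shifts = rbind(c(0L, 0L, 0L), d, d))
  expect_equal(y2, coroscreen:::.shiftArray(x, d, fill = 0),
               tolerance = 1e-12)
  expect_error(simulateMotion(x, 3L, 5, weights = c(0.5, 0.5)), "weights")
  expect_error(simulateMotion(x, 0L), "nGhosts")
})

test_that("step artifact alters exactly the slices at and above the break", {
  x <- rt(c(14, 12, 10), seed = 9)
  s <- 4L
  y <- simulateStepArtifact(x, slabAxis = 3L, maxShiftMm = 3,
                            s = s, shiftVox = c(2L, -1L))
  changed <- apply(abs(y - x) > 0, 3, any)
  expect_false(any(changed[seq_len(s)]))
  expect_true(all(changed[(s + 1):10]))
  # boundary cases: s = 0 shifts everything, s = depth is the identity
  y0 <- simulateStepArtifact(x, 3L, 3, s = 0L, shiftVox = c(1L, 1L))
  expect_equal(y0, coroscreen:::.shiftArray(x, c(1L, 1L, 0L), fill = 0))
  expect_identical(simulateStepArtifact(x, 3L, 3, s = 10L,
                                        shiftVox = c(1L, 1L)), x)
  expect_error(simulateStepArtifact(array(0, c(4, 4, 1)), 3L, 3), "slices")
})

test_that("composition is deterministic and reduces to single stages", {
  x <- rt()
  cfg <- augmentationConfig()
  expect_identical(augmentTensor(x, cfg, seed = 11L),
                   augmentTensor(x, cfg, seed = 11L))
  # probability-1 noise alone equals addNoise under the same stream
  cfgN <- augmentationConfig(pNoise = 1, pBlur = 0, pContrast = 0,
                             pMotion = 0, pStep = 0, noiseSigma = 0.04)
  got <- augmentTensor(x, cfgN, seed = 13L)
  set.seed(13L)
  u <- runif(1)                      # the apply-draw consumed by augment
  want <- addNoise(x, 0.04)
  expect_identical(got, want)
})
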