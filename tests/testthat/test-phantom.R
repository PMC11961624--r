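# Synthetic phantom generator: determinism, label-map structure, tissue
# intensities, course geometry, cohort apportionment, phase simulation.

test_that("identical config and seed give bitwise-identical phantoms", {
  cfg <- phantomConfig(anomalyClass = "R-AAOCA", course = "interarterial",
                       seed = 5L)
  a <- generatePhantom(cfg)
  b <- generatePhantom(cfg)
  expect_identical(a@volumes[[1]]@data, b@volumes[[1]]@data)
  expect_identical(a@labelMap@data, b@labelMap@data)
})

test_that("label regions are non-empty, disjoint and singly connected", {
  rec <- fixturePhantom()
  lm <- rec@labelMap
  for (nm in names(labelCodes(lm))) {
    m <- structureMask(lm, nm)
    expect_gt(sum(m), 0)
    expect_equal(max(coroscreen:::.label_components(m)), 1,
                 label = paste("components of", nm))
  }
  # one label per voxel => regions disjoint by construction; verify codes
  expect_true(all(lm@data %in% c(0L, labelCodes(lm))))
})

test_that("region mean HU matches the configured tissue values", {
  cfg <- phantomConfig(anomalyClass = "L-AAOCA", course = "retroaortic",
                       seed = 9L)
  rec <- generatePhantom(cfg)
  img <- rec@volumes[[1]]@data
  want <- c(aorta = "blood_pool_contrast", lv_myocardium = "myocardium",
            lv_cavity = "blood_pool_contrast",
            pulmonary_artery = "pa_blood", coronary = "coronary_contrast")
  for (nm in names(want)) {
    m <- structureMask(rec@labelMap, nm)
    n <- sum(m)
    expect_lt(abs(mean(img[m]) - cfg$tissueHu[[want[[nm]]]]),
              3 * cfg$noiseSigmaHu / sqrt(n))
  }
})

test_that("normal cases carry no origin or risk label", {
  rec <- generatePhantom(phantomConfig(seed = 2L))
  expect_identical(rec@yAnomaly, 0L)
  expect_true(is.na(rec@yOrigin))
  expect_true(is.na(rec@yRisk))
  expect_error(phantomConfig(anomalyClass = "normal", course = "interarterial"),
               "course")
  expect_error(phantomConfig(anomalyClass = "R-AAOCA", course = "normal"),
               "course")
})

test_that("risk labels derive mechanically from the course taxonomy", {
  expect_identical(courseRisk("interarterial"), "high")
  expect_identical(courseRisk("subpulmonic"), "high")
  expect_identical(courseRisk("prepulmonic"), "low")
  expect_identical(courseRisk("retroaortic"), "low")
  expect_identical(courseRisk("high_takeoff"), "low")
  expect_true(is.na(courseRisk("normal")))
})

test_that("course geometric predicates hold on generated centerlines", {
  # predicates recomputed here from the realised geometry, independently
  # of the rasteriser
  for (case in list(c("R-AAOCA", "interarterial"),
                    c("L-AAOCA", "interarterial"),
                    c("R-AAOCA", "prepulmonic"), c("L-AAOCA", "prepulmonic"),
                    c("R-AAOCA", "retroaortic"), c("L-AAOCA", "retroaortic"),
                    c("R-AAOCA", "high_takeoff"),
                    c("R-AAOCA", "subpulmonic"), c("L-AAOCA", "subpulmonic")))
    for (seed in c(11L, 222L)) {
      cfg <- phantomConfig(anomalyClass = case[1], course = case[2],
                           seed = seed)
      rec <- generatePhantom(cfg)
      g <- phantomGeometry(cfg)
      A <- g$aorta$axisXY; P <- g$pa$axisXY
      Ra <- g$aorta$radius; Rp <- g$pa$radius
      dAP <- sqrt(sum((P - A)^2)); u <- (P - A) / dAP
      cl <- rec@centerline
      pr <- proximalSegment(cl, 20)
      ok <- switch(case[2],
        interarterial = {   # proximal 2 cm projects between the surfaces
          t <- (pr[, 1:2] - matrix(A, nrow(pr), 2, byrow = TRUE)) %*% u
          all(t >= Ra - 1e-6 & t <= dAP - Rp + 1e-6)
        },
        prepulmonic = {     # anterior to the PA centroid inside its slab
          slab <- abs(cl[, 1] - P[1]) <= Rp &
            cl[, 3] >= g$pa$zRange[1] & cl[, 3] <= g$pa$zRange[2]
          sum(slab) > 0 && all(cl[slab, 2] > P[2])
        },
        retroaortic = {     # posterior to the aorta centroid
          zone <- abs(cl[, 1] - A[1]) <= Ra
          all(cl[zone, 2] < A[2]) && all(pr[, 2] < A[2])
        },
        high_takeoff =      # ostium above the sinotubular junction
          cl[1, 3] >= g$aorta$stjZ + cfg$highTakeoffMm - 1e-6,
        subpulmonic = {     # inferior to the PA centroid, anterior to aorta
          all(pr[, 3] < mean(g$pa$zRange)) && all(pr[, 2] > A[2])
        })
      expect_true(ok, label = paste(case[1], case[2], "seed", seed))
    }
})

test_that("too-small grids fail naming the limiting structure", {
  expect_error(generatePhantom(phantomConfig(gridShape = c(48L, 48L, 24L),
                                             seed = 1L)),
               "grid too small.*lv_myocardium|grid too small.*aorta")
})

test_that("cohort apportionment follows largest-remainder rounding", {
  mix <- setNames(rep(1 / 6, 6),
                  c("normal", "R-AAOCA/interarterial",
                    "L-AAOCA/prepulmonic", "R-AAOCA/retroaortic",
                    "L-AAOCA/high_takeoff", "R-AAOCA/subpulmonic"))
  cfgs <- cohortConfigs(100L, mix, seed = 3L)
  courses <- vapply(cfgs, function(x) x$config$course, "")
  # independent largest-remainder computation: 100/6 = 16.67 each ->
  # base 16 with 4 strata rounded up
  counts <- as.vector(table(factor(
    vapply(cfgs, function(x)
      paste0(x$config$anomalyClass,
             ifelse(x$config$course == "normal", "", paste0("/", x$config$course))),
      ""), levels = names(mix))))
  expect_equal(sum(counts), 100)
  expect_true(all(counts %in% c(16, 17)))
  expect_equal(sum(counts == 17), 4)
  expect_error(cohortConfigs(0L, mix), "nCases")
  expect_error(cohortConfigs(10L, mix * 2), "sum to 1")
})

test_that("a rounding-free mix yields exact class labels", {
  res <- generateCohort(10L, c(normal = 0.5,
                               `R-AAOCA/interarterial` = 0.5), seed = 4L)
  expect_equal(sum(res$manifest$y_anomaly == 0), 5)
  anom <- res$manifest[res$manifest$y_anomaly == 1, ]
  expect_true(all(anom$y_origin == "right" & anom$y_risk == "high"))
})

test_that("cohorts written to disk round-trip through NIfTI", {
  dir <- withr::local_tempdir()
  res <- generateCohort(2L, c(normal = 0.5, `R-AAOCA/interarterial` = 0.5),
                        baseConfig = phantomConfig(gridShape = c(80L, 80L, 80L),
                                                   spacingMm = rep(1.5, 3)),
                        seed = 8L, outDir = dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  back <- readCohort(dir)
  expect_equal(back$manifest$case_id, res$manifest$case_id)
  i <- which(res$manifest$y_anomaly == 1)[1]
  expect_equal(back$cases[[i]]@labelMap@data, res$cases[[i]]@labelMap@data)
  expect_equal(back$cases[[i]]@volumes[[1]]@data,
               res$cases[[i]]@volumes[[1]]@data, tolerance = 1e-5)
})

test_that("phase simulation respects the displacement bound and identities", {
  rec <- fixturePhantom()
  expect_identical(simulatePhases(rec, 1L, 2, seed = 1L), rec)
  r0 <- simulatePhases(rec, 3L, 0, seed = 1L)
  expect_equal(r0@volumes[[2]]@data, r0@volumes[[1]]@data)
  expect_equal(r0@volumes[[3]]@data, r0@volumes[[1]]@data)
  f <- phaseDeformationField(dim(rec@volumes[[1]]@data),
                             spacing(rec@volumes[[1]]), 2,
                             seed = 77L)
  expect_lte(max(sqrt(f[[1]]^2 + f[[2]]^2 + f[[3]]^2)), 2 + 1e-9)
  expect_error(simulatePhases(rec, 3L, -1), "amplitude")
  r2 <- simulatePhases(rec, 2L, 1.5, seed = 5L)
  expect_identical(r2@labelMap@data, rec@labelMap@data)  # labels untouched
})
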