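# Training machinery: schedule, splitting, checkpoint selection,
# transfer, ensembling arithmetic.

test_that("cosine schedule matches its closed form", {
  expect_equal(cosineLR(0, 300), 0.001)
  expect_equal(cosineLR(300, 300), 0, tolerance = 1e-12)
  expect_equal(cosineLR(150, 300), 0.0005, tolerance = 1e-12)
  for (e in 0:20)
    expect_equal(cosineLR(e, 20, 0.01),
                 0.01 * (1 + cos(pi * e / 20)) / 2, tolerance = 1e-12)
  expect_error(cosineLR(-1, 10), "epoch")
  expect_error(cosineLR(11, 10), "epoch")
})

test_that("patient-wise split is disjoint, sized, and seed-stable", {
  ids <- sprintf("p%03d", 1:100)
  s <- splitPatientwise(ids, 0.9, seed = 5L)
  expect_length(s$val, 10)
  expect_length(s$train, 90)
  expect_length(intersect(s$train, s$val), 0)
  expect_identical(s, splitPatientwise(ids, 0.9, seed = 5L))
  expect_error(splitPatientwise("p1"), "at least 2")
  # all images (repeats) of one patient land on one side by construction
  rep_ids <- rep(ids[1:10], each = 4)
  s2 <- splitPatientwise(rep_ids, 0.9, seed = 1L)
  expect_equal(sort(c(s2$train, s2$val)), sort(unique(rep_ids)))
})

test_that("checkpoint selection and early stopping follow the rules", {
  # lowest val loss wins; accuracy breaks ties; earlier epoch breaks both
  expect_equal(coroscreen:::.selectCheckpoint(c(0.5, 0.3, 0.4),
                                              c(0.6, 0.7, 0.9)), 2)
  expect_equal(coroscreen:::.selectCheckpoint(c(0.5, 0.3, 0.3),
                                              c(0.6, 0.7, 0.9)), 3)
  expect_equal(coroscreen:::.selectCheckpoint(c(0.3, 0.3), c(0.8, 0.8)), 1)
  # scripted trajectory: best at epoch 3, rising after; patience 2 halts
  # by epoch 5
  traj <- c(0.6, 0.5, 0.4, 0.45, 0.5, 0.55)
  stops <- vapply(seq_along(traj), function(k)
    coroscreen:::.shouldStop(traj[1:k], patience = 2L), TRUE)
  expect_false(any(stops[1:4]))
  expect_true(stops[5])
})

test_that("task labels implement the conditional cascade", {
  man <- data.frame(case_id = c("a", "b", "c"),
                    y_anomaly = c(0L, 1L, 1L),
                    y_origin = c(NA, "right", "left"),
                    y_risk = c(NA, "high", "low"))
  expect_equal(unname(taskLabels(man, "anomaly")), c(0L, 1L, 1L))
  expect_equal(unname(taskLabels(man, "origin")), c(NA, 0L, 1L))
  expect_equal(unname(taskLabels(man, "risk")), c(NA, 1L, 0L))
})

test_that("ensemble and phase aggregation are arithmetic means", {
  probs <- matrix(c(0.2, 0.4, 0.6, 0.8, 1.0), 1)
  ps <- predictionSet(probs, "case1")
  expect_equal(ps@ensembleProb, 0.6)
  single <- predictionSet(matrix(0.37, 1), "case1")
  expect_equal(single@ensembleProb, 0.37)
  # ensemble mean is permutation-invariant and bounded by member range
  set.seed(2)
  m <- matrix(runif(15), 3)
  ps3 <- predictionSet(m, c("a", "b", "c"))
  psPerm <- predictionSet(m[, c(3, 1, 5, 2, 4)], c("a", "b", "c"))
  expect_equal(ps3@ensembleProb, psPerm@ensembleProb)
  expect_true(all(ps3@ensembleProb >= apply(m, 1, min) &
                    ps3@ensembleProb <= apply(m, 1, max)))
})

test_that("training runs, stops early on scripted stalls, and transfers", {
  # tiny synthetic "images": bright box present vs absent, linearly
  # separable
  set.seed(1)
  d <- c(12L, 12L, 8L)
  mkimg <- function(pos) {
    x <- array(runif(prod(d), 0, 0.2), d)
    if (pos) x[4:8, 4:8, 3:6] <- x[4:8, 4:8, 3:6] + 0.7
    x
  }
  n <- 24
  y <- rep(c(0L, 1L), n / 2)
  ds <- list(tensors = lapply(y == 1, mkimg),
             caseId = sprintf("c%02d", seq_len(n)),
             manifest = data.frame(case_id = sprintf("c%02d", seq_len(n)),
                                   y_anomaly = y,
                                   y_origin = ifelse(y == 1, "right", NA),
                                   y_risk = ifelse(y == 1, "high", NA)))
  net <- networkConfig("tiny", inputDims = d, baseChannels = 4L,
                       seReduction = 2L)
  tr <- trainTask(ds, "anomaly", net,
                  trainConfig(totalEpochs = 6L, patience = 6L,
                              nMembers = 2L, lr0 = 0.01, batchSize = 8L,
                              seed = 3L))
  expect_length(tr$members, 2)
  expect_true(all(is.finite(tr$history$valLoss)))
  expect_true(max(tr$history$epoch) <= 6)
  expect_length(intersect(tr$split$train, tr$split$val), 0)
  # probabilities from the trained ensemble separate the classes
  probs <- rowMeans(predictTensors(tr, ds$tensors))
  expect_gt(rocAUC(probs, y), 0.9)
  # transfer: fine-tune with 0 epochs = pretrained backbone + fresh head
  ft0 <- fineTune(tr, ds, "risk",
                  trainConfig(totalEpochs = 0L, nMembers = 2L, seed = 4L))
  m1 <- ft0$members[[1]]
  expect_identical(m1$layers$stem_conv$w, tr$members[[1]]$layers$stem_conv$w)
  expect_false(identical(m1$layers$fc$w, tr$members[[1]]$layers$fc$w))
  # single-class partition raises a stratification error
  dsBad <- ds
  dsBad$manifest$y_anomaly <- 1L
  expect_error(trainTask(dsBad, "anomaly", net,
                         trainConfig(totalEpochs = 2L, nMembers = 1L)),
               "stratification|single class")
})

test_that("checkpoints round-trip through disk", {
  model <- fixtureTinyNet()
  tr <- structure(list(task = "anomaly", members = list(model),
                       history = NULL, split = NULL,
                       netConfig = model$config,
                       trainConfig = trainConfig(nMembers = 1L)),
                  class = "TrainedTask")
  dir <- withr::local_tempdir()
  saveCheckpoint(tr, dir)
  expect_true(file.exists(file.path(dir, "config.json")))
  back <- loadCheckpoint(dir)
  x <- array(runif(16 * 16 * 8), c(16, 16, 8))
  expect_identical(netForward(back$members[[1]], x)$prob,
                   netForward(model, x)$prob)
})
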