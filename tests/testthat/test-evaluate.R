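# Evaluation: confusion/metric arithmetic, AUC pair-statistic oracle,
# bootstrap behaviour, cutoff sweeps, grouped reports.

# brute-force pair-counting oracle for the Mann-Whitney AUC
aucPairs <- function(probs, labels) {
  pos <- probs[labels == 1]; neg <- probs[labels == 0]
  s <- 0
  for (p in pos) for (q in neg)
    s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

test_that("confusion matrices follow the >= cutoff boundary rule", {
  cm <- confusionAtCutoff(c(0.9, 0.1), c(1, 0), 0.5)
  expect_equal(unlist(cm[c("tp", "tn", "fp", "fn")]),
               c(tp = 1, tn = 1, fp = 0, fn = 0))
  # a probability exactly at the cutoff counts positive
  cmEq <- confusionAtCutoff(c(0.5), c(1), 0.5)
  expect_equal(cmEq$tp, 1)
  cm0 <- confusionAtCutoff(c(0.3, 0.8), c(0, 1), 0)
  expect_equal(cm0$tn + cm0$fn, 0)
  expect_error(confusionAtCutoff(c(0.5), c(1, 0)), "length")
})

test_that("point metrics and their degenerate cases", {
  cm <- confusionAtCutoff(c(rep(0.9, 9), 0.1), c(rep(1, 10)), 0.5)
  expect_equal(classificationMetrics(cm)[["sensitivity"]], 0.9)
  # tp = fp = 0 leaves PPV undefined, not zero
  cmU <- confusionAtCutoff(c(0.1, 0.2), c(1, 0), 0.9)
  expect_true(is.na(classificationMetrics(cmU)[["ppv"]]))
  # tp=8 fp=2 fn=2: ppv = sens = f1 = 0.8
  m <- classificationMetrics(structure(list(tp = 8, fp = 2, tn = 0, fn = 2,
                                            cutoff = 0.5),
                                       class = "ConfusionMatrix"))
  expect_equal(unname(m[c("ppv", "sensitivity", "f1")]), c(0.8, 0.8, 0.8))
})

test_that("rocAUC equals exhaustive pair counting, including ties", {
  expect_equal(rocAUC(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(rocAUC(rep(0.4, 10), rep(c(0, 1), 5)), 0.5)
  set.seed(31)
  for (i in 1:50) {
    n <- sample(4:50, 1)
    probs <- if (i %% 3 == 0) sample(seq(0, 1, 0.25), n, replace = TRUE)
             else runif(n)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    expect_equal(rocAUC(probs, labels), aucPairs(probs, labels),
                 tolerance = 1e-12)
  }
  expect_error(rocAUC(runif(5), rep(1, 5)), "both classes")
})

test_that("AUC invariances hold", {
  set.seed(7)
  probs <- runif(40); labels <- c(0, 1, sample(0:1, 38, TRUE))
  a <- rocAUC(probs, labels)
  expect_equal(rocAUC(1 - probs, labels), 1 - a, tolerance = 1e-12)
  expect_equal(rocAUC(plogis(5 * probs - 2), labels), a, tolerance = 1e-12)
})

test_that("rocAUC agrees with an independent reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(11)
  for (i in 1:10) {
    probs <- round(runif(30), 2)
    labels <- c(0, 1, sample(0:1, 28, TRUE))
    ref <- as.numeric(pROC::auc(pROC::roc(labels, probs, quiet = TRUE,
                                          direction = "<")))
    expect_equal(rocAUC(probs, labels), ref, tolerance = 1e-9)
  }
})

test_that("prAUC step integration matches a hand computation", {
  # scores 0.9(+), 0.8(-), 0.7(+): recall steps 1/2 at P=1, 1/2->1 at 2/3
  expect_equal(prAUC(c(0.9, 0.8, 0.7), c(1, 0, 1)),
               0.5 * 1 + 0.5 * (2 / 3))
  expect_equal(prAUC(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
})

test_that("bootstrap intervals are deterministic with degenerate limits", {
  probs <- c(0.9, 0.8, 0.7, 0.3, 0.2, 0.4)
  labels <- c(1, 1, 1, 0, 0, 0)
  ci1 <- bootstrapInterval(rocAUC, probs, labels, nIter = 200L, seed = 9L)
  ci2 <- bootstrapInterval(rocAUC, probs, labels, nIter = 200L, seed = 9L)
  expect_identical(ci1, ci2)
  expect_true(ci1[1] <= ci1[2])
  # constant metric collapses the interval
  cc <- bootstrapInterval(function(p, l) 0.42, probs, labels,
                          nIter = 50L, seed = 1L)
  expect_equal(unname(cc[1:2]), c(0.42, 0.42))
  # a single iteration degenerates to that resample's metric
  c1 <- bootstrapInterval(rocAUC, probs, labels, nIter = 1L, seed = 2L)
  expect_equal(c1[1], c1[2])
  # tolerance band: pointwise ROC percentiles on the fpr grid
  tb <- bootstrapInterval(rocAUC, probs, labels, nIter = 50L, seed = 3L,
                          kind = "tolerance")
  expect_equal(names(tb), c("fpr", "low", "high"))
  expect_true(all(tb$low <= tb$high + 1e-12))
  expect_error(bootstrapInterval(rocAUC, probs, labels, nIter = 0L), "nIter")
})

test_that("cutoff sweeps are monotone over the default 0.1..0.9 grid", {
  set.seed(13)
  for (i in 1:5) {
    probs <- runif(60)
    labels <- rbinom(60, 1, probs)   # correlated labels
    if (length(unique(labels)) < 2) next
    sw <- cutoffSweep(probs, labels)
    expect_equal(nrow(sw), 9)
    expect_equal(sw$cutoff, seq(0.1, 0.9, 0.1))
    expect_true(all(diff(sw$sensitivity) <= 1e-12))
    expect_true(all(diff(sw$specificity) >= -1e-12))
  }
  expect_error(cutoffSweep(runif(5), rep(0:1, 3)[1:5], numeric(0)),
               "non-empty")
})

test_that("grouped reports are consistent with pooling", {
  set.seed(17)
  probs <- runif(40)
  labels <- rbinom(40, 1, probs)
  groups <- rep(c("F", "M"), 20)
  rep_ <- groupedReport(probs, labels, groups)
  expect_named(rep_, c("pooled", "F", "M"))
  # identical predictions per group give identical reports
  g2 <- groupedReport(c(probs[1:20], probs[1:20]),
                      c(labels[1:20], labels[1:20]),
                      rep(c("A", "B"), each = 20))
  expect_equal(g2$A, g2$B)
  # pooled confusion = sum of group confusions at a fixed cutoff
  cmAll <- confusionAtCutoff(probs, labels, 0.5)
  cmF <- confusionAtCutoff(probs[groups == "F"], labels[groups == "F"], 0.5)
  cmM <- confusionAtCutoff(probs[groups == "M"], labels[groups == "M"], 0.5)
  for (f in c("tp", "fp", "tn", "fn"))
    expect_equal(cmAll[[f]], cmF[[f]] + cmM[[f]])
  # single-class group: AUC undefined (NA), not 0
  gg <- groupedReport(c(0.2, 0.8, 0.6), c(1, 1, 0), c("x", "x", "y"))
  expect_true(is.na(gg$x$value[gg$x$metric == "roc_auc"]))
})
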