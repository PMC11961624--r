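# Classification evaluation: confusion matrices at fixed and swept
# cutoffs, the Table-1 metric set (ROC AUC, sensitivity, specificity, F1,
# PPV, AUPR, accuracy), percentile-bootstrap confidence and tolerance
# intervals, and group-disaggregated (e.g. sex-stratified) reporting.
# The canonical AUC is the Mann-Whitney pair statistic (ties count 1/2).

#' Confusion matrix at a probability cutoff
#'
#' Predicted positive iff prob >= cutoff (the boundary counts positive).
#'
#' @param probs probabilities in [0, 1].
#' @param labels binary labels (0/1), same length.
#' @param cutoff decision threshold.
#' @return list of class "ConfusionMatrix" (tp, fp, tn, fn, cutoff).
#' @export
confusionAtCutoff <- function(probs, labels, cutoff = 0.5) {
  if (length(probs) != length(labels))
    stop("probs and labels must have the same length")
  if (any(probs < 0 | probs > 1)) stop("probs must lie in [0, 1]")
  pred <- probs >= cutoff
  pos <- labels == 1
  structure(list(tp = sum(pred & pos), fp = sum(pred & !pos),
                 tn = sum(!pred & !pos), fn = sum(!pred & pos),
                 cutoff = cutoff),
            class = "ConfusionMatrix")
}

#' Point classification metrics from a confusion matrix
#'
#' F1 is the harmonic mean of precision (PPV) and recall (sensitivity).
#' Metrics with an empty denominator are reported as NA (undefined), not 0.
#'
#' @param cm a [confusionAtCutoff()] result.
#' @return named numeric vector (sensitivity, specificity, ppv, accuracy,
#'   f1); undefined entries are NA.
#' @export
classificationMetrics <- function(cm) {
  div <- function(a, b) if (b == 0) NA_real_ else a / b
  sens <- div(cm$tp, cm$tp + cm$fn)
  spec <- div(cm$tn, cm$tn + cm$fp)
  ppv <- div(cm$tp, cm$tp + cm$fp)
  acc <- div(cm$tp + cm$tn, cm$tp + cm$tn + cm$fp + cm$fn)
  f1 <- if (is.na(ppv) || is.na(sens) || ppv + sens == 0) NA_real_
        else 2 * ppv * sens / (ppv + sens)
  c(sensitivity = sens, specificity = spec, ppv = ppv, accuracy = acc,
    f1 = f1)
}

#' ROC AUC as the Mann-Whitney pair statistic
#'
#' Equals the probability that a random positive scores above a random
#' negative, with ties counting 1/2; computed from average ranks.
#'
#' @param probs scores.
#' @param labels binary labels; both classes must be present.
#' @return AUC in [0, 1].
#' @export
rocAUC <- function(probs, labels) {
  pos <- labels == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be present for AUC")
  r <- rank(probs)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Step integration of the precision-recall curve over distinct score
#' thresholds (no trapezoids): sum over recall increments of the precision
#' at each threshold.
#'
#' @inheritParams rocAUC
#' @return AUPR in [0, 1].
#' @export
prAUC <- function(probs, labels) {
  pos <- labels == 1
  n1 <- sum(pos)
  if (n1 == 0 || sum(!pos) == 0) stop("both classes must be present for AUPR")
  ord <- order(probs, decreasing = TRUE)
  p <- probs[ord]; y <- pos[ord]
  grp <- cumsum(!duplicated(p))          # tie groups share one threshold
  tpCum <- tapply(cumsum(y), grp, max)
  nCum <- tapply(seq_along(y), grp, max)
  prec <- tpCum / nCum
  rec <- tpCum / n1
  sum(diff(c(0, rec)) * prec)
}

#' ROC curve points
#' @inheritParams rocAUC
#' @return data.frame(fpr, tpr) including the (0,0) and (1,1) endpoints.
#' @export
rocCurve <- function(probs, labels) {
  pos <- labels == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  ord <- order(probs, decreasing = TRUE)
  y <- pos[ord]; p <- probs[ord]
  keep <- !duplicated(p, fromLast = TRUE)   # last index of each tie group
  data.frame(fpr = c(0, cumsum(!y)[keep] / n0),
             tpr = c(0, cumsum(y)[keep] / n1))
}

#' Percentile bootstrap interval for a classification metric
#'
#' Case-level resampling with replacement (respecting the patient-wise
#' unit of independence), percentile 2.5/97.5 limits, deterministic given
#' the seed. Resamples containing a single class are redrawn (bounded
#' retries, counted in the "redraws" attribute). kind = "tolerance"
#' instead returns the pointwise percentile band of the resampled ROC
#' curves on a common FPR grid (the gray plot shading).
#'
#' @param metricFn function(probs, labels) -> scalar, e.g. [rocAUC()].
#' @param probs scores.
#' @param labels binary labels.
#' @param nIter bootstrap iterations (>= 1; 10000 in the reference
#'   analysis).
#' @param seed RNG seed.
#' @param kind "confidence" or "tolerance".
#' @param level interval coverage (default 0.95).
#' @param fprGrid FPR grid for the tolerance band.
#' @return confidence: c(low, high); tolerance: data.frame(fpr, low, high).
#' @export
bootstrapInterval <- function(metricFn, probs, labels, nIter = 1000L,
                              seed = 1L, kind = c("confidence", "tolerance"),
                              level = 0.95, fprGrid = seq(0, 1, 0.01)) {
  kind <- match.arg(kind)
  if (nIter < 1) stop("nIter must be >= 1")
  n <- length(probs)
  alpha <- (1 - level) / 2
  redraws <- 0L
  .withSeed(seed, {
    drawIdx <- function() {
      for (r in seq_len(50L)) {
        idx <- sample.int(n, n, replace = TRUE)
        if (length(unique(labels[idx])) > 1L) return(idx)
        redraws <<- redraws + 1L
      }
      stop("could not draw a two-class bootstrap resample")
    }
    if (kind == "confidence") {
      stats <- vapply(seq_len(nIter), function(i) {
        idx <- drawIdx()
        metricFn(probs[idx], labels[idx])
      }, 0)
      out <- unname(quantile(stats, c(alpha, 1 - alpha), na.rm = TRUE,
                             type = 6))
    } else {
      curves <- vapply(seq_len(nIter), function(i) {
        idx <- drawIdx()
        rc <- rocCurve(probs[idx], labels[idx])
        # step interpolation of tpr on the common fpr grid
        vapply(fprGrid, function(f) max(rc$tpr[rc$fpr <= f]), 0)
      }, numeric(length(fprGrid)))
      qs <- apply(curves, 1, quantile, probs = c(alpha, 1 - alpha), type = 6)
      out <- data.frame(fpr = fprGrid, low = qs[1, ], high = qs[2, ])
    }
    if (redraws > 0)
      message(redraws, " single-class bootstrap resample(s) redrawn")
    attr(out, "redraws") <- redraws
    out
  })
}

#' Metric sweep over a cutoff grid
#'
#' One confusion matrix + metric row per cutoff; the default grid is
#' 0.1 to 0.9 in steps of 0.1.
#'
#' @inheritParams confusionAtCutoff
#' @param cutoffs non-empty cutoff grid.
#' @return data.frame with cutoff, tp, fp, tn, fn and the point metrics.
#' @export
cutoffSweep <- function(probs, labels, cutoffs = seq(0.1, 0.9, by = 0.1)) {
  if (length(cutoffs) == 0) stop("cutoffs must be non-empty")
  do.call(rbind, lapply(cutoffs, function(ct) {
    cm <- confusionAtCutoff(probs, labels, ct)
    cbind(data.frame(cutoff = ct, tp = cm$tp, fp = cm$fp, tn = cm$tn,
                     fn = cm$fn),
          as.data.frame(t(classificationMetrics(cm))))
  }))
}

#' Full metric report for one prediction set
#'
#' @inheritParams confusionAtCutoff
#' @param nBoot bootstrap iterations for CIs (0 disables).
#' @param seed bootstrap seed.
#' @return data.frame(metric, value, ciLow, ciHigh).
#' @export
metricsReport <- function(probs, labels, cutoff = 0.5, nBoot = 0L,
                          seed = 1L) {
  cm <- confusionAtCutoff(probs, labels, cutoff)
  pts <- classificationMetrics(cm)
  both <- length(unique(labels)) > 1L
  vals <- c(roc_auc = if (both) rocAUC(probs, labels) else NA_real_,
            sensitivity = pts[["sensitivity"]],
            specificity = pts[["specificity"]],
            f1 = pts[["f1"]], ppv = pts[["ppv"]],
            aupr = if (both) prAUC(probs, labels) else NA_real_,
            accuracy = pts[["accuracy"]])
  out <- data.frame(metric = names(vals), value = unname(vals),
                    ciLow = NA_real_, ciHigh = NA_real_)
  if (nBoot > 0L && both) {
    fns <- list(
      roc_auc = rocAUC,
      sensitivity = function(p, l) classificationMetrics(
        confusionAtCutoff(p, l, cutoff))[["sensitivity"]],
      specificity = function(p, l) classificationMetrics(
        confusionAtCutoff(p, l, cutoff))[["specificity"]],
      f1 = function(p, l) classificationMetrics(
        confusionAtCutoff(p, l, cutoff))[["f1"]],
      ppv = function(p, l) classificationMetrics(
        confusionAtCutoff(p, l, cutoff))[["ppv"]],
      aupr = prAUC,
      accuracy = function(p, l) classificationMetrics(
        confusionAtCutoff(p, l, cutoff))[["accuracy"]])
    for (i in seq_len(nrow(out))) {
      ci <- suppressMessages(
        bootstrapInterval(fns[[out$metric[i]]], probs, labels, nBoot,
                          seed = .deriveSeed(seed, i)))
      out$ciLow[i] <- ci[1]; out$ciHigh[i] <- ci[2]
    }
  }
  out
}

#' Group-disaggregated metric reports
#'
#' Metrics computed independently for every group value plus the pooled
#' set. Groups with a single class get NA for AUC/AUPR (undefined, not 0).
#'
#' @inheritParams metricsReport
#' @param groups group value per case (e.g. sex).
#' @return named list of [metricsReport()] data.frames ("pooled" plus one
#'   per group level).
#' @export
groupedReport <- function(probs, labels, groups, cutoff = 0.5, nBoot = 0L,
                          seed = 1L) {
  if (length(groups) != length(probs)) stop("groups must align with probs")
  out <- list(pooled = metricsReport(probs, labels, cutoff, nBoot, seed))
  for (g in sort(unique(groups))) {
    sel <- groups == g
    out[[as.character(g)]] <-
      metricsReport(probs[sel], labels[sel], cutoff, nBoot, seed)
  }
  out
}
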