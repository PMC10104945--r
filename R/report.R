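# Territorial and global aggregation, ROC and group comparison.

.metricCols <- c("peakSystolicStrain", "peakSystolicSR", "psi")

#' Territory means of segment metrics
#'
#' Unweighted arithmetic means of each metric over the contributing
#' (non-missing) segments of each coronary territory. Missing segments are
#' skipped and the contributing count reported; an empty territory yields
#' `NA` means with `n = 0`.
#'
#' @param metrics per-segment metrics table from [computeSegmentMetrics()]
#'   (possibly with values set to `NA` for rejected segments).
#' @param map territory map from [territoryMap()].
#' @return data.frame with one row per territory: the mean of each metric
#'   column plus the contributing count `n`.
#' @export
territoryMeans <- function(metrics, map = territoryMap()) {
  rows <- lapply(names(map), function(tn) {
    sub <- metrics[metrics$segmentId %in% map[[tn]], , drop = FALSE]
    means <- vapply(.metricCols, function(cl) {
      v <- sub[[cl]]
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    }, 0)
    n <- sum(stats::complete.cases(sub[, .metricCols]))
    cbind(data.frame(territory = tn), as.data.frame(as.list(means)),
          data.frame(n = n))
  })
  do.call(rbind, rows)
}

#' Global means of segment metrics
#'
#' Unweighted mean over all contributing segments: GLS, global systolic
#' strain rate and global PSI.
#'
#' @param metrics per-segment metrics table.
#' @return one-row data.frame with the metric means and contributing
#'   count `n`.
#' @export
globalMeans <- function(metrics) {
  means <- vapply(.metricCols, function(cl) {
    v <- metrics[[cl]]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, 0)
  cbind(as.data.frame(as.list(means)),
        data.frame(n = sum(stats::complete.cases(metrics[, .metricCols]))))
}

#' Rank-based (Mann-Whitney) AUC with bootstrap confidence interval
#'
#' The AUC is the fraction of (positive, negative) pairs in which the
#' positive study's score is larger, ties counted 1/2. The orientation is
#' the caller's: scores should already be oriented so that larger = more
#' abnormal (for strain and strain rate the clinical direction,
#' less-negative = abnormal, is the numeric order already; for PSI larger
#' is abnormal). The AUC is deliberately not folded to be >= 0.5. The
#' confidence interval is a seeded percentile bootstrap over studies.
#'
#' @param scores numeric score per study.
#' @param labels logical (or 0/1): TRUE = positive class (e.g. occluded).
#' @param nBoot bootstrap resamples (default 2000).
#' @param seed seed for the bootstrap stream.
#' @param conf confidence level (default 0.95).
#' @return list with `auc`, `ciLo`, `ciHi`, `nPos`, `nNeg`.
#' @export
aucCI <- function(scores, labels, nBoot = 2000L, seed = 1L, conf = 0.95) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), all(is.finite(scores)))
  if (!any(labels) || all(labels))
    stop("both classes must be present")
  auc <- .rankAUC(scores, labels)
  set.seed(seed)
  boots <- numeric(nBoot)
  n <- length(scores)
  for (b in seq_len(nBoot)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (any(labels[idx]) && !all(labels[idx])) break
    }
    boots[b] <- .rankAUC(scores[idx], labels[idx])
  }
  a <- (1 - conf) / 2
  ci <- unname(stats::quantile(boots, c(a, 1 - a), type = 7))
  list(auc = auc, ciLo = ci[1], ciHi = ci[2],
       nPos = sum(labels), nNeg = sum(!labels))
}

# Mann-Whitney AUC via midranks (ties counted 1/2)
.rankAUC <- function(scores, labels) {
  r <- rank(scores)
  n1 <- sum(labels)
  n0 <- sum(!labels)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Welch two-sample t-test
#'
#' Two-sided unequal-variance t-test between two groups. When both groups
#' have zero variance and equal means the comparison is degenerate and
#' `t = 0, p = 1` is returned by convention.
#'
#' @param a,b numeric group values (each n >= 2).
#' @return list with `t`, `p`, `df`, `meanA`, `meanB`.
#' @export
twoSampleT <- function(a, b) {
  stopifnot(length(a) >= 2L, length(b) >= 2L,
            all(is.finite(a)), all(is.finite(b)))
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b))
      return(list(t = 0, p = 1, df = NA_real_,
                  meanA = mean(a), meanB = mean(b)))
    stop("zero variance in both groups with different means: t undefined")
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter), meanA = mean(a), meanB = mean(b))
}

#' Evaluate occlusion discrimination over a cohort
#'
#' Given one row of territorial/global metrics per study plus occlusion
#' labels, computes for each metric the rank AUC with bootstrap CI and the
#' Welch comparison of occluded vs non-occluded studies. Scores are
#' oriented so that larger = more abnormal: strain and strain-rate values
#' are used as-is (less negative is numerically larger), PSI as-is (higher
#' is abnormal).
#'
#' @param studyTable data.frame with one row per study; metric columns plus
#'   a logical `occluded` column.
#' @param metrics which columns to evaluate (default: all numeric columns
#'   except `occluded`/`studyId`).
#' @param nBoot,seed,conf bootstrap parameters passed to [aucCI()].
#' @return data.frame with one row per metric: `metric`, `auc`, `ciLo`,
#'   `ciHi`, `t`, `p`, `meanOccluded`, `meanOpen`.
#' @export
evaluateCohort <- function(studyTable, metrics = NULL, nBoot = 2000L,
                           seed = 1L, conf = 0.95) {
  stopifnot("occluded" %in% names(studyTable))
  occ <- as.logical(studyTable$occluded)
  if (is.null(metrics)) {
    metrics <- setdiff(names(studyTable)[vapply(studyTable, is.numeric, TRUE)],
                       c("occluded", "studyId"))
  }
  rows <- lapply(metrics, function(m) {
    sc <- studyTable[[m]]
    ok <- is.finite(sc)
    a <- aucCI(sc[ok], occ[ok], nBoot = nBoot, seed = seed, conf = conf)
    tt <- twoSampleT(sc[ok & occ], sc[ok & !occ])
    data.frame(metric = m, auc = a$auc, ciLo = a$ciLo, ciHi = a$ciHi,
               t = tt$t, p = tt$p,
               meanOccluded = tt$meanA, meanOpen = tt$meanB)
  })
  do.call(rbind, rows)
}
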