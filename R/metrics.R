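# Peak extraction, PSI, noise flags, noise area fraction, cycle selection.

#' Select the analysed cycle
#'
#' The analysis always uses the second of the available consecutive cycles;
#' with a single complete cycle it falls back to the first.
#'
#' @param rWaveTimes R-wave marker times, ms (n markers delimit n-1 complete
#'   cycles).
#' @return cycle index (1-based).
#' @export
selectCycle <- function(rWaveTimes) {
  n <- length(rWaveTimes) - 1L
  if (n < 1L)
    stop("no complete cardiac cycle in the recording")
  if (n >= 2L) 2L else 1L
}

#' Peak-search windows of the analysed cycle
#'
#' All windows are half-open `[lo, hi)`. Systole runs from cycle start to
#' AVC. The systolic strain-rate window is restricted to
#' `[lowerFrac, upperFrac)` of the systolic length (default 8% to 50%) to
#' avoid the pre-ejection spike. The post-systolic window runs from
#' `AVC + pssOffsetMs` (default 90 ms, avoiding the post-ejection spike)
#' until mid-diastole.
#'
#' @param timing a [CardiacTiming-class].
#' @param srWindowFrac fractions `c(lower, upper)` of the systolic length.
#' @param pssOffsetMs offset of the post-systolic window after AVC, ms.
#' @return list of `c(lo, hi)` pairs: `systole`, `sr`, `pss`.
#' @export
searchWindows <- function(timing, srWindowFrac = c(0.08, 0.50),
                          pssOffsetMs = 90) {
  Ts <- timing@systoleLength
  list(
    systole = c(timing@cycleStart, timing@avc),
    sr = timing@cycleStart + srWindowFrac * Ts,
    pss = c(timing@avc + pssOffsetMs, timing@midDiastole))
}

.inWindow <- function(times, win) times >= win[1] & times < win[2]

#' Peak systolic strain
#'
#' Minimum (most negative) strain over the entire systole,
#' `[cycleStart, avc)`.
#'
#' @param timesMs frame times, ms.
#' @param strainPct strain trace, %.
#' @param windows from [searchWindows()].
#' @return peak systolic strain, %, with the peak time as attribute
#'   `timeMs`.
#' @export
peakSystolicStrain <- function(timesMs, strainPct, windows) {
  sel <- which(.inWindow(timesMs, windows$systole))
  if (!length(sel)) stop("empty systole window")
  i <- sel[which.min(strainPct[sel])]
  structure(strainPct[i], timeMs = timesMs[i])
}

#' Peak systolic strain rate
#'
#' Minimum strain rate over the systolic strain-rate window; frames outside
#' the window are never considered, even if more negative.
#'
#' @param timesMs frame times, ms.
#' @param srPerS strain-rate trace, 1/s.
#' @param windows from [searchWindows()].
#' @return peak systolic strain rate, 1/s, with attribute `timeMs`.
#' @export
peakSystolicSR <- function(timesMs, srPerS, windows) {
  sel <- which(.inWindow(timesMs, windows$sr))
  if (!length(sel)) stop("empty strain-rate window")
  i <- sel[which.min(srPerS[sel])]
  structure(srPerS[i], timeMs = timesMs[i])
}

#' Post-systolic strain peak
#'
#' Minimum strain over `[avc + offset, mid-diastole)`. An empty window
#' (short diastole) is recorded as missing (`NA`), not an error.
#'
#' @param timesMs frame times, ms.
#' @param strainPct strain trace, %.
#' @param windows from [searchWindows()].
#' @return post-systolic strain, %, or `NA` when the window holds no frame.
#' @export
postSystolicPeak <- function(timesMs, strainPct, windows) {
  sel <- which(.inWindow(timesMs, windows$pss))
  if (!length(sel)) return(structure(NA_real_, timeMs = NA_real_))
  i <- sel[which.min(strainPct[sel])]
  structure(strainPct[i], timeMs = timesMs[i])
}

#' Post-systolic index
#'
#' `PSI = 100 * (peak cycle strain - end systolic strain) / peak cycle
#' strain`, where peak cycle strain is the whole-cycle extremum (most
#' negative) of the smoothed strain trace and end-systolic strain is the
#' strain at the AVC frame. A flat trace (`peakCycleStrain = 0`) gets
#' `PSI = 0` with attribute `flag = "flat"`; `PSI > 100` (end-systolic
#' strain of opposite sign) is flagged `"suspect"`.
#'
#' @param peakCycleStrain whole-cycle strain extremum, %.
#' @param endSystolicStrain strain at the AVC frame, %.
#' @return PSI in %.
#' @export
psi <- function(peakCycleStrain, endSystolicStrain) {
  if (peakCycleStrain == 0)
    return(structure(0, flag = "flat"))
  v <- 100 * (peakCycleStrain - endSystolicStrain) / peakCycleStrain
  if (v > 100) structure(v, flag = "suspect") else v
}

#' Noise flag for a strain value
#'
#' A strain value strictly below the lower cut-off (default -25%) or
#' strictly above the upper cut-off (default +5%) is most likely noise.
#' Boundary values pass.
#'
#' @param strainPct strain value(s), %.
#' @param cutoffs `c(lower, upper)` in %.
#' @return logical, TRUE = noise.
#' @export
noiseFlag <- function(strainPct, cutoffs = c(-25, 5)) {
  stopifnot(all(is.finite(strainPct)))
  strainPct < cutoffs[1] | strainPct > cutoffs[2]
}

#' Area fraction of noisy myocardium
#'
#' `100 * flagged area / total area` over the non-discarded subsegments;
#' discarded apical subsegments are excluded from both numerator and
#' denominator.
#'
#' @param flags logical noise flag per subsegment.
#' @param areasMm2 subsegment areas, mm^2.
#' @param discard optional logical discard mask.
#' @return noise area fraction, %.
#' @export
noiseAreaFraction <- function(flags, areasMm2, discard = NULL) {
  stopifnot(length(flags) == length(areasMm2))
  if (!is.null(discard)) {
    flags <- flags[!discard]
    areasMm2 <- areasMm2[!discard]
  }
  tot <- sum(areasMm2)
  if (!length(areasMm2) || tot <= 0)
    stop("no non-discarded area")
  100 * sum(areasMm2[flags]) / tot
}

#' Per-segment metrics from strain traces
#'
#' Extracts, for each of the 16 segments: peak systolic strain, peak
#' systolic strain rate, post-systolic strain, peak-cycle and end-systolic
#' strain, PSI and the noise flag, using the search windows derived from
#' the cycle timing.
#'
#' @param traces list of 16 per-segment trace data.frames from
#'   [computeStrainTraces()].
#' @param timing a [CardiacTiming-class].
#' @param config a [PipelineConfig-class].
#' @return data.frame with one row per segment: `segmentId`,
#'   `peakSystolicStrain`, `peakSystolicSR`, `postSystolicStrain`,
#'   `peakCycleStrain`, `endSystolicStrain`, `psi`, `noiseFlag`,
#'   `lowQualityFrames`.
#' @export
computeSegmentMetrics <- function(traces, timing,
                                  config = pipelineConfig()) {
  win <- searchWindows(timing, config@srWindowFrac, config@pssOffsetMs)
  res <- lapply(1:16, function(s) {
    tr <- traces[[s]]
    cyc <- tr$timeMs >= timing@cycleStart & tr$timeMs < timing@cycleEnd
    tt <- tr$timeMs[cyc]
    st <- tr$strainPct[cyc]
    sr <- tr$srPerS[cyc]
    pkSys <- peakSystolicStrain(tt, st, win)
    pkSR <- peakSystolicSR(tt, sr, win)
    pss <- postSystolicPeak(tt, st, win)
    peakCycle <- min(st)
    esIdx <- which(tt <= timing@avc + 1e-9)
    es <- st[esIdx[length(esIdx)]]  # nearest frame at or before AVC
    p <- psi(peakCycle, es)
    flagSrc <- if (config@noiseFlagSource == "peak") peakCycle else st
    data.frame(
      segmentId = s,
      peakSystolicStrain = as.numeric(pkSys),
      peakSystolicSR = as.numeric(pkSR),
      postSystolicStrain = as.numeric(pss),
      peakCycleStrain = peakCycle,
      endSystolicStrain = es,
      psi = as.numeric(p),
      psiFlag = if (is.null(attr(p, "flag"))) "" else attr(p, "flag"),
      noiseFlag = any(noiseFlag(flagSrc, config@noiseCutoffs)),
      lowQualityFrames = sum(tr$lowQuality[cyc]))
  })
  do.call(rbind, res)
}
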