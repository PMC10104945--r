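# End-to-end analysis: cycle selection, tracking, meshing, timing,
# segmentation, deformation, metrics, aggregation. Fully deterministic for
# a given study and configuration.

#' Run the full deformation analysis on one study
#'
#' Pipeline stages: (1) select the analysed cycle (second of the available
#' cycles); (2) track the three wall traces through the cycle with the TDI
#' velocity fields; (3) build the 3D mesh by periodic circumferential
#' interpolation; (4) detect AVC as the smallest reconstructed cavity
#' volume; (5) label mesh subsegments with the 16-segment model and the
#' apical discard mask; (6) compute per-segment strain-rate/strain traces;
#' (7) extract peaks, PSI and noise flags; (8) aggregate to territories and
#' globals, and compute the noise area fraction. No stage draws random
#' numbers: the same study and configuration give identical output.
#'
#' @param study an [LVStudy-class].
#' @param config a [PipelineConfig-class].
#' @param verbose log one line per stage with counts of clamped points,
#'   flagged frames and discarded subsegments.
#' @return a [StudyReport-class].
#' @export
runPipeline <- function(study, config = pipelineConfig(), verbose = FALSE) {
  stopifnot(is(study, "LVStudy"))
  validObject(study)
  validObject(config)
  log <- function(...) if (verbose) message(sprintf(...))

  rw <- rWaveTimes(study)
  ft <- frameTimes(study)
  cyc <- selectCycle(rw)
  frames <- which(ft >= rw[cyc] - 1e-9 & ft < rw[cyc + 1L] - 1e-9)
  if (length(frames) < 3L)
    stop("analysed cycle holds fewer than 3 frames")
  log("cycle %d of %d selected: frames %d..%d", cyc, length(rw) - 1L,
      frames[1], frames[length(frames)])

  tracked <- list()
  for (nm in c("a4c", "a2c", "aplax")) {
    tracked[[nm]] <- trackWall(study@views[[nm]], study@traces[[nm]], frames)
    log("tracked %s: %d points, %d clamped point-frames", nm,
        nrow(tracked[[nm]]@points), sum(tracked[[nm]]@clamped))
  }

  mesh <- buildMesh(tracked, levels = config@meshLevels,
                    angles = config@meshAngles, frameTimes = ft[frames])
  vols <- vapply(seq_along(frames), function(f) cavityVolume(mesh, f), 0)
  override <- NA_real_
  for (v in study@views) if (is.finite(v@avcOverride)) {
    override <- v@avcOverride
    break
  }
  timing <- detectAVC(vols, ft[frames], cycleStart = rw[cyc],
                      cycleEnd = rw[cyc + 1L], avcOverride = override)
  if (timing@edgeWarning)
    warning("volume minimum at a cycle edge: AVC timing implausible")
  log("AVC %.0f ms (systole %.0f ms), cavity volume %.0f..%.0f mm^3",
      timing@avc, timing@systoleLength, min(vols), max(vols))

  cells <- assignSegments(mesh, config@apicalDiscardFrac)
  log("mesh %dx%d: %d subsegments, %d discarded",
      config@meshLevels, config@meshAngles, nrow(cells), sum(cells$discard))

  traces <- computeStrainTraces(tracked, ft[frames], config)
  metrics <- computeSegmentMetrics(traces, timing, config)
  log("segments: %d noise-flagged, %d with low-quality frames",
      sum(metrics$noiseFlag), sum(metrics$lowQualityFrames > 0))

  # subsegments inherit their segment's noise flag for the area fraction
  segFlag <- metrics$noiseFlag[match(cells$segment, metrics$segmentId)]
  naf <- noiseAreaFraction(segFlag, cells$areaMm2, cells$discard)

  if (config@rejectNoisy) {
    bad <- metrics$noiseFlag
    metrics[bad, c("peakSystolicStrain", "peakSystolicSR",
                   "postSystolicStrain", "psi")] <- NA_real_
    log("rejected %d noisy segments from aggregation", sum(bad))
  }

  new("StudyReport",
      segments = metrics,
      territories = territoryMeans(metrics),
      global = globalMeans(metrics),
      noiseAreaFraction = naf,
      timing = timing,
      traces = traces)
}

#' One row of territorial and global metrics per study
#'
#' Flattens a [StudyReport-class] into the per-study row consumed by
#' [evaluateCohort()].
#'
#' @param report a [StudyReport-class].
#' @return one-row data.frame: `strain_<territory>`, `sr_<territory>`,
#'   `psi_<territory>` for LAD/CX/RCA, plus `gls`, `globalSr`, `globalPsi`
#'   and `noiseArea`.
#' @export
reportRow <- function(report) {
  terr <- report@territories
  out <- list()
  for (i in seq_len(nrow(terr))) {
    tn <- terr$territory[i]
    out[[paste0("strain_", tn)]] <- terr$peakSystolicStrain[i]
    out[[paste0("sr_", tn)]] <- terr$peakSystolicSR[i]
    out[[paste0("psi_", tn)]] <- terr$psi[i]
  }
  out$gls <- report@global$peakSystolicStrain
  out$globalSr <- report@global$peakSystolicSR
  out$globalPsi <- report@global$psi
  out$noiseArea <- report@noiseAreaFraction
  as.data.frame(out)
}

#' Generate and analyse a synthetic cohort
#'
#' Generates `nNormal` normal phantoms and `nOccluded` phantoms with one
#' ischemic coronary territory (attenuated systolic peak plus post-systolic
#' shortening), runs the full pipeline on each, and evaluates the
#' discrimination of the culprit territory's strain, strain rate and PSI
#' and the global metrics (rank AUC with bootstrap CI, Welch comparison).
#' Studies are generated one at a time and discarded after analysis, so
#' memory stays flat. Each study gets its own derived seed; the whole
#' cohort is reproducible from `seed`.
#'
#' @param nNormal,nOccluded cohort sizes.
#' @param culprit occluded territory (`"LAD"`, `"CX"` or `"RCA"`).
#' @param seed cohort seed.
#' @param phantom base [PhantomConfig-class] (cohort default: 2 cycles,
#'   40 beams x 100 samples at 100 Hz).
#' @param pipeline a [PipelineConfig-class].
#' @param normalPeak,occludedPeak,pssAmplitude kinematics of the two
#'   groups, %.
#' @param nBoot bootstrap resamples for the AUC CIs.
#' @return list with `studies` (per-study metric rows with `studyId` and
#'   `occluded`) and `evaluation` (from [evaluateCohort()], culprit
#'   territory and global metrics).
#' @export
runCohort <- function(nNormal = 30L, nOccluded = 10L, culprit = "LAD",
                      seed = 1L,
                      phantom = phantomConfig(nCycles = 2L,
                                              beamsPerView = 40L,
                                              samplesPerBeam = 100L),
                      pipeline = pipelineConfig(),
                      normalPeak = -18, occludedPeak = -8,
                      pssAmplitude = 8, nBoot = 2000L) {
  n <- nNormal + nOccluded
  stopifnot(n >= 2L, nNormal >= 1L, nOccluded >= 1L)
  occluded <- c(rep(FALSE, nNormal), rep(TRUE, nOccluded))
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    kin <- if (occluded[i]) {
      ischemicKinematics(culprit, occludedPeak = occludedPeak,
                         pssAmplitude = pssAmplitude,
                         normalPeak = normalPeak)
    } else {
      segmentKinematics(peakSystolicStrain = normalPeak)
    }
    cfg <- initialize(phantom, seed = as.integer(seed + i))
    study <- generatePhantom(cfg, kin)
    rep <- runPipeline(study, pipeline)
    rows[[i]] <- cbind(data.frame(studyId = i, occluded = occluded[i]),
                       reportRow(rep))
  }
  studies <- do.call(rbind, rows)
  cols <- c(paste0(c("strain_", "sr_", "psi_"), culprit),
            "gls", "globalSr", "globalPsi")
  eval <- evaluateCohort(studies, metrics = cols, nBoot = nBoot,
                         seed = pipeline@seed)
  list(studies = studies, evaluation = eval)
}
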