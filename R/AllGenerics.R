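# Constructors, accessors and show methods for the core classes.

#' Construct a ViewRecording
#'
#' @param viewId `"A4C"`, `"A2C"` or `"APLAX"`.
#' @param velocity array `[frame, beam, depth]` of along-beam velocities,
#'   cm/s, positive toward the probe.
#' @param beamAngles beam angles in degrees from the sector midline.
#' @param depths sample depths in mm from the probe.
#' @param frameTimes frame timestamps, ms.
#' @param rWaveTimes R-wave markers, ms.
#' @param avcOverride optional AVC time in ms overriding detection.
#' @return a [ViewRecording-class].
#' @export
viewRecording <- function(viewId, velocity, beamAngles, depths, frameTimes,
                          rWaveTimes, avcOverride = NA_real_) {
  new("ViewRecording", viewId = viewId, velocity = velocity,
      beamAngles = as.numeric(beamAngles), depths = as.numeric(depths),
      frameTimes = as.numeric(frameTimes), rWaveTimes = as.numeric(rWaveTimes),
      avcOverride = as.numeric(avcOverride))
}

#' Construct a WallTrace
#'
#' @param viewId `"A4C"`, `"A2C"` or `"APLAX"`.
#' @param points N x 2 matrix of (x, y) mm, base of wall 1 -> apex -> base of
#'   wall 2.
#' @param apexIndex row index of the apex point.
#' @param referenceFrame frame index at which the contour was traced.
#' @return a [WallTrace-class].
#' @export
wallTrace <- function(viewId, points, apexIndex, referenceFrame = 1L) {
  new("WallTrace", viewId = viewId, points = as.matrix(points),
      apexIndex = as.integer(apexIndex),
      referenceFrame = as.integer(referenceFrame))
}

#' Construct a Mesh3D directly from a node lattice
#'
#' Mostly useful for tests and synthetic geometry; [buildMesh()] is the
#' normal route.
#'
#' @param nodes array `[frame, level, angle, 3]`, mm.
#' @param apexFrac arc fraction from apex per level (0 = apex, 1 = base).
#' @param angles circumferential angles, degrees.
#' @param frameTimes frame timestamps, ms.
#' @param sourceAngles angles that are source planes (default: none).
#' @return a [Mesh3D-class].
#' @export
mesh3D <- function(nodes, apexFrac, angles, frameTimes,
                   sourceAngles = numeric(0)) {
  new("Mesh3D", nodes = nodes, apexFrac = as.numeric(apexFrac),
      angles = as.numeric(angles), sourceAngles = as.numeric(sourceAngles),
      frameTimes = as.numeric(frameTimes))
}

#' Construct a PhantomConfig
#'
#' Any slot of [PhantomConfig-class] can be set by name; the rest keep their
#' defaults.
#'
#' @param ... named slot values, e.g. `noiseSd = 0`, `seed = 7L`.
#' @return a [PhantomConfig-class].
#' @export
phantomConfig <- function(...) {
  args <- list(...)
  for (nm in c("nCycles", "beamsPerView", "samplesPerBeam",
               "tracePointsPerWall", "seed"))
    if (nm %in% names(args)) args[[nm]] <- as.integer(args[[nm]])
  do.call(new, c(list("PhantomConfig"), args))
}

#' Construct a PipelineConfig
#'
#' @param ... named slot values of [PipelineConfig-class], e.g.
#'   `rejectNoisy = TRUE`.
#' @return a [PipelineConfig-class].
#' @export
pipelineConfig <- function(...) {
  args <- list(...)
  for (nm in c("meshLevels", "meshAngles", "seed"))
    if (nm %in% names(args)) args[[nm]] <- as.integer(args[[nm]])
  do.call(new, c(list("PipelineConfig"), args))
}

#' Construct an LVStudy
#'
#' @param views named list (`a4c`, `a2c`, `aplax`) of [ViewRecording-class].
#' @param traces named list (same names) of [WallTrace-class].
#' @param truth optional [PhantomTruth-class].
#' @return an [LVStudy-class].
#' @export
lvStudy <- function(views, traces, truth = NULL) {
  new("LVStudy", views = views, traces = traces, truth = truth)
}

# ---- accessors --------------------------------------------------------------

#' @describeIn viewRecording the view identifier.
#' @param object a package object.
#' @export
setGeneric("viewId", function(object) standardGeneric("viewId"))
#' @export
setMethod("viewId", "ViewRecording", function(object) object@viewId)
#' @export
setMethod("viewId", "WallTrace", function(object) object@viewId)

#' Velocity field of a recording
#' @param object a [ViewRecording-class].
#' @return array `[frame, beam, depth]`, cm/s.
#' @export
setGeneric("velocityField", function(object) standardGeneric("velocityField"))
#' @export
setMethod("velocityField", "ViewRecording", function(object) object@velocity)

#' Beam angles (degrees) of a recording's sector
#' @param object a [ViewRecording-class].
#' @export
setGeneric("beamAngles", function(object) standardGeneric("beamAngles"))
#' @export
setMethod("beamAngles", "ViewRecording", function(object) object@beamAngles)

#' Sample depths (mm) of a recording
#' @param object a [ViewRecording-class].
#' @export
setGeneric("sampleDepths", function(object) standardGeneric("sampleDepths"))
#' @export
setMethod("sampleDepths", "ViewRecording", function(object) object@depths)

#' Frame timestamps (ms)
#' @param object a recording, mesh or study.
#' @export
setGeneric("frameTimes", function(object) standardGeneric("frameTimes"))
#' @export
setMethod("frameTimes", "ViewRecording", function(object) object@frameTimes)
#' @export
setMethod("frameTimes", "Mesh3D", function(object) object@frameTimes)
#' @export
setMethod("frameTimes", "LVStudy",
          function(object) object@views[[1L]]@frameTimes)

#' R-wave marker times (ms)
#' @param object a [ViewRecording-class] or [LVStudy-class].
#' @export
setGeneric("rWaveTimes", function(object) standardGeneric("rWaveTimes"))
#' @export
setMethod("rWaveTimes", "ViewRecording", function(object) object@rWaveTimes)
#' @export
setMethod("rWaveTimes", "LVStudy",
          function(object) object@views[[1L]]@rWaveTimes)

#' Trace points (mm) of a wall trace
#' @param object a [WallTrace-class].
#' @export
setGeneric("tracePoints", function(object) standardGeneric("tracePoints"))
#' @export
setMethod("tracePoints", "WallTrace", function(object) object@points)

#' Tracked per-frame positions of a wall trace
#' @param object a [WallTrace-class] after [trackWall()].
#' @return array `[frame, point, 2]`, mm.
#' @export
setGeneric("trackedPositions",
           function(object) standardGeneric("trackedPositions"))
#' @export
setMethod("trackedPositions", "WallTrace", function(object) object@tracked)

#' Mesh node lattice
#' @param object a [Mesh3D-class].
#' @return array `[frame, level, angle, 3]`, mm.
#' @export
setGeneric("meshNodes", function(object) standardGeneric("meshNodes"))
#' @export
setMethod("meshNodes", "Mesh3D", function(object) object@nodes)

#' Ground truth attached to a phantom study
#' @param object an [LVStudy-class].
#' @export
setGeneric("studyTruth", function(object) standardGeneric("studyTruth"))
#' @export
setMethod("studyTruth", "LVStudy", function(object) object@truth)

#' Per-segment metrics table of a report
#' @param object a [StudyReport-class].
#' @export
setGeneric("segmentTable", function(object) standardGeneric("segmentTable"))
#' @export
setMethod("segmentTable", "StudyReport", function(object) object@segments)

#' Territory means table of a report
#' @param object a [StudyReport-class].
#' @export
setGeneric("territoryTable",
           function(object) standardGeneric("territoryTable"))
#' @export
setMethod("territoryTable", "StudyReport", function(object) object@territories)

#' Global means table of a report
#' @param object a [StudyReport-class].
#' @export
setGeneric("globalTable", function(object) standardGeneric("globalTable"))
#' @export
setMethod("globalTable", "StudyReport", function(object) object@global)

#' Noise area fraction (%) of a report
#' @param object a [StudyReport-class].
#' @export
setGeneric("noiseArea", function(object) standardGeneric("noiseArea"))
#' @export
setMethod("noiseArea", "StudyReport", function(object) object@noiseAreaFraction)

#' Cardiac timing of a report
#' @param object a [StudyReport-class].
#' @export
setGeneric("studyTiming", function(object) standardGeneric("studyTiming"))
#' @export
setMethod("studyTiming", "StudyReport", function(object) object@timing)

# ---- show methods -----------------------------------------------------------

setMethod("show", "ViewRecording", function(object) {
  d <- dim(object@velocity)
  cat(sprintf("ViewRecording '%s': %d frames x %d beams x %d depths\n",
              object@viewId, d[1], d[2], d[3]))
  cat(sprintf("  sector %.1f..%.1f deg, depth %.1f..%.1f mm, %d R-waves\n",
              min(object@beamAngles), max(object@beamAngles),
              min(object@depths), max(object@depths),
              length(object@rWaveTimes)))
})

setMethod("show", "WallTrace", function(object) {
  cat(sprintf("WallTrace '%s': %d points (apex at %d), reference frame %d%s\n",
              object@viewId, nrow(object@points), object@apexIndex,
              object@referenceFrame,
              if (length(object@trackedFrames))
                sprintf(", tracked over %d frames",
                        length(object@trackedFrames)) else ""))
})

setMethod("show", "Mesh3D", function(object) {
  d <- dim(object@nodes)
  cat(sprintf("Mesh3D: %d frames, %d levels x %d angles (%d source planes)\n",
              d[1], d[2], d[3], length(object@sourceAngles)))
})

setMethod("show", "CardiacTiming", function(object) {
  cat(sprintf(
    "CardiacTiming: cycle [%.0f, %.0f) ms, AVC %.0f ms (systole %.0f ms), mid-diastole %.0f ms%s\n",
    object@cycleStart, object@cycleEnd, object@avc, object@systoleLength,
    object@midDiastole,
    if (object@edgeWarning) " [volume minimum at cycle edge]" else ""))
})

setMethod("show", "PhantomConfig", function(object) {
  cat(sprintf(
    "PhantomConfig: LV %0.f x %.0f mm, cycle %.0f ms (systole %.0f), %d cycles @ %.0f Hz\n",
    object@longAxisMm, object@baseRadiusMm, object@cycleMs, object@systoleMs,
    object@nCycles, object@frameRateHz))
  cat(sprintf(
    "  %d beams x %d samples, +-%.0f deg, noise %.2f cm/s, %d reverberation band(s), seed %d\n",
    object@beamsPerView, object@samplesPerBeam, object@sectorHalfAngleDeg,
    object@noiseSd, length(object@reverberationBands), object@seed))
})

setMethod("show", "PhantomTruth", function(object) {
  cat(sprintf(
    "PhantomTruth: 16 segments, true AVC %.0f ms (cycle start %.0f ms), %d frames\n",
    object@trueAvcMs, object@referenceCycleStartMs, length(object@frameTimes)))
})

setMethod("show", "LVStudy", function(object) {
  cat(sprintf("LVStudy: %d views, %d frames, %d R-waves%s\n",
              length(object@views), length(frameTimes(object)),
              length(rWaveTimes(object)),
              if (!is.null(object@truth)) ", with phantom truth" else ""))
})

setMethod("show", "PipelineConfig", function(object) {
  cat(sprintf(
    "PipelineConfig: mesh %dx%d, SR window [%.0f%%, %.0f%%) of systole, PSS from AVC+%.0f ms\n",
    object@meshLevels, object@meshAngles, 100 * object@srWindowFrac[1],
    100 * object@srWindowFrac[2], object@pssOffsetMs))
  cat(sprintf(
    "  noise cut-offs (%.0f, %.0f) %%, apical discard %.0f%%, rejectNoisy=%s\n",
    object@noiseCutoffs[1], object@noiseCutoffs[2],
    100 * object@apicalDiscardFrac, object@rejectNoisy))
})

setMethod("show", "StudyReport", function(object) {
  cat("StudyReport\n")
  g <- object@global
  cat(sprintf("  GLS %.1f %%  global SR %.2f 1/s  global PSI %.1f %%  noise area %.1f %%\n",
              g$peakSystolicStrain, g$peakSystolicSR, g$psi,
              object@noiseAreaFraction))
  show(object@timing)
})
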