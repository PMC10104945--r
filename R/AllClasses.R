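#' @import methods
NULL

#' One apical view's tissue-velocity recording
#'
#' Holds along-beam tissue velocities on a beam-angle x depth polar grid over
#' frames, together with the sector geometry and cardiac cycle (R-wave)
#' markers. Velocities are in cm/s, positive toward the probe; beam angles in
#' degrees from the sector midline; depths in mm from the probe; times in ms.
#'
#' @slot viewId one of `"A4C"`, `"A2C"`, `"APLAX"`.
#' @slot velocity numeric array `[frame, beam, depth]`, cm/s.
#' @slot beamAngles strictly increasing beam angles, degrees.
#' @slot depths strictly increasing sample depths, mm.
#' @slot frameTimes strictly increasing frame timestamps, ms.
#' @slot rWaveTimes R-wave markers, ms (at least 2, so at least one complete
#'   cycle is delimited).
#' @slot avcOverride optional aortic-valve-closure time in ms; when finite it
#'   supersedes volume-based AVC detection.
#' @exportClass ViewRecording
setClass("ViewRecording",
  slots = c(
    viewId      = "character",
    velocity    = "array",
    beamAngles  = "numeric",
    depths      = "numeric",
    frameTimes  = "numeric",
    rWaveTimes  = "numeric",
    avcOverride = "numeric"
  ),
  prototype = prototype(avcOverride = NA_real_)
)

setValidity("ViewRecording", function(object) {
  msg <- character()
  if (!object@viewId %in% c("A4C", "A2C", "APLAX"))
    msg <- c(msg, "viewId must be one of 'A4C', 'A2C', 'APLAX'")
  d <- dim(object@velocity)
  if (length(d) != 3L)
    msg <- c(msg, "velocity must be a 3D array [frame, beam, depth]")
  else {
    if (d[1] != length(object@frameTimes))
      msg <- c(msg, "dim(velocity)[1] must equal length(frameTimes)")
    if (d[2] != length(object@beamAngles))
      msg <- c(msg, "dim(velocity)[2] must equal length(beamAngles)")
    if (d[3] != length(object@depths))
      msg <- c(msg, "dim(velocity)[3] must equal length(depths)")
  }
  if (is.unsorted(object@frameTimes, strictly = TRUE))
    msg <- c(msg, "frameTimes must be strictly increasing")
  if (is.unsorted(object@beamAngles, strictly = TRUE))
    msg <- c(msg, "beamAngles must be strictly increasing")
  if (is.unsorted(object@depths, strictly = TRUE))
    msg <- c(msg, "depths must be strictly increasing")
  if (length(object@rWaveTimes) < 2L)
    msg <- c(msg, "at least 2 R-wave markers are required")
  if (length(msg)) msg else TRUE
})

#' Traced mid-wall contour for one apical view
#'
#' Ordered mid-wall points in the view plane, running from the base of wall 1
#' through the apex to the base of wall 2, traced at a single reference frame.
#' After tracking, per-frame positions are stored in `tracked`.
#'
#' @slot viewId one of `"A4C"`, `"A2C"`, `"APLAX"`.
#' @slot points N x 2 matrix of (x, y) positions in mm; x across the sector,
#'   y along the sector midline (depth), probe at the origin.
#' @slot apexIndex row index of the apex point; rows `1:apexIndex` are wall 1,
#'   rows `apexIndex:N` are wall 2 (the apex belongs to both walls).
#' @slot referenceFrame frame index at which the trace was drawn.
#' @slot tracked numeric array `[frame, point, 2]` of tracked positions for
#'   the analysed cycle (empty before tracking).
#' @slot trackedFrames frame indices corresponding to rows of `tracked`.
#' @slot clamped logical matrix `[frame, point]`: point hit the edge of the
#'   sampled sector and was clamped during tracking.
#' @exportClass WallTrace
setClass("WallTrace",
  slots = c(
    viewId         = "character",
    points         = "matrix",
    apexIndex      = "integer",
    referenceFrame = "integer",
    tracked        = "array",
    trackedFrames  = "integer",
    clamped        = "matrix"
  ),
  prototype = prototype(
    tracked       = array(numeric(0), dim = c(0L, 0L, 2L)),
    trackedFrames = integer(0),
    clamped       = matrix(logical(0), 0L, 0L)
  )
)

setValidity("WallTrace", function(object) {
  msg <- character()
  n <- nrow(object@points)
  if (ncol(object@points) != 2L)
    msg <- c(msg, "points must be an N x 2 matrix")
  a <- object@apexIndex
  if (a < 7L || (n - a + 1L) < 7L)
    msg <- c(msg, "each wall needs at least 7 points (including the apex)")
  if (n >= 2L) {
    step <- sqrt(rowSums((object@points[-1L, , drop = FALSE] -
                          object@points[-n, , drop = FALSE])^2))
    if (any(step == 0))
      msg <- c(msg, "consecutive trace points must be distinct")
  }
  if (length(msg)) msg else TRUE
})

#' Circumferentially interpolated 3D wall mesh
#'
#' Lattice of wall nodes on (longitudinal level x circumferential angle),
#' per frame, in 3D mm coordinates with the z axis along the probe midline
#' (z = depth from the probe). Six of the circumferential angles are source
#' planes (tracked 2D points embedded in 3D); the rest are interpolated by a
#' periodic cubic spline.
#'
#' @slot nodes numeric array `[frame, level, angle, 3]` (x, y, z in mm).
#' @slot apexFrac arc-length fraction from the apex for each level row
#'   (0 = apex, 1 = base).
#' @slot angles circumferential node angles, degrees in `[0, 360)`.
#' @slot sourceAngles the six angles that coincide with tracked wall planes.
#' @slot frameTimes timestamps of the mesh frames, ms.
#' @exportClass Mesh3D
setClass("Mesh3D",
  slots = c(
    nodes        = "array",
    apexFrac     = "numeric",
    angles       = "numeric",
    sourceAngles = "numeric",
    frameTimes   = "numeric"
  )
)

setValidity("Mesh3D", function(object) {
  msg <- character()
  d <- dim(object@nodes)
  if (length(d) != 4L || d[4] != 3L)
    msg <- c(msg, "nodes must be a [frame, level, angle, 3] array")
  else {
    if (d[1] != length(object@frameTimes))
      msg <- c(msg, "dim(nodes)[1] must equal length(frameTimes)")
    if (d[2] != length(object@apexFrac))
      msg <- c(msg, "dim(nodes)[2] must equal length(apexFrac)")
    if (d[3] != length(object@angles))
      msg <- c(msg, "dim(nodes)[3] must equal length(angles)")
  }
  if (length(msg)) msg else TRUE
})

#' Cardiac timing landmarks for one analysed cycle
#'
#' @slot cycleStart,cycleEnd cycle boundaries (R-wave to R-wave), ms.
#' @slot avc aortic valve closure, ms (detected as the minimum reconstructed
#'   cavity volume, or taken from an override).
#' @slot systoleLength `avc - cycleStart`, ms.
#' @slot midDiastole midpoint of diastole, `avc + (cycleEnd - avc)/2`, ms.
#' @slot edgeWarning TRUE when the volume minimum fell on the first or last
#'   frame of the cycle (physiologically implausible).
#' @exportClass CardiacTiming
setClass("CardiacTiming",
  slots = c(
    cycleStart    = "numeric",
    cycleEnd      = "numeric",
    avc           = "numeric",
    systoleLength = "numeric",
    midDiastole   = "numeric",
    edgeWarning   = "logical"
  ),
  prototype = prototype(edgeWarning = FALSE)
)

setValidity("CardiacTiming", function(object) {
  # cycleStart == avc is tolerated (degenerate edge minimum, flagged by
  # edgeWarning) so implausible inputs are reported rather than rejected
  ok <- object@cycleStart <= object@avc &&
    object@avc < object@midDiastole &&
    object@midDiastole < object@cycleEnd
  if (!ok)
    return("timing must satisfy cycleStart <= avc < midDiastole < cycleEnd")
  if (abs(object@systoleLength - (object@avc - object@cycleStart)) > 1e-9)
    return("systoleLength must equal avc - cycleStart")
  TRUE
})

#' Synthetic left-ventricle phantom configuration
#'
#' Geometry, timing, acquisition and artifact parameters of the half-ellipsoid
#' LV phantom. Defaults are a normal adult-sized ventricle imaged at a
#' TDI-like frame rate. See [generatePhantom()].
#'
#' @slot longAxisMm apex-to-base long axis of the half-ellipsoid, mm.
#' @slot baseRadiusMm cavity radius at the base, mm.
#' @slot cycleMs cardiac cycle length, ms.
#' @slot systoleMs time from cycle start to true aortic valve closure, ms.
#' @slot nCycles number of simulated cycles.
#' @slot frameRateHz acquisition frame rate (>= 50 for TDI-like sampling).
#' @slot beamsPerView,samplesPerBeam polar grid size.
#' @slot sectorHalfAngleDeg half opening angle of the imaging sector, degrees.
#' @slot probeStandoffMm distance from the probe to the LV apex, mm.
#' @slot depthRangeMm sampled depth range, mm.
#' @slot wallHalfwidthMm half thickness of the band around the wall within
#'   which tissue velocity is painted onto the grid, mm.
#' @slot noiseSd additive white Gaussian velocity noise SD, cm/s.
#' @slot reverberationBands list of bands, each
#'   `list(view=, beams=c(lo,hi), depthsMm=c(lo,hi), attenuation=)`.
#' @slot tracePointsPerWall number of traced contour points per wall.
#' @slot seed integer seed for the phantom's single pseudorandom stream.
#' @exportClass PhantomConfig
setClass("PhantomConfig",
  slots = c(
    longAxisMm         = "numeric",
    baseRadiusMm       = "numeric",
    cycleMs            = "numeric",
    systoleMs          = "numeric",
    nCycles            = "integer",
    frameRateHz        = "numeric",
    beamsPerView       = "integer",
    samplesPerBeam     = "integer",
    sectorHalfAngleDeg = "numeric",
    probeStandoffMm    = "numeric",
    depthRangeMm       = "numeric",
    wallHalfwidthMm    = "numeric",
    noiseSd            = "numeric",
    reverberationBands = "list",
    tracePointsPerWall = "integer",
    seed               = "integer"
  ),
  prototype = prototype(
    longAxisMm         = 90,
    baseRadiusMm       = 25,
    cycleMs            = 1000,
    systoleMs          = 350,
    nCycles            = 3L,
    frameRateHz        = 100,
    beamsPerView       = 48L,
    samplesPerBeam     = 120L,
    sectorHalfAngleDeg = 30,
    probeStandoffMm    = 10,
    depthRangeMm       = c(5, 115),
    wallHalfwidthMm    = 8,
    noiseSd            = 0.5,
    reverberationBands = list(),
    tracePointsPerWall = 26L,
    seed               = 1L
  )
)

setValidity("PhantomConfig", function(object) {
  msg <- character()
  if (object@systoleMs >= object@cycleMs)
    msg <- c(msg, "systoleMs must be < cycleMs")
  if (object@frameRateHz < 50)
    msg <- c(msg, "frameRateHz must be >= 50 (TDI-like)")
  if (object@nCycles < 2L || object@beamsPerView < 2L ||
      object@samplesPerBeam < 2L || object@tracePointsPerWall < 7L)
    msg <- c(msg, "counts (nCycles, beams, samples) must be >= 2; trace points >= 7/wall")
  if (length(object@depthRangeMm) != 2L ||
      diff(object@depthRangeMm) <= 0)
    msg <- c(msg, "depthRangeMm must be an increasing pair")
  if (object@noiseSd < 0)
    msg <- c(msg, "noiseSd must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Ground truth of a generated phantom study
#'
#' @slot kinematics data.frame of per-segment prescribed kinematics
#'   (see [segmentKinematics()]).
#' @slot trueAvcMs absolute time of true aortic valve closure in the
#'   reference (analysed) cycle, ms.
#' @slot referenceCycleStartMs absolute start time of the reference cycle, ms.
#' @slot strain matrix `[frame, 16]` of ground-truth Lagrangian strain (%).
#' @slot volume analytic ground-truth cavity volume per frame, mm^3.
#' @slot frameTimes frame timestamps, ms.
#' @slot config the [PhantomConfig-class] that produced the study.
#' @exportClass PhantomTruth
setClass("PhantomTruth",
  slots = c(
    kinematics            = "data.frame",
    trueAvcMs             = "numeric",
    referenceCycleStartMs = "numeric",
    strain                = "matrix",
    volume                = "numeric",
    frameTimes            = "numeric",
    config                = "PhantomConfig"
  )
)

#' A complete per-patient study: three views, three traces, optional truth
#'
#' @slot views named list of three [ViewRecording-class]s (`a4c`, `a2c`,
#'   `aplax`), sharing frame times and R-wave markers.
#' @slot traces named list of three [WallTrace-class]s, same names.
#' @slot truth a [PhantomTruth-class] for phantom studies, else `NULL`.
#' @exportClass LVStudy
setClass("LVStudy",
  slots = c(views = "list", traces = "list", truth = "ANY"),
  prototype = prototype(truth = NULL)
)

setValidity("LVStudy", function(object) {
  msg <- character()
  nm <- c("a4c", "a2c", "aplax")
  if (!identical(sort(names(object@views)), sort(nm)))
    msg <- c(msg, "views must be named a4c, a2c, aplax")
  if (!identical(sort(names(object@traces)), sort(nm)))
    msg <- c(msg, "traces must be named a4c, a2c, aplax")
  if (!length(msg)) {
    if (!all(vapply(object@views, is, TRUE, "ViewRecording")))
      msg <- c(msg, "all views must be ViewRecording objects")
    if (!all(vapply(object@traces, is, TRUE, "WallTrace")))
      msg <- c(msg, "all traces must be WallTrace objects")
  }
  if (!length(msg)) {
    t0 <- object@views[[1L]]@frameTimes
    r0 <- object@views[[1L]]@rWaveTimes
    for (v in object@views) {
      if (!isTRUE(all.equal(v@frameTimes, t0)))
        msg <- c(msg, "all views must share frame times")
      if (!isTRUE(all.equal(v@rWaveTimes, r0)))
        msg <- c(msg, "all views must share R-wave markers")
    }
  }
  if (length(msg)) unique(msg) else TRUE
})

#' Analysis pipeline configuration
#'
#' All constants of the deformation analysis are configuration, never
#' hard-coded, so sensitivity analyses (e.g. of the 90 ms post-systolic
#' window offset) are scriptable.
#'
#' @slot meshLevels,meshAngles mesh lattice resolution (longitudinal levels,
#'   circumferential angles; angles should be a multiple of 6 so the source
#'   planes fall on lattice nodes).
#' @slot smoothStrain,smoothSR apply the 5-frame centered moving average to
#'   strain / strain-rate traces.
#' @slot noiseCutoffs strain noise cut-offs `c(lower, upper)` in %; a value
#'   strictly below the lower or strictly above the upper is flagged.
#' @slot pssOffsetMs start of the post-systolic search window, ms after AVC.
#' @slot srWindowFrac systolic strain-rate search window as fractions of the
#'   systolic length, `c(lower, upper)`.
#' @slot apicalDiscardFrac fraction of the apical third's longitudinal extent
#'   (apex-most) discarded from all segment statistics.
#' @slot rejectNoisy drop noise-flagged segments from territorial/global
#'   means (off by default: all segments are accepted regardless of quality).
#' @slot noiseFlagSource `"any"` (default) flags a segment when any frame of
#'   its smoothed strain trace crosses a cut-off (equivalently: cycle minimum
#'   below the lower, or cycle maximum above the upper cut-off, so
#'   reverberation-inverted, stretch-only traces are caught); `"peak"`
#'   restricts the check to the most negative (peak-cycle) value.
#' @slot beamWallMaxAngleDeg frames where the beam-wall angle at a segment
#'   end point exceeds this are flagged low quality.
#' @slot seed seed for the report layer's bootstrap resampling.
#' @exportClass PipelineConfig
setClass("PipelineConfig",
  slots = c(
    meshLevels          = "integer",
    meshAngles          = "integer",
    smoothStrain        = "logical",
    smoothSR            = "logical",
    noiseCutoffs        = "numeric",
    pssOffsetMs         = "numeric",
    srWindowFrac        = "numeric",
    apicalDiscardFrac   = "numeric",
    rejectNoisy         = "logical",
    noiseFlagSource     = "character",
    beamWallMaxAngleDeg = "numeric",
    seed                = "integer"
  ),
  prototype = prototype(
    meshLevels          = 30L,
    meshAngles          = 36L,
    smoothStrain        = TRUE,
    smoothSR            = TRUE,
    noiseCutoffs        = c(-25, 5),
    pssOffsetMs         = 90,
    srWindowFrac        = c(0.08, 0.50),
    apicalDiscardFrac   = 0.25,
    rejectNoisy         = FALSE,
    noiseFlagSource     = "any",
    beamWallMaxAngleDeg = 75,
    seed                = 1L
  )
)

setValidity("PipelineConfig", function(object) {
  msg <- character()
  f <- object@srWindowFrac
  if (length(f) != 2L || f[1] < 0 || f[2] >= 1 || f[1] >= f[2])
    msg <- c(msg, "srWindowFrac must satisfy 0 <= lower < upper < 1")
  ct <- object@noiseCutoffs
  if (length(ct) != 2L || ct[1] >= ct[2])
    msg <- c(msg, "noiseCutoffs must be c(lower, upper) with lower < upper")
  if (object@apicalDiscardFrac < 0 || object@apicalDiscardFrac >= 1)
    msg <- c(msg, "apicalDiscardFrac must be in [0, 1)")
  if (!object@noiseFlagSource %in% c("peak", "any"))
    msg <- c(msg, "noiseFlagSource must be 'peak' or 'any'")
  if (object@meshLevels < 4L || object@meshAngles < 12L)
    msg <- c(msg, "mesh resolution too coarse (need >= 4 levels, >= 12 angles)")
  if (length(msg)) msg else TRUE
})

#' Per-study analysis report
#'
#' @slot segments per-segment metrics table (see [computeSegmentMetrics()]).
#' @slot territories per-territory means with contributing counts.
#' @slot global global means (GLS, global SR, global PSI) with counts.
#' @slot noiseAreaFraction area fraction (%) of non-discarded myocardium
#'   whose strain crossed a noise cut-off.
#' @slot timing the [CardiacTiming-class] used for all search windows.
#' @slot traces list of 16 per-segment strain/strain-rate trace data.frames.
#' @exportClass StudyReport
setClass("StudyReport",
  slots = c(
    segments          = "data.frame",
    territories       = "data.frame",
    global            = "data.frame",
    noiseAreaFraction = "numeric",
    timing            = "CardiacTiming",
    traces            = "list"
  )
)
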