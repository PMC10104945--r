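# Shared fixtures, generated once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

.cached <- function(key, expr) {
  if (is.null(.fixtures[[key]]))
    assign(key, expr, envir = .fixtures)
  .fixtures[[key]]
}

# noiseless phantom at the generator defaults (3 cycles, 100 Hz) and its
# pipeline report: the reference end-to-end recovery condition
fixNormalStudy <- function() {
  .cached("normalStudy", generatePhantom(phantomConfig(noiseSd = 0)))
}

fixNormalReport <- function() {
  .cached("normalReport", runPipeline(fixNormalStudy(), pipelineConfig()))
}

# a small, fast phantom for container/determinism tests
fixSmallConfig <- function() {
  phantomConfig(noiseSd = 0, nCycles = 2L, frameRateHz = 50,
                beamsPerView = 16L, samplesPerBeam = 40L,
                tracePointsPerWall = 10L, seed = 42L)
}

fixSmallStudy <- function() {
  .cached("smallStudy", generatePhantom(fixSmallConfig()))
}

# straight-walled synthetic tracked traces: each wall is one straight line
# from its base position down to a shared apex at (0, apexY), so a point at
# arc fraction u from the apex sits at radius u * wallRadius exactly, and
# the wall tangent is constant along the wall. Optionally translated
# rigidly per frame. Returns a named list of tracked WallTrace objects.
makeStraightTraces <- function(radii = rep(20, 6), apexY = 30, baseY = 100,
                               nPoints = 9, nFrames = 4,
                               shiftPerFrame = c(0, 0)) {
  stopifnot(length(radii) == 6L)
  views <- c("a4c", "aplax", "a2c")
  ids <- c(a4c = "A4C", aplax = "APLAX", a2c = "A2C")
  out <- list()
  for (k in seq_along(views)) {
    r1 <- radii[k]          # wall 1 of this view (angles 0/60/120)
    r2 <- radii[k + 3L]     # wall 2 (angles 180/240/300)
    u <- seq(1, 0, length.out = nPoints)       # base -> apex
    w1 <- cbind(u * r1, apexY + u * (baseY - apexY))
    u2 <- seq(0, 1, length.out = nPoints)[-1L] # apex -> base
    w2 <- cbind(-u2 * r2, apexY + u2 * (baseY - apexY))
    pts <- rbind(w1, w2)
    tr <- wallTrace(ids[[views[k]]], pts, apexIndex = nPoints,
                    referenceFrame = 1L)
    tracked <- array(NA_real_, dim = c(nFrames, nrow(pts), 2L))
    for (f in seq_len(nFrames)) {
      tracked[f, , 1] <- pts[, 1] + (f - 1L) * shiftPerFrame[1]
      tracked[f, , 2] <- pts[, 2] + (f - 1L) * shiftPerFrame[2]
    }
    out[[views[k]]] <- methods::initialize(
      tr, tracked = tracked, trackedFrames = seq_len(nFrames),
      clamped = matrix(FALSE, nFrames, nrow(pts)))
  }
  out
}

# analytic node lattices for volume tests
cylinderMesh <- function(r = 10, h = 50, L = 50L, C = 64L) {
  ang <- seq(0, 360, length.out = C + 1L)[-(C + 1L)] * pi / 180
  z <- seq(0, h, length.out = L)
  nodes <- array(NA_real_, dim = c(1, L, C, 3))
  for (l in seq_len(L)) {
    nodes[1, l, , 1] <- r * cos(ang)
    nodes[1, l, , 2] <- r * sin(ang)
    nodes[1, l, , 3] <- z[l]
  }
  mesh3D(nodes, apexFrac = seq(0, 1, length.out = L),
         angles = ang * 180 / pi, frameTimes = 0)
}

halfEllipsoidMesh <- function(a = 20, h = 60, L = 120L, C = 64L) {
  ang <- seq(0, 360, length.out = C + 1L)[-(C + 1L)] * pi / 180
  z <- seq(h / 400, h, length.out = L)  # skip the degenerate apex point
  nodes <- array(NA_real_, dim = c(1, L, C, 3))
  for (l in seq_len(L)) {
    r <- a * sqrt(1 - ((h - z[l]) / h)^2)
    nodes[1, l, , 1] <- r * cos(ang)
    nodes[1, l, , 2] <- r * sin(ang)
    nodes[1, l, , 3] <- z[l]
  }
  mesh3D(nodes, apexFrac = seq(0, 1, length.out = L),
         angles = ang * 180 / pi, frameTimes = 0)
}

# ground-truth PSI of one segment from the prescribed curve, using the same
# landmark definitions (peak-cycle = most negative, end-systolic at AVC)
truthPSI <- function(kinRow, cycleMs, systoleMs, frameTimesRel) {
  s <- prescribedStrainCurve(kinRow, frameTimesRel, cycleMs, systoleMs)
  peakCyc <- min(s)
  es <- s[max(which(frameTimesRel <= systoleMs))]
  if (peakCyc == 0) 0 else 100 * (peakCyc - es) / peakCyc
}
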