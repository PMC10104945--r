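# Per-segment strain-rate and strain traces from tracked wall positions.

#' Strain rate from segment end points
#'
#' The natural (logarithmic) strain rate of a wall segment is estimated from
#' its end points as `(vFar - vNear) / L`: the difference of the along-wall
#' velocity components of the basal-most and apical-most material points,
#' over the current inter-point arc distance. Negative values mean
#' shortening.
#'
#' @param vNear along-wall velocity of the apical end point, mm/s (positive
#'   toward the base).
#' @param vFar along-wall velocity of the basal end point, mm/s.
#' @param lengthMm current arc distance between the end points, mm (>= 1).
#' @return strain rate in 1/s (vectorised).
#' @export
segmentStrainRate <- function(vNear, vFar, lengthMm) {
  if (any(lengthMm < 1))
    stop("degenerate segment: inter-point distance below 1 mm")
  (vFar - vNear) / lengthMm
}

#' Integrate a strain-rate trace into Lagrangian strain
#'
#' The natural strain integral is accumulated by trapezoidal quadrature and
#' converted to Lagrangian strain:
#' `strain(t) = exp( integral_0^t SR dtau ) - 1`, reported in %. Strain is
#' zero at the first frame by construction.
#'
#' @param sr strain-rate trace, 1/s, one value per frame.
#' @param timesMs frame times, ms.
#' @return Lagrangian strain trace in %.
#' @export
integrateStrain <- function(sr, timesMs) {
  stopifnot(length(sr) == length(timesMs))
  if (any(!is.finite(sr)))
    stop("non-finite strain rate")
  n <- length(sr)
  dt <- diff(timesMs) / 1000
  I <- c(0, cumsum((sr[-1] + sr[-n]) / 2 * dt))
  (exp(I) - 1) * 100
}

#' Five-frame centered moving average
#'
#' The smoothing used on strain traces: the current frame averaged with the
#' two frames back and two frames forward. At the trace boundaries the
#' window is clipped to the available frames and the mean taken over what
#' remains.
#'
#' @param x numeric trace.
#' @param width odd window width (default 5).
#' @return smoothed trace, same length.
#' @export
smooth5 <- function(x, width = 5L) {
  stopifnot(length(x) >= 1L, width %% 2L == 1L)
  n <- length(x)
  h <- (width - 1L) %/% 2L
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  cs <- c(0, cumsum(x))
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# positions / arc positions / tangents of an arbitrary material point
# (reference arc fraction u from the apex) interpolated between tracked
# trace points, per frame.
#
# Returns, for each frame and each requested u:
#   pos   [frame, u, 2]   position (mm)
#   arc   [frame, u]      arc position along the tracked polyline (mm)
#   tang  [frame, u, 2]   unit wall tangent, oriented apex -> base
.materialTrack <- function(trace, wall, us) {
  rows <- .wallRows(trace, wall)
  trk <- trace@tracked[, rows, , drop = FALSE]
  nf <- dim(trk)[1]
  npt <- dim(trk)[2]
  # reference arc fractions of the trace points (apex -> base at reference)
  iRef <- match(trace@referenceFrame, trace@trackedFrames)
  pRef <- trk[iRef, , ]
  dim(pRef) <- c(npt, 2L)
  arcRef <- c(0, cumsum(sqrt(rowSums(diff(pRef)^2))))
  uRef <- arcRef / arcRef[npt]
  pos <- array(NA_real_, dim = c(nf, length(us), 2L))
  arc <- matrix(NA_real_, nf, length(us))
  tang <- array(NA_real_, dim = c(nf, length(us), 2L))
  for (f in seq_len(nf)) {
    p <- trk[f, , ]
    dim(p) <- c(npt, 2L)
    a <- c(0, cumsum(sqrt(rowSums(diff(p)^2))))
    pos[f, , 1] <- approx(uRef, p[, 1], xout = us)$y
    pos[f, , 2] <- approx(uRef, p[, 2], xout = us)$y
    arc[f, ] <- approx(uRef, a, xout = us)$y
    h <- 0.02
    txa <- approx(uRef, p[, 1], xout = pmin(us + h, 1))$y -
      approx(uRef, p[, 1], xout = pmax(us - h, 0))$y
    tya <- approx(uRef, p[, 2], xout = pmin(us + h, 1))$y -
      approx(uRef, p[, 2], xout = pmax(us - h, 0))$y
    nrm <- sqrt(txa^2 + tya^2)
    tang[f, , 1] <- txa / nrm
    tang[f, , 2] <- tya / nrm
  }
  list(pos = pos, arc = arc, tang = tang)
}

#' Per-segment strain-rate and strain traces
#'
#' For every AHA segment, the tracked wall(s) imaging it are evaluated at
#' the segment's longitudinal end points (fixed material points on the
#' reference trace). The along-wall velocity of each end point is the
#' tracked (along-beam) frame-to-frame displacement projected onto the
#' local wall tangent; the strain rate is their difference over the current
#' inter-point arc distance ([segmentStrainRate()]); strain is its
#' integral ([integrateStrain()]). Where a 90-degree apical sector contains
#' two imaged walls the strain-rate traces are averaged. Five-frame
#' smoothing ([smooth5()]) is applied to strain, and (by default) to strain
#' rate, per the configuration. Frames where the beam is near-orthogonal to
#' the wall at an end point (angle above `beamWallMaxAngleDeg`) are flagged
#' low-quality rather than angle-corrected.
#'
#' @param traces named list of tracked [WallTrace-class]es (`a4c`, `a2c`,
#'   `aplax`).
#' @param frameTimesMs timestamps (ms) of the tracked frames.
#' @param config a [PipelineConfig-class].
#' @return list of 16 data.frames (one per segment id), each with columns
#'   `timeMs`, `srPerS`, `strainPct`, `lowQuality`.
#' @export
computeStrainTraces <- function(traces, frameTimesMs,
                                config = pipelineConfig()) {
  segMer <- .segmentMeridians()
  nf <- length(frameTimesMs)
  dtMs <- diff(frameTimesMs)
  # cache per-(view, wall) material tracks at the union of span boundaries
  spans <- lapply(1:16, .segmentSpanU,
                  apicalDiscardFrac = config@apicalDiscardFrac)
  usAll <- sort(unique(round(unlist(spans), 10)))
  viewKey <- c(A4C = "a4c", A2C = "a2c", APLAX = "aplax")
  cache <- list()
  getTrack <- function(view, wall) {
    key <- paste0(view, wall)
    if (is.null(cache[[key]]))
      cache[[key]] <<- .materialTrack(traces[[viewKey[[view]]]], wall, usAll)
    cache[[key]]
  }
  out <- vector("list", 16L)
  for (s in 1:16) {
    span <- spans[[s]]
    iLo <- match(round(span[1], 10), usAll)
    iHi <- match(round(span[2], 10), usAll)
    mer <- segMer[[as.character(s)]]
    srM <- matrix(NA_real_, nf, nrow(mer))
    lowQ <- rep(FALSE, nf)
    for (m in seq_len(nrow(mer))) {
      tk <- getTrack(mer$view[m], mer$wall[m])
      L <- tk$arc[, iHi] - tk$arc[, iLo]
      vAl <- function(i) {
        dp <- tk$pos[-1, i, , drop = FALSE] - tk$pos[-nf, i, , drop = FALSE]
        dim(dp) <- c(nf - 1L, 2L)
        (dp[, 1] * tk$tang[-nf, i, 1] + dp[, 2] * tk$tang[-nf, i, 2]) /
          dtMs * 1000  # mm/s
      }
      sr <- segmentStrainRate(vAl(iLo), vAl(iHi), L[-nf])
      srM[, m] <- c(sr, sr[nf - 1L])
      # beam-wall angle at the end points
      for (i in c(iLo, iHi)) {
        bdir <- tk$pos[, i, ] / sqrt(rowSums(tk$pos[, i, ]^2))
        cosang <- abs(rowSums(bdir * tk$tang[, i, ]))
        lowQ <- lowQ | cosang < cos(config@beamWallMaxAngleDeg * pi / 180)
      }
    }
    sr <- rowMeans(srM)
    strain <- integrateStrain(sr, frameTimesMs)
    if (config@smoothStrain) strain <- smooth5(strain)
    if (config@smoothSR) sr <- smooth5(sr)
    out[[s]] <- data.frame(timeMs = frameTimesMs, srPerS = sr,
                           strainPct = strain, lowQuality = lowQ)
  }
  out
}
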