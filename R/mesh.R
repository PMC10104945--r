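# Wall tracking, 3D mesh interpolation, cavity volume and AVC detection.

#' Snap a view-plane point to the TDI sector grid
#'
#' When a traced point lies inside the sector, the enclosing/nearest beam and
#' the point's polar depth are returned. When the myocardium was traced
#' outside the TDI sector, the sector-edge beam minimising angular distance
#' is used and the depth is clamped to the sampled range -- the traced point
#' is still analysed, on the closest available beam. Ties between two equally
#' near beams break toward the lower beam index.
#'
#' @param point length-2 `(x, y)` position in mm, probe at the origin, y along
#'   the sector midline.
#' @param beamAngles beam angles in degrees (strictly increasing).
#' @param depths sampled depths in mm (strictly increasing).
#' @return list with `beam` (index), `depthMm` (polar depth, clamped into the
#'   sampled range), and `clamped` (TRUE when the point lay outside the
#'   sector in angle or depth).
#' @export
snapToSector <- function(point, beamAngles, depths) {
  stopifnot(length(point) == 2L, all(is.finite(point)))
  th <- atan2(point[1], point[2]) * 180 / pi
  d <- sqrt(sum(point^2))
  clamped <- FALSE
  if (th < beamAngles[1] || th > beamAngles[length(beamAngles)]) {
    beam <- if (th < beamAngles[1]) 1L else length(beamAngles)
    clamped <- TRUE
  } else {
    dAng <- abs(beamAngles - th)
    # ties (within numerical precision) break toward the lower beam index
    beam <- which(dAng <= min(dAng) + 1e-9)[1L]
  }
  dC <- min(max(d, depths[1]), depths[length(depths)])
  if (dC != d) clamped <- TRUE
  list(beam = as.integer(beam), depthMm = dC, clamped = clamped)
}

#' Sample the velocity field at beam-space coordinates
#'
#' Bilinear interpolation in (beam angle, depth) at one frame. Coordinates
#' are clamped to the grid edges (consistent with the nearest-beam fallback
#' of [snapToSector()]).
#'
#' @param rec a [ViewRecording-class].
#' @param angleDeg beam-space angle(s), degrees (vectorised).
#' @param depthMm depth(s), mm (vectorised, recycled against `angleDeg`).
#' @param frame frame index.
#' @return velocity value(s), cm/s, positive toward the probe.
#' @export
sampleVelocity <- function(rec, angleDeg, depthMm, frame) {
  nf <- length(rec@frameTimes)
  if (frame < 1L || frame > nf)
    stop(sprintf("frame %d out of range 1..%d", frame, nf))
  n <- max(length(angleDeg), length(depthMm))
  a <- rep_len(angleDeg, n)
  d <- rep_len(depthMm, n)
  ba <- rec@beamAngles
  dp <- rec@depths
  a <- pmin(pmax(a, ba[1]), ba[length(ba)])
  d <- pmin(pmax(d, dp[1]), dp[length(dp)])
  ia <- findInterval(a, ba, rightmost.closed = TRUE)
  ia <- pmin(pmax(ia, 1L), length(ba) - 1L)
  id <- findInterval(d, dp, rightmost.closed = TRUE)
  id <- pmin(pmax(id, 1L), length(dp) - 1L)
  wa <- (a - ba[ia]) / (ba[ia + 1L] - ba[ia])
  wd <- (d - dp[id]) / (dp[id + 1L] - dp[id])
  v <- rec@velocity
  v00 <- v[cbind(frame, ia, id)]
  v10 <- v[cbind(frame, ia + 1L, id)]
  v01 <- v[cbind(frame, ia, id + 1L)]
  v11 <- v[cbind(frame, ia + 1L, id + 1L)]
  (1 - wa) * (1 - wd) * v00 + wa * (1 - wd) * v10 +
    (1 - wa) * wd * v01 + wa * wd * v11
}

#' Track a traced wall through the cycle using the TDI velocity field
#'
#' Each trace point is advanced frame to frame along its local beam
#' direction by `v * dt` (explicit Euler), with the velocity re-sampled at
#' the updated position each frame. Frames of the cycle before the reference
#' frame are filled by stepping backward with the same scheme. Points that
#' leave the sampled depth range are clamped to the edge and flagged.
#'
#' @param rec a [ViewRecording-class].
#' @param trace a [WallTrace-class] whose `referenceFrame` lies inside
#'   `frames`.
#' @param frames integer frame indices of the analysed cycle (increasing).
#' @return the trace with `tracked` (`[frame, point, 2]` mm),
#'   `trackedFrames` and `clamped` filled in.
#' @export
trackWall <- function(rec, trace, frames) {
  stopifnot(is(rec, "ViewRecording"), is(trace, "WallTrace"))
  frames <- as.integer(frames)
  ref <- trace@referenceFrame
  if (!ref %in% frames)
    stop("trace referenceFrame must lie inside the analysed cycle")
  npts <- nrow(trace@points)
  nf <- length(frames)
  tt <- rec@frameTimes[frames]
  pos <- array(NA_real_, dim = c(nf, npts, 2L))
  clamped <- matrix(FALSE, nf, npts)
  iRef <- match(ref, frames)
  pos[iRef, , ] <- trace@points

  step <- function(p, fromFrame, dtMs) {
    th <- atan2(p[, 1], p[, 2])
    d <- sqrt(rowSums(p^2))
    out <- d > max(rec@depths) | d < min(rec@depths)
    v <- sampleVelocity(rec, th * 180 / pi, d, fromFrame)  # cm/s toward probe
    disp <- -v * 0.01 * dtMs                               # mm, away-positive
    list(p = p + cbind(sin(th), cos(th)) * disp, clamped = out)
  }

  if (iRef < nf) {
    for (i in iRef:(nf - 1L)) {
      st <- step(pos[i, , ], frames[i], tt[i + 1L] - tt[i])
      pos[i + 1L, , ] <- st$p
      clamped[i + 1L, ] <- st$clamped
    }
  }
  if (iRef > 1L) {
    for (i in iRef:2L) {
      st <- step(pos[i, , ], frames[i], tt[i - 1L] - tt[i])
      pos[i - 1L, , ] <- st$p
      clamped[i - 1L, ] <- st$clamped
    }
  }
  initialize(trace, tracked = pos, trackedFrames = frames, clamped = clamped)
}

#' Periodic cubic spline interpolation on a circle
#'
#' Interpolates values given at knot angles by the (unique) C2 periodic
#' cubic spline with the stated period. The interpolant reproduces its
#' knots exactly. This is the circumferential interpolation used by
#' [buildMesh()] between the six imaged wall planes.
#'
#' @param knotAngles knot positions, degrees, strictly increasing within one
#'   period.
#' @param values knot values.
#' @param outAngles evaluation angles, degrees (any real; evaluation is
#'   periodic).
#' @param period period in degrees (default 360).
#' @return interpolated values at `outAngles`.
#' @export
periodicInterp <- function(knotAngles, values, outAngles, period = 360) {
  stopifnot(length(knotAngles) == length(values),
            is.unsorted(knotAngles, strictly = TRUE) == FALSE,
            diff(range(knotAngles)) < period)
  f <- splinefun(c(knotAngles, knotAngles[1] + period),
                 c(values, values[1]), method = "periodic")
  f(knotAngles[1] + (outAngles - knotAngles[1]) %% period)
}

# per-wall polylines of a tracked trace, apex first:
# wall 1 = rows apexIndex..1, wall 2 = rows apexIndex..N
.wallRows <- function(trace, wall) {
  a <- trace@apexIndex
  if (wall == 1L) seq(a, 1L) else seq(a, nrow(trace@points))
}

#' Build the 3D mesh from three tracked views
#'
#' The six tracked walls (two per view, at circumferential angles
#' 0/60/120/180/240/300 degrees under the 60-degree inter-view assumption)
#' are resampled to a common longitudinal parameter -- arc-length fraction
#' from the apex -- at `levels` positions. At each level the six wall points
#' are interpolated across the circumference by a periodic cubic spline
#' (radius and depth as functions of circumferential angle), evaluated at
#' `angles` uniform angles. The spline reproduces its six knots exactly, so
#' source-plane nodes coincide with the tracked 2D points embedded in 3D.
#'
#' @param traces named list (`a4c`, `a2c`, `aplax`) of tracked
#'   [WallTrace-class]es covering the same frames.
#' @param levels number of longitudinal levels (default 30).
#' @param angles number of circumferential nodes (default 36; use a multiple
#'   of 6 so source planes fall on lattice nodes).
#' @param frameTimes timestamps (ms) of the tracked frames.
#' @return a [Mesh3D-class].
#' @export
buildMesh <- function(traces, levels = 30L, angles = 36L,
                      frameTimes = NULL) {
  stopifnot(all(c("a4c", "a2c", "aplax") %in% names(traces)))
  nf <- unique(vapply(traces, function(tr) dim(tr@tracked)[1], 0))
  if (length(nf) != 1L)
    stop("views tracked over unequal frame counts")
  if (is.null(frameTimes)) frameTimes <- seq_len(nf) - 1
  u <- (seq_len(levels) - 0.5) / levels          # arc fraction from apex
  phiKnots <- c(0, 60, 120, 180, 240, 300)
  # wall order matching phiKnots: (view, wall)
  wallsOf <- list(c("a4c", 1L), c("aplax", 1L), c("a2c", 1L),
                  c("a4c", 2L), c("aplax", 2L), c("a2c", 2L))
  angOut <- seq(0, 360, length.out = angles + 1L)[-(angles + 1L)]
  nodes <- array(NA_real_, dim = c(nf, levels, angles, 3L))
  for (f in seq_len(nf)) {
    rad <- matrix(NA_real_, levels, 6L)  # signed radius from long axis
    dep <- matrix(NA_real_, levels, 6L)  # depth (z) coordinate
    for (w in seq_along(wallsOf)) {
      tr <- traces[[wallsOf[[w]][[1]]]]
      rows <- .wallRows(tr, as.integer(wallsOf[[w]][[2]]))
      p <- tr@tracked[f, rows, , drop = TRUE]
      dim(p) <- c(length(rows), 2L)
      arc <- c(0, cumsum(sqrt(rowSums(diff(p)^2))))
      S <- arc[length(arc)]
      rad[, w] <- abs(approx(arc, p[, 1], xout = u * S)$y)
      dep[, w] <- approx(arc, p[, 2], xout = u * S)$y
    }
    for (l in seq_len(levels)) {
      rho <- periodicInterp(phiKnots, rad[l, ], angOut)
      zz <- periodicInterp(phiKnots, dep[l, ], angOut)
      nodes[f, l, , 1] <- rho * cos(angOut * pi / 180)
      nodes[f, l, , 2] <- rho * sin(angOut * pi / 180)
      nodes[f, l, , 3] <- zz
    }
  }
  mesh3D(nodes, apexFrac = u, angles = angOut, frameTimes = frameTimes,
         sourceAngles = phiKnots)
}

#' Cavity volume of the mesh at one frame
#'
#' Disk summation along the long axis: each longitudinal level's
#' cross-section area is computed with the shoelace formula over its
#' circumferential nodes (projected onto the plane normal to the long axis),
#' and areas are integrated over the levels' mean depths by the trapezoidal
#' rule.
#'
#' @param mesh a [Mesh3D-class].
#' @param frame frame index.
#' @return cavity volume in mm^3.
#' @export
cavityVolume <- function(mesh, frame) {
  stopifnot(is(mesh, "Mesh3D"))
  nodes <- mesh@nodes[frame, , , , drop = TRUE]
  L <- dim(mesh@nodes)[2]; C <- dim(mesh@nodes)[3]
  dim(nodes) <- c(L, C, 3L)
  areas <- numeric(L)
  for (l in seq_len(L)) {
    x <- nodes[l, , 1]; y <- nodes[l, , 2]
    j <- c(2:C, 1L)
    a <- sum(x * y[j] - x[j] * y) / 2
    if (!is.finite(a) || a <= 0)
      stop(sprintf("degenerate cross-section at level %d", l))
    areas[l] <- a
  }
  z <- rowMeans(nodes[, , 3, drop = TRUE])
  o <- order(z)
  z <- z[o]; areas <- areas[o]
  sum((areas[-1] + areas[-L]) / 2 * diff(z))
}

#' Detect aortic valve closure from the reconstructed volume trace
#'
#' AVC is the time of the smallest reconstructed cavity volume within the
#' cycle; ties break to the earliest frame. When the minimum falls on the
#' first or last frame the timing is flagged as physiologically implausible.
#' Mid-diastole is defined as the midpoint of diastole,
#' `avc + (cycleEnd - avc) / 2`. A finite `avcOverride` wins over detection.
#'
#' @param volumes per-frame cavity volumes, mm^3 (>= 3 frames).
#' @param frameTimes timestamps of those frames, ms.
#' @param cycleStart,cycleEnd cycle boundaries, ms.
#' @param avcOverride optional AVC time in ms; when finite, detection is
#'   skipped.
#' @return a [CardiacTiming-class].
#' @export
detectAVC <- function(volumes, frameTimes, cycleStart, cycleEnd,
                      avcOverride = NA_real_) {
  stopifnot(length(volumes) == length(frameTimes), length(volumes) >= 3L)
  edge <- FALSE
  if (is.finite(avcOverride)) {
    avc <- avcOverride
  } else {
    idx <- which.min(volumes)  # ties -> earliest
    avc <- frameTimes[idx]
    edge <- idx == 1L || idx == length(volumes)
  }
  new("CardiacTiming",
      cycleStart = cycleStart, cycleEnd = cycleEnd, avc = avc,
      systoleLength = avc - cycleStart,
      midDiastole = avc + (cycleEnd - avc) / 2,
      edgeWarning = edge)
}
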