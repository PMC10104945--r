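# Synthetic left-ventricle phantom: half-ellipsoid geometry, prescribed
# segmental kinematics, Doppler along-beam projection, noise and
# reverberation artifacts.

#' Per-segment prescribed kinematics
#'
#' Builds the kinematics table driving the phantom: for each AHA segment a
#' peak systolic strain, the timing of that peak, and an optional
#' post-systolic shortening (PSS) component appearing after aortic valve
#' closure -- the ischemia marker the analysis pipeline is meant to recover.
#' Arguments are recycled across the 16 segments.
#'
#' @param peakSystolicStrain peak systolic strain in % (negative =
#'   shortening), in `[-30, 5]`.
#' @param timeToPeak time of the systolic peak as a fraction of systole,
#'   in `(0, 1]`.
#' @param pssAmplitude additional shortening (%) after AVC; 0 = normal
#'   segment.
#' @param pssTimeMs time of the post-systolic peak, ms after AVC (>= 90 so
#'   injected PSS falls inside the post-systolic search window).
#' @return data.frame with columns `segmentId`, `peakSystolicStrain`,
#'   `timeToPeak`, `pssAmplitude`, `pssTimeMs`.
#' @export
segmentKinematics <- function(peakSystolicStrain = -18, timeToPeak = 1,
                              pssAmplitude = 0, pssTimeMs = 150) {
  kin <- data.frame(
    segmentId = 1:16,
    peakSystolicStrain = rep_len(peakSystolicStrain, 16L),
    timeToPeak = rep_len(timeToPeak, 16L),
    pssAmplitude = rep_len(pssAmplitude, 16L),
    pssTimeMs = rep_len(pssTimeMs, 16L))
  .validateKinematics(kin)
  kin
}

.validateKinematics <- function(kin) {
  stopifnot(is.data.frame(kin), nrow(kin) == 16L,
            all(c("segmentId", "peakSystolicStrain", "timeToPeak",
                  "pssAmplitude", "pssTimeMs") %in% names(kin)))
  if (any(kin$peakSystolicStrain < -30 | kin$peakSystolicStrain > 5))
    stop("peakSystolicStrain must lie in [-30, 5] %")
  if (any(kin$pssAmplitude < 0))
    stop("pssAmplitude must be >= 0")
  if (any(kin$pssAmplitude > 0 & kin$pssTimeMs < 90))
    stop("pssTimeMs must be >= 90 ms when pssAmplitude > 0")
  if (any(kin$timeToPeak <= 0 | kin$timeToPeak > 1))
    stop("timeToPeak must lie in (0, 1]")
  invisible(kin)
}

#' Kinematics with one ischemic coronary territory
#'
#' Convenience wrapper over [segmentKinematics()]: all segments normal except
#' those of `territory`, which get an attenuated systolic peak and a
#' post-systolic shortening component.
#'
#' @param territory `"LAD"`, `"CX"` or `"RCA"`.
#' @param occludedPeak peak systolic strain (%) of the ischemic segments.
#' @param pssAmplitude post-systolic shortening amplitude (%) of the
#'   ischemic segments.
#' @param normalPeak peak systolic strain (%) of the remaining segments.
#' @param pssTimeMs post-systolic peak time, ms after AVC.
#' @return kinematics data.frame as from [segmentKinematics()].
#' @export
ischemicKinematics <- function(territory = "LAD", occludedPeak = -8,
                               pssAmplitude = 8, normalPeak = -18,
                               pssTimeMs = 150) {
  map <- territoryMap()
  stopifnot(territory %in% names(map))
  kin <- segmentKinematics(peakSystolicStrain = normalPeak)
  idx <- map[[territory]]
  kin$peakSystolicStrain[idx] <- occludedPeak
  kin$pssAmplitude[idx] <- pssAmplitude
  kin$pssTimeMs[idx] <- pssTimeMs
  .validateKinematics(kin)
  kin
}

# raised-cosine landmark knots of one segment's strain curve
.strainKnots <- function(kin, cycleMs, systoleMs) {
  tp <- kin$timeToPeak * systoleMs
  peak <- kin$peakSystolicStrain
  if (kin$pssAmplitude > 0) {
    tRec <- systoleMs + 0.4 * kin$pssTimeMs
    tPss <- systoleMs + kin$pssTimeMs
    relaxEnd <- tPss + 0.6 * (cycleMs - tPss)
    t <- c(0, tp, tRec, tPss, relaxEnd, cycleMs)
    y <- c(0, peak, peak / 2, peak - kin$pssAmplitude, 0, 0)
  } else {
    relaxEnd <- systoleMs + 0.5 * (cycleMs - systoleMs)
    t <- c(0, tp, relaxEnd, cycleMs)
    y <- c(0, peak, 0, 0)
  }
  if (is.unsorted(t, strictly = TRUE))
    stop("degenerate strain-curve landmarks: check timeToPeak/pssTimeMs vs cycle timing")
  list(t = t, y = y)
}

#' Prescribed segmental strain curve
#'
#' Smooth strain trace anchored at landmark extrema: zero at cycle start and
#' end, the systolic extremum `peakSystolicStrain` at
#' `timeToPeak * systole`, and -- when `pssAmplitude > 0` -- a post-systolic
#' extremum of `peakSystolicStrain - pssAmplitude` at `AVC + pssTimeMs`.
#' Between landmarks the curve is a raised cosine, so every landmark is a
#' true local extremum and the curve is continuously differentiable.
#'
#' @param kin one row of a [segmentKinematics()] table (or an equivalent
#'   list).
#' @param tMs times since cycle start, ms (vectorised); must satisfy
#'   `0 <= t < cycleMs`.
#' @param cycleMs cycle length, ms.
#' @param systoleMs systole length (cycle start to AVC), ms.
#' @param deriv if TRUE return the time derivative in %/ms instead.
#' @return strain in % (or %/ms).
#' @export
prescribedStrainCurve <- function(kin, tMs, cycleMs, systoleMs,
                                  deriv = FALSE) {
  if (any(tMs < 0 | tMs >= cycleMs))
    stop("t outside [0, cycle): caller bug")
  k <- .strainKnots(kin, cycleMs, systoleMs)
  i <- findInterval(tMs, k$t, rightmost.closed = FALSE)
  i[i >= length(k$t)] <- length(k$t) - 1L
  ta <- k$t[i]; tb <- k$t[i + 1L]
  ya <- k$y[i]; yb <- k$y[i + 1L]
  ph <- pi * (tMs - ta) / (tb - ta)
  if (deriv) {
    (yb - ya) * pi / (2 * (tb - ta)) * sin(ph)
  } else {
    ya + (yb - ya) * (1 - cos(ph)) / 2
  }
}

#' Project a velocity vector onto a beam direction
#'
#' Doppler only measures the along-beam velocity component; this is the
#' inner product of the in-plane velocity with the unit beam direction.
#' With the beam direction pointing toward the probe, motion toward the
#' probe is positive.
#'
#' @param velocity length-2 velocity vector in the view plane, cm/s.
#' @param beamDirection length-2 unit vector (norm within 1e-9 of 1).
#' @return along-beam velocity, cm/s.
#' @export
projectOntoBeam <- function(velocity, beamDirection) {
  stopifnot(length(velocity) == 2L, length(beamDirection) == 2L)
  if (abs(sqrt(sum(beamDirection^2)) - 1) > 1e-9)
    stop("beamDirection must have unit norm")
  sum(velocity * beamDirection)
}

#' Inject a reverberation band into a recording
#'
#' Reverberations are stationary multipath clutter; inside the band the
#' Doppler signal is pulled toward zero velocity. Samples inside the band
#' are replaced by `(1 - attenuation) * original`; `attenuation = 1` models
#' full stationary clutter, `attenuation = 0` leaves the recording
#' unchanged.
#'
#' @param rec a [ViewRecording-class].
#' @param beams beam index range `c(lo, hi)`.
#' @param depthsMm depth range `c(lo, hi)` in mm.
#' @param attenuation fraction in `[0, 1]`.
#' @return a new [ViewRecording-class].
#' @export
injectReverberation <- function(rec, beams, depthsMm, attenuation) {
  stopifnot(is(rec, "ViewRecording"), length(beams) == 2L,
            length(depthsMm) == 2L)
  if (attenuation < 0 || attenuation > 1)
    stop("attenuation must lie in [0, 1]")
  nb <- length(rec@beamAngles)
  if (beams[1] < 1 || beams[2] > nb || beams[1] > beams[2])
    stop("beam range outside the sector grid")
  if (depthsMm[1] < min(rec@depths) - 1e-9 ||
      depthsMm[2] > max(rec@depths) + 1e-9 || depthsMm[1] > depthsMm[2])
    stop("depth range outside the sector grid")
  dMask <- rec@depths >= depthsMm[1] & rec@depths <= depthsMm[2]
  vel <- rec@velocity
  vel[, beams[1]:beams[2], dMask] <-
    vel[, beams[1]:beams[2], dMask] * (1 - attenuation)
  initialize(rec, velocity = vel)
}

# dense arc-length parameterisation of the half-ellipsoid meridian
# (z from apex along the long axis, r = cavity radius at z), continued
# straight past the base (annulus continuation, r constant) so that basal
# material and the velocity field remain defined slightly beyond the wall
.meridianGeom <- function(cfg, n = 4001L, extendMm = 80) {
  L <- cfg@longAxisMm; R <- cfg@baseRadiusMm
  z <- seq(0, L, length.out = n)
  r <- R * sqrt(pmax(0, 1 - ((L - z) / L)^2))
  nx <- ceiling(extendMm / (L / n))
  z <- c(z, L + seq_len(nx) * extendMm / nx)
  r <- c(r, rep(R, nx))
  s <- c(0, cumsum(sqrt(diff(z)^2 + diff(r)^2)))
  drds <- .centralDiff(r, s)
  dzds <- .centralDiff(z, s)
  nrm <- sqrt(drds^2 + dzds^2)
  list(z = z, r = r, s = s, S = s[n],
       drds = drds / nrm, dzds = dzds / nrm)
}

.centralDiff <- function(y, x) {
  n <- length(y)
  d <- numeric(n)
  d[1] <- (y[2] - y[1]) / (x[2] - x[1])
  d[n] <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
  d[2:(n - 1)] <- (y[3:n] - y[1:(n - 2)]) / (x[3:n] - x[1:(n - 2)])
  d
}

# analytic cavity volume of the ellipsoid dome from apex (z = 0) to z = zb;
# beyond the base the cavity continues as a cylinder of radius R
.domeVolume <- function(zb, L, R) {
  zc <- pmin(zb, L)
  pi * R^2 * (2 * L / 3 - (L - zc) + (L - zc)^3 / (3 * L^2)) +
    pi * R^2 * pmax(zb - L, 0)
}

# current arc-from-apex position (and its time derivative) of material
# points at reference arc m, for third strains eps = c(apical, mid, basal)
# as fractions; apex is fixed, points slide along the meridian.
.advect <- function(m, S, eps) {
  S3 <- S / 3
  (1 + eps[1]) * pmin(m, S3) +
    (1 + eps[2]) * pmin(pmax(m - S3, 0), S3) +
    (1 + eps[3]) * pmax(m - 2 * S3, 0)
}

.advectRate <- function(m, S, deps) {
  S3 <- S / 3
  deps[1] * pmin(m, S3) +
    deps[2] * pmin(pmax(m - S3, 0), S3) +
    deps[3] * pmax(m - 2 * S3, 0)
}

#' Generate a synthetic three-view phantom study
#'
#' Material wall points slide along the meridians of a static half-ellipsoid
#' so that each AHA segment's longitudinal Lagrangian strain follows its
#' [prescribedStrainCurve()] (the apex is fixed; the base descends toward it
#' in systole). Instantaneous wall velocities are projected onto the beam
#' directions of three apical sectors rotated 0/60/120 degrees about the
#' long axis and painted onto the beam x depth grid in a band of
#' `wallHalfwidthMm` around the wall. White Gaussian velocity noise and the
#' configured reverberation bands are then applied. A mid-wall contour trace
#' per view is produced at the reference frame (start of the analysed
#' cycle), and the ground truth (kinematics, strain traces, analytic cavity
#' volume, true AVC) is attached.
#'
#' The same seed gives bit-identical output; `noiseSd = 0` with no
#' reverberation bands gives noiseless fields.
#'
#' @param config a [PhantomConfig-class].
#' @param kinematics a [segmentKinematics()] table.
#' @return an [LVStudy-class] with a [PhantomTruth-class] attached.
#' @export
generatePhantom <- function(config = phantomConfig(),
                            kinematics = segmentKinematics()) {
  validObject(config)
  .validateKinematics(kinematics)
  set.seed(config@seed)
  geom <- .meridianGeom(config)
  ft <- seq(0, config@nCycles * config@cycleMs, by = 1000 / config@frameRateHz)
  rw <- (0:config@nCycles) * config@cycleMs
  nf <- length(ft)
  tRel <- ft %% config@cycleMs
  tRel[tRel >= config@cycleMs] <- 0

  beams <- seq(-config@sectorHalfAngleDeg, config@sectorHalfAngleDeg,
               length.out = config@beamsPerView)
  depths <- seq(config@depthRangeMm[1], config@depthRangeMm[2],
                length.out = config@samplesPerBeam)

  epsMat <- matrix(0, nf, 16L)
  depsMat <- matrix(0, nf, 16L)
  for (s in 1:16) {
    kin <- kinematics[s, ]
    epsMat[, s] <- prescribedStrainCurve(kin, tRel, config@cycleMs,
                                         config@systoleMs)
    depsMat[, s] <- prescribedStrainCurve(kin, tRel, config@cycleMs,
                                          config@systoleMs, deriv = TRUE)
  }

  refCycle <- if (config@nCycles >= 2L) 2L else 1L
  refTime <- rw[refCycle]
  referenceFrame <- which(ft >= refTime - 1e-9)[1L]

  # dense material points: the wall itself plus 60 mm of basal (annulus)
  # continuation that deforms with the basal segment, so the painted
  # velocity field does not end abruptly at the wall's base end -- even at
  # peak contraction, when the continuation is drawn apex-ward with the base
  mDense <- seq(0, geom$S + 60, length.out = 360L)
  mWall <- mDense <= geom$S + 1e-9
  uTrace1 <- seq(1, 0, length.out = config@tracePointsPerWall)   # base -> apex
  uTrace2 <- seq(0, 1, length.out = config@tracePointsPerWall)[-1L]

  views <- list()
  traces <- list()
  viewOrder <- c(a4c = "A4C", a2c = "A2C", aplax = "APLAX")
  for (k in seq_along(viewOrder)) {
    vn <- viewOrder[[k]]
    vel <- array(0, dim = c(nf, length(beams), length(depths)))
    for (wall in 1:2) {
      sgn <- if (wall == 1L) 1 else -1
      phi <- .meridianAngle(vn, wall)
      segs <- c(segmentAt(5 / 6, phi), segmentAt(1 / 2, phi),
                segmentAt(1 / 6, phi))  # apical, mid, basal
      # cycles repeat exactly: compute one frame per unique cycle phase and
      # replicate across cycles
      phase <- round(tRel, 9)
      for (ph in unique(phase)) {
        fSet <- which(phase == ph)
        f <- fSet[1L]
        eps3 <- epsMat[f, segs] / 100
        deps3 <- depsMat[f, segs] / 100
        sCur <- .advect(mDense, geom$S, eps3)
        vs <- .advectRate(mDense, geom$S, deps3)          # mm/ms
        zC <- approx(geom$s, geom$z, sCur)$y
        rC <- approx(geom$s, geom$r, sCur)$y
        x2d <- sgn * rC
        y2d <- config@probeStandoffMm + zC
        dPol <- sqrt(x2d^2 + y2d^2)
        if (max(dPol[mWall]) > max(depths) + 1e-9 ||
            min(dPol[mWall]) < min(depths) - 1e-9)
          stop(sprintf("wall leaves the sampled depth range at frame %d", f))
        tx <- sgn * approx(geom$s, geom$drds, sCur)$y
        ty <- approx(geom$s, geom$dzds, sCur)$y
        vx <- tx * vs * 100                               # cm/s
        vy <- ty * vs * 100
        th <- atan2(x2d, y2d) * 180 / pi
        iExt <- if (sgn > 0) which.max(th) else which.min(th)
        branches <- list(seq_len(iExt), iExt:length(th))
        for (br in branches) {
          if (length(br) < 2L) next
          lo <- min(th[br]); hi <- max(th[br])
          bIdx <- which(beams >= lo & beams <= hi)
          if (!length(bIdx)) next
          # wall crossing of each beam: depth, spatial arc, wall tangent
          dW <- approx(th[br], dPol[br], xout = beams[bIdx], ties = mean)$y
          sX <- approx(th[br], sCur[br], xout = beams[bIdx], ties = mean)$y
          txW <- approx(th[br], tx[br], xout = beams[bIdx], ties = mean)$y
          tyW <- approx(th[br], ty[br], xout = beams[bIdx], ties = mean)$y
          iB <- integer(0); iD <- integer(0); sEff <- numeric(0)
          bradAll <- numeric(0)
          for (j in seq_along(bIdx)) {
            if (is.na(dW[j])) next
            brad <- beams[bIdx[j]] * pi / 180
            cosb <- txW[j] * sin(brad) + tyW[j] * cos(brad)
            sinb <- sqrt(max(1 - cosb^2, 1e-6))
            # a sample at depth offset delta along the beam lies a
            # perpendicular distance |delta|*sin(beam-wall angle) from the
            # locally straight wall, and its nearest wall point sits at arc
            # offset delta*cos(beam-wall angle) from the crossing; paint
            # samples within the wall thickness band with that tissue's
            # velocity (extent along the beam capped where the straight-wall
            # approximation degrades)
            delta <- depths - dW[j]
            mask <- which(abs(delta) * sinb <= config@wallHalfwidthMm &
                            abs(delta) <= 35)
            if (!length(mask)) next
            iB <- c(iB, rep(bIdx[j], length(mask)))
            iD <- c(iD, mask)
            sEff <- c(sEff, sX[j] + delta[mask] * cosb)
            bradAll <- c(bradAll, rep(brad, length(mask)))
          }
          if (!length(iB)) next
          vxS <- approx(sCur, vx, xout = sEff, rule = 2)$y
          vyS <- approx(sCur, vy, xout = sEff, rule = 2)$y
          # along-beam component, positive toward the probe
          val <- -(vxS * sin(bradAll) + vyS * cos(bradAll))
          for (ff in fSet)
            vel[cbind(ff, iB, iD)] <- val
        }
      }
    }
    # additive white Gaussian noise from the single seeded stream; the
    # standard-normal draws are independent of noiseSd so the noise
    # component scales exactly with it
    noise <- array(rnorm(length(vel)), dim = dim(vel))
    vel <- vel + config@noiseSd * noise

    rec <- viewRecording(vn, vel, beams, depths, ft, rw)
    for (band in config@reverberationBands) {
      if (identical(band$view, vn) || identical(band$view, names(viewOrder)[k]))
        rec <- injectReverberation(rec, band$beams, band$depthsMm,
                                   band$attenuation)
    }
    views[[names(viewOrder)[k]]] <- rec

    # reference-frame trace: strain is zero at cycle start, so the trace is
    # the undeformed mid-wall geometry
    ptsW1 <- cbind(approx(geom$s, geom$r, uTrace1 * geom$S)$y,
                   config@probeStandoffMm +
                     approx(geom$s, geom$z, uTrace1 * geom$S)$y)
    ptsW2 <- cbind(-approx(geom$s, geom$r, uTrace2 * geom$S)$y,
                   config@probeStandoffMm +
                     approx(geom$s, geom$z, uTrace2 * geom$S)$y)
    pts <- rbind(ptsW1, ptsW2)
    traces[[names(viewOrder)[k]]] <-
      wallTrace(vn, pts, apexIndex = config@tracePointsPerWall,
                referenceFrame = referenceFrame)
  }

  # analytic ground-truth cavity volume: mean over the six meridians of the
  # ellipsoid dome volume below each meridian's current base position
  meridians <- c(0, 60, 120, 180, 240, 300)
  volume <- numeric(nf)
  for (phi in meridians) {
    segs <- c(segmentAt(5 / 6, phi), segmentAt(1 / 2, phi),
              segmentAt(1 / 6, phi))
    sBase <- (1 + epsMat[, segs[1]] / 100) * geom$S / 3 +
      (1 + epsMat[, segs[2]] / 100) * geom$S / 3 +
      (1 + epsMat[, segs[3]] / 100) * geom$S / 3
    zb <- approx(geom$s, geom$z, pmin(sBase, geom$S))$y
    volume <- volume + .domeVolume(zb, config@longAxisMm,
                                   config@baseRadiusMm) / 6
  }

  truth <- new("PhantomTruth",
               kinematics = kinematics,
               trueAvcMs = refTime + config@systoleMs,
               referenceCycleStartMs = refTime,
               strain = epsMat,
               volume = volume,
               frameTimes = ft,
               config = config)
  lvStudy(views, traces, truth)
}
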