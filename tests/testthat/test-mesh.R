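# Sector snapping, velocity sampling, tracking, mesh interpolation, cavity
# volume and AVC detection.

test_that("points snap to the enclosing or nearest beam", {
  beams <- seq(-30, 30, length.out = 21)  # 3-degree spacing
  depths <- seq(10, 110, length.out = 50)
  # interior identity: a point exactly on beam 12 at depth 60
  a <- beams[12] * pi / 180
  s <- snapToSector(c(60 * sin(a), 60 * cos(a)), beams, depths)
  expect_equal(s$beam, 12L)
  expect_equal(s$depthMm, 60)
  expect_false(s$clamped)
  # beyond the last beam: nearest edge
  a <- (beams[21] + 5) * pi / 180
  s <- snapToSector(c(60 * sin(a), 60 * cos(a)), beams, depths)
  expect_equal(s$beam, 21L)
  expect_true(s$clamped)
  a <- (beams[1] - 5) * pi / 180
  expect_equal(snapToSector(c(60 * sin(a), 60 * cos(a)), beams, depths)$beam,
               1L)
  # ties at angular midpoints break toward the lower index: exhaustive scan
  for (i in 1:20) {
    mid <- (beams[i] + beams[i + 1]) / 2 * pi / 180
    expect_equal(snapToSector(c(50 * sin(mid), 50 * cos(mid)),
                              beams, depths)$beam, i)
  }
  # depth clamping
  a <- beams[10] * pi / 180
  s <- snapToSector(c(200 * sin(a), 200 * cos(a)), beams, depths)
  expect_equal(s$depthMm, 110)
  expect_true(s$clamped)
})

test_that("velocity sampling is bilinear with node identity", {
  vel <- array(0, dim = c(2, 3, 3))
  vel[1, , ] <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8, 9), 3, byrow = TRUE)
  rec <- viewRecording("A4C", vel, beamAngles = c(-10, 0, 10),
                       depths = c(20, 40, 60), frameTimes = c(0, 10),
                       rWaveTimes = c(0, 10))
  expect_equal(sampleVelocity(rec, 0, 40, 1), 5)            # node identity
  expect_equal(sampleVelocity(rec, 0, 30, 1), (4 + 5) / 2)  # depth midpoint
  expect_equal(sampleVelocity(rec, -5, 20, 1), (1 + 4) / 2) # beam midpoint
  # uniform field preserved anywhere
  velC <- array(7, dim = c(2, 3, 3))
  recC <- viewRecording("A4C", velC, c(-10, 0, 10), c(20, 40, 60),
                        c(0, 10), c(0, 10))
  expect_equal(sampleVelocity(recC, 3.3, 33.7, 2), 7)
  expect_error(sampleVelocity(rec, 0, 40, 5), "out of range")
})

test_that("tracking integrates the along-beam velocity", {
  mkRec <- function(v) {
    viewRecording("A4C", array(v, dim = c(11, 5, 30)),
                  beamAngles = seq(-20, 20, length.out = 5),
                  depths = seq(10, 110, length.out = 30),
                  frameTimes = seq(0, 100, by = 10),
                  rWaveTimes = c(0, 100))
  }
  pts <- cbind(c(rep(15, 8), rep(-15, 7)),
               c(seq(100, 30, by = -10), seq(40, 100, by = 10)))
  tr <- wallTrace("A4C", pts, apexIndex = 8L, referenceFrame = 1L)
  # zero field: no motion
  tk0 <- trackWall(mkRec(0), tr, 1:11)
  for (f in 1:11)
    expect_equal(tk0@tracked[f, , ], pts, tolerance = 1e-12)
  # uniform 1 cm/s toward the probe for 100 ms: 1 mm displacement along
  # the beam, toward the probe
  tk1 <- trackWall(mkRec(1), tr, 1:11)
  d0 <- sqrt(rowSums(pts^2))
  d1 <- sqrt(rowSums(tk1@tracked[11, , ]^2))
  expect_equal(d0 - d1, rep(1, nrow(pts)), tolerance = 1e-9)
})

test_that("tracked displacement matches phantom truth near end systole", {
  st <- fixNormalStudy()
  rec <- st@views$a4c
  rw <- rWaveTimes(st); ft <- frameTimes(st)
  frames <- which(ft >= rw[2] - 1e-9 & ft < rw[3] - 1e-9)
  tk <- trackWall(rec, st@traces$a4c, frames)
  iES <- which.min(abs(ft[frames] - (rw[2] + 350)))
  # base point of wall 1 (first trace row): longitudinal (y) displacement
  yDisp <- tk@tracked[1, 1, 2] - tk@tracked[iES, 1, 2]
  cfg <- studyTruth(st)@config
  geom <- tdistrain:::.meridianGeom(cfg)
  zTrue <- approx(geom$s, geom$z, geom$S * (1 - 0.18))$y
  yTrue <- cfg@longAxisMm - zTrue
  expect_lt(abs(yDisp - yTrue) / yTrue, 0.10)
})

test_that("the mesh reproduces its six wall knots", {
  # equal walls: the six knots at each level are equal, so the periodic
  # spline is constant around the circumference (u * 20 at arc fraction u
  # from the apex, since the walls are straight lines through the apex)
  tr <- makeStraightTraces(radii = rep(20, 6))
  mesh <- buildMesh(tr, levels = 10L, angles = 36L)
  nodes <- meshNodes(mesh)
  for (l in seq_along(mesh@apexFrac)) {
    rho <- sqrt(nodes[1, l, , 1]^2 + nodes[1, l, , 2]^2)
    expect_equal(rho, rep(mesh@apexFrac[l] * 20, 36), tolerance = 1e-9)
  }

  # random straight-wall geometries: nodes at the source angles equal the
  # arc-resampled tracked 2D points embedded in 3D (radius u * wallRadius)
  set.seed(31)
  for (trial in 1:20) {
    radii <- runif(6, 15, 30)
    tr <- makeStraightTraces(radii = radii)
    mesh <- buildMesh(tr, levels = 8L, angles = 36L)
    nodes <- meshNodes(mesh)
    angIdx <- match(c(0, 60, 120, 180, 240, 300), mesh@angles)
    rho <- sqrt(nodes[1, , angIdx, 1]^2 + nodes[1, , angIdx, 2]^2)
    for (w in 1:6)
      expect_equal(unname(rho[, w]), mesh@apexFrac * radii[w],
                   tolerance = 1e-9)
  }
  expect_error(
    buildMesh(list(a4c = tr$a4c, a2c = tr$a2c,
                   aplax = makeStraightTraces(nFrames = 3)$aplax)),
    "unequal frame")
})

test_that("circumferential interpolation agrees with an independent periodic-spline solver", {
  knots <- seq(0, 300, by = 60)
  vals <- c(20, 22, 20, 22, 20, 22)
  expect_equal(periodicInterp(knots, vals, 30),
               oraclePeriodicSpline(knots, vals, 30), tolerance = 1e-9)
  set.seed(5)
  for (trial in 1:100) {
    vals <- runif(6, 10, 40)
    out <- runif(10, 0, 360)
    expect_equal(periodicInterp(knots, vals, out),
                 oraclePeriodicSpline(knots, vals, out), tolerance = 1e-9)
    # knot reproduction
    expect_equal(periodicInterp(knots, vals, knots), vals, tolerance = 1e-9)
  }
})

test_that("cavity volume matches closed forms and similarity scaling", {
  mesh <- cylinderMesh()
  vTrue <- pi * 10^2 * 50
  expect_lt(abs(cavityVolume(mesh, 1) - vTrue) / vTrue, 0.005)

  m2 <- mesh
  m2@nodes <- mesh@nodes * 2
  expect_equal(cavityVolume(m2, 1) / cavityVolume(mesh, 1), 8,
               tolerance = 1e-9)

  me <- halfEllipsoidMesh()
  vTrue <- 2 / 3 * pi * 20^2 * 60
  expect_lt(abs(cavityVolume(me, 1) - vTrue) / vTrue, 0.01)
})

test_that("cavity volume is invariant under rotation about the long axis", {
  mesh <- halfEllipsoidMesh(a = 17, h = 55, L = 40L, C = 36L)
  v0 <- cavityVolume(mesh, 1)
  set.seed(9)
  for (aRot in runif(3, 0, 2 * pi)) {
    m <- mesh
    x <- mesh@nodes[1, , , 1]; y <- mesh@nodes[1, , , 2]
    m@nodes[1, , , 1] <- cos(aRot) * x - sin(aRot) * y
    m@nodes[1, , , 2] <- sin(aRot) * x + cos(aRot) * y
    expect_lt(abs(cavityVolume(m, 1) - v0) / v0, 1e-9)
  }
})

test_that("degenerate cross-sections are reported with their level", {
  mesh <- cylinderMesh(L = 5L, C = 12L)
  mesh@nodes[1, 3, , 1:2] <- 0  # collapse level 3
  expect_error(cavityVolume(mesh, 1), "level 3")
})

test_that("AVC detection is the argmin of the volume trace", {
  tt <- c(0, 100, 200, 300, 400)
  timing <- detectAVC(c(120, 80, 60, 65, 90), tt, cycleStart = -50,
                      cycleEnd = 800)
  expect_equal(timing@avc, 200)
  expect_equal(timing@midDiastole, 200 + (800 - 200) / 2)
  expect_false(timing@edgeWarning)
  # tie: earliest frame, flagged as an edge minimum
  timing <- detectAVC(c(5, 5, 5), c(0, 100, 200), cycleStart = 0,
                      cycleEnd = 600)
  expect_equal(timing@avc, 0)
  expect_true(timing@edgeWarning)
  # override wins
  timing <- detectAVC(c(120, 80, 60, 65, 90), tt, cycleStart = -50,
                      cycleEnd = 800, avcOverride = 321)
  expect_equal(timing@avc, 321)
  # equals a brute-force scan on random traces
  set.seed(13)
  for (i in 1:50) {
    n <- sample(3:40, 1)
    vols <- runif(n, 40, 150)
    tt <- sort(runif(n, 10, 900))
    timing <- detectAVC(vols, tt, cycleStart = 0, cycleEnd = 1000)
    best <- Inf; bi <- 0L
    for (j in seq_len(n)) if (vols[j] < best) { best <- vols[j]; bi <- j }
    expect_equal(timing@avc, tt[bi])
  }
})

test_that("segment labels follow the 16-segment model with apical discard", {
  # level 0.9 is apical but above the discard line (1 - 0.25/3 = 0.9167)
  expect_true(segmentAt(0.9, 0) %in% 13:16)
  # anteroseptal sector at a basal level
  expect_equal(segmentAt(0.1, 60), 2L)
  expect_equal(segmentAt(0.1, 0), 3L)   # inferoseptal
  expect_equal(segmentAt(0.5, 120), 7L) # mid anterior
  expect_equal(segmentAt(0.9, 30), 14L) # apical septal

  st <- fixSmallStudy()
  rw <- rWaveTimes(st); ft <- frameTimes(st)
  frames <- which(ft >= rw[2] - 1e-9 & ft < rw[3] - 1e-9)
  tk <- lapply(c(a4c = "a4c", a2c = "a2c", aplax = "aplax"), function(nm)
    trackWall(st@views[[nm]], st@traces[[nm]], frames))
  mesh <- buildMesh(tk, levels = 30L, angles = 36L)
  cells <- assignSegments(mesh)
  expect_setequal(unique(cells$segment), 1:16)
  expect_true(all(cells$discard == (cells$level > 1 - 0.25 / 3)))
  # discarded fraction of the apical third's longitudinal extent is about
  # 25% (within one subsegment row: the rule is a cut on the level axis)
  api <- cells$level >= 2 / 3
  rows <- unique(cells$levelIdx[api])
  nDiscard <- length(unique(cells$levelIdx[api & cells$discard]))
  frac <- nDiscard / length(rows)
  expect_lte(abs(frac - 0.25), 1 / length(rows))
  expect_true(all(cells$areaMm2 > 0))
})
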