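# Synthetic phantom: strain curves, beam projection, determinism, noise
# model, reverberation bands and ground truth.

test_that("prescribed strain curves hit their landmark extrema", {
  kin <- segmentKinematics()[1, ]
  expect_equal(prescribedStrainCurve(kin, 0, 1000, 350), 0)
  expect_equal(prescribedStrainCurve(kin, 350, 1000, 350), -18)

  kinP <- segmentKinematics(peakSystolicStrain = -10, pssAmplitude = 8,
                            pssTimeMs = 120)[1, ]
  expect_equal(prescribedStrainCurve(kinP, 350 + 120, 1000, 350), -18)

  # anchored at both cycle ends, smooth in between
  expect_lt(abs(prescribedStrainCurve(kin, 1000 - 1e-6, 1000, 350)), 1e-6)
  tt <- seq(0, 999, by = 1)
  s <- prescribedStrainCurve(kin, tt, 1000, 350)
  expect_lt(max(abs(diff(s))), 0.2)  # no jumps at 1 ms resolution

  expect_error(prescribedStrainCurve(kin, 1000, 1000, 350), "outside")
  expect_error(prescribedStrainCurve(kin, -1, 1000, 350), "outside")
})

test_that("strain-curve derivative is consistent with the curve", {
  kinP <- segmentKinematics(peakSystolicStrain = -12, pssAmplitude = 6)[1, ]
  tt <- seq(5, 990, by = 5)
  d <- prescribedStrainCurve(kinP, tt, 1000, 350, deriv = TRUE)
  num <- (prescribedStrainCurve(kinP, tt + 0.5, 1000, 350) -
            prescribedStrainCurve(kinP, tt - 0.5, 1000, 350))
  expect_lt(max(abs(d - num)), 1e-3)
})

test_that("beam projection is the inner product with unit-norm guard", {
  expect_equal(projectOntoBeam(c(1, 0), c(1, 0)), 1.0)
  expect_equal(projectOntoBeam(c(1, 0), c(0, 1)), 0.0)
  expect_equal(projectOntoBeam(c(3, 4), c(0.6, 0.8)), 5.0)
  expect_error(projectOntoBeam(c(1, 0), c(1, 1)), "unit norm")
  set.seed(7)
  for (i in 1:50) {
    v <- rnorm(2, sd = 10)
    a <- runif(1, 0, 2 * pi)
    expect_lte(abs(projectOntoBeam(v, c(cos(a), sin(a)))),
               sqrt(sum(v^2)) + 1e-12)
  }
})

test_that("zero-motion phantom yields identically zero velocity", {
  cfg <- phantomConfig(noiseSd = 0, nCycles = 2L, frameRateHz = 50,
                       beamsPerView = 16L, samplesPerBeam = 40L,
                       tracePointsPerWall = 10L)
  st <- generatePhantom(cfg, segmentKinematics(peakSystolicStrain = 0))
  for (v in st@views)
    expect_true(all(velocityField(v) == 0))
})

test_that("the same seed reproduces the study bit for bit", {
  cfg <- fixSmallConfig()
  a <- generatePhantom(cfg)
  b <- generatePhantom(cfg)
  for (nm in c("a4c", "a2c", "aplax")) {
    expect_identical(velocityField(a@views[[nm]]),
                     velocityField(b@views[[nm]]))
    expect_identical(tracePoints(a@traces[[nm]]), tracePoints(b@traces[[nm]]))
  }
  expect_identical(studyTruth(a)@strain, studyTruth(b)@strain)
})

test_that("doubling the noise SD changes only the noise component", {
  cfg1 <- phantomConfig(noiseSd = 0.5, nCycles = 2L, frameRateHz = 50,
                        beamsPerView = 24L, samplesPerBeam = 60L,
                        tracePointsPerWall = 10L, seed = 11L)
  cfg2 <- methods::initialize(cfg1, noiseSd = 1.0)
  v1 <- velocityField(generatePhantom(cfg1)@views$a4c)
  v2 <- velocityField(generatePhantom(cfg2)@views$a4c)
  d <- v2 - v1
  expect_gt(length(d), 1e4)
  expect_lt(abs(sd(d) - 0.5) / 0.5, 0.05)
})

test_that("ground-truth cavity volume is smallest at true AVC", {
  st <- fixSmallStudy()
  tru <- studyTruth(st)
  tMin <- tru@frameTimes[which.min(tru@volume)]
  dt <- 1000 / tru@config@frameRateHz
  # the volume trace is cyclic; compare against the same cycle phase
  phaseMin <- tMin %% tru@config@cycleMs
  phaseAvc <- (tru@trueAvcMs - tru@referenceCycleStartMs) %% tru@config@cycleMs
  expect_lte(abs(phaseMin - phaseAvc), dt + 1e-9)
})

test_that("reverberation bands attenuate exactly and validate their range", {
  st <- fixSmallStudy()
  rec <- st@views$a4c
  full <- injectReverberation(rec, c(3L, 6L), c(30, 60), 1.0)
  dMask <- sampleDepths(rec) >= 30 & sampleDepths(rec) <= 60
  expect_true(all(velocityField(full)[, 3:6, dMask] == 0))
  # outside the band: untouched
  expect_identical(velocityField(full)[, 8:16, ],
                   velocityField(rec)[, 8:16, ])
  ident <- injectReverberation(rec, c(3L, 6L), c(30, 60), 0.0)
  expect_identical(velocityField(ident), velocityField(rec))
  half <- injectReverberation(rec, c(3L, 6L), c(30, 60), 0.5)
  expect_equal(velocityField(half)[, 3:6, dMask],
               velocityField(rec)[, 3:6, dMask] * 0.5)
  expect_error(injectReverberation(rec, c(0L, 4L), c(30, 60), 1), "beam range")
  expect_error(injectReverberation(rec, c(3L, 6L), c(-5, 60), 1), "depth range")
  expect_error(injectReverberation(rec, c(3L, 6L), c(30, 60), 1.2),
               "attenuation")
})

test_that("a wall outside the sampled depth range is an error naming the frame", {
  cfg <- phantomConfig(noiseSd = 0, nCycles = 2L, frameRateHz = 50,
                       beamsPerView = 16L, samplesPerBeam = 40L,
                       tracePointsPerWall = 10L,
                       depthRangeMm = c(5, 95))  # base sits at ~103 mm depth
  expect_error(generatePhantom(cfg), "depth range at frame")
})

test_that("kinematics tables enforce their physiologic invariants", {
  expect_error(segmentKinematics(peakSystolicStrain = -40), "\\[-30, 5\\]")
  expect_error(segmentKinematics(pssAmplitude = -1), ">= 0")
  expect_error(segmentKinematics(pssAmplitude = 5, pssTimeMs = 50), "90 ms")
  kin <- ischemicKinematics("RCA", occludedPeak = -8, pssAmplitude = 8)
  idx <- territoryMap()$RCA
  expect_true(all(kin$pssAmplitude[idx] == 8))
  expect_true(all(kin$pssAmplitude[-idx] == 0))
})
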