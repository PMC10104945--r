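# Cycle selection, search windows, peak extraction, PSI and noise flags.

test_that("the second of the available cycles is analysed", {
  expect_equal(selectCycle(c(0, 800, 1600, 2400)), 2L)  # 3 cycles
  expect_equal(selectCycle(c(0, 800)), 1L)              # single cycle
  expect_equal(selectCycle(c(0, 8, 16, 24, 32, 40)), 2L)  # rule is "second"
  expect_error(selectCycle(1000), "no complete")
})

mkTiming <- function(cycleStart = 0, avc = 300, cycleEnd = 900) {
  new("CardiacTiming", cycleStart = cycleStart, cycleEnd = cycleEnd,
      avc = avc, systoleLength = avc - cycleStart,
      midDiastole = avc + (cycleEnd - avc) / 2)
}

test_that("search windows follow the printed rules", {
  win <- searchWindows(mkTiming(avc = 300))
  expect_equal(win$sr, c(0.08 * 300, 0.50 * 300))
  expect_equal(win$systole, c(0, 300))
  win <- searchWindows(mkTiming(avc = 350, cycleEnd = 900))
  expect_equal(win$pss, c(440, 625))  # [AVC + 90, mid-diastole)
})

test_that("peak extraction respects its half-open windows", {
  tt <- seq(0, 850, by = 50)
  win <- searchWindows(mkTiming(avc = 300, cycleEnd = 900))
  # monotone fall to -18 through systole
  strain <- pmax(-18, -18 * tt / 250)
  expect_equal(as.numeric(peakSystolicStrain(tt, strain, win)), -18)
  expect_equal(as.numeric(peakSystolicStrain(tt, rep(0, length(tt)), win)), 0)
  # pre-ejection spike at 10 ms is outside [24, 150)
  sr <- rep(-1, length(tt)); sr[1] <- -3
  expect_equal(as.numeric(peakSystolicSR(tt, sr, win)), -1)
  # a dip 50 ms after AVC is outside the post-systolic window
  strain2 <- rep(-5, length(tt)); strain2[tt == 350] <- -20
  expect_gt(as.numeric(postSystolicPeak(tt, strain2, win)), -20)
  # empty post-systolic window: missing, not an error
  winShort <- searchWindows(mkTiming(avc = 300, cycleEnd = 420))
  expect_true(is.na(postSystolicPeak(tt, strain, winShort)))
  expect_error(peakSystolicStrain(tt[tt > 500], strain[tt > 500], win),
               "empty")
})

test_that("window extrema equal brute-force frame scans on random traces", {
  set.seed(17)
  for (i in 1:100) {
    sc <- randomTraceScenario()
    win <- searchWindows(sc$timing)
    got <- tryCatch(as.numeric(peakSystolicStrain(sc$times, sc$strain, win)),
                    error = function(e) NA_real_)
    expect_identical(got, oracleWindowMin(sc$times, sc$strain,
                                          win$systole[1], win$systole[2]))
    gotSR <- tryCatch(as.numeric(peakSystolicSR(sc$times, sc$sr, win)),
                      error = function(e) NA_real_)
    expect_identical(gotSR, oracleWindowMin(sc$times, sc$sr,
                                            win$sr[1], win$sr[2]))
    gotP <- as.numeric(postSystolicPeak(sc$times, sc$strain, win))
    expect_identical(gotP, oracleWindowMin(sc$times, sc$strain,
                                           win$pss[1], win$pss[2]))
    # systole contains the SR window start, so peak systolic strain is
    # never below the whole-cycle minimum
    if (!is.na(got)) expect_gte(got, min(sc$strain))
  }
})

test_that("PSI follows the peak-cycle / end-systolic formula", {
  expect_equal(as.numeric(psi(-20, -18)), 10.0)
  expect_equal(as.numeric(psi(-15, -15)), 0.0)
  p <- psi(-10, 2)
  expect_equal(as.numeric(p), 120.0)
  expect_equal(attr(p, "flag"), "suspect")
  p0 <- psi(0, 0)
  expect_equal(as.numeric(p0), 0)
  expect_equal(attr(p0, "flag"), "flat")
  # invariant under positive scaling of the whole trace
  set.seed(3)
  for (i in 1:20) {
    pc <- -runif(1, 1, 25); es <- pc + runif(1, 0, 10)
    k <- runif(1, 0.1, 4)
    expect_equal(as.numeric(psi(pc, es)), as.numeric(psi(k * pc, k * es)),
                 tolerance = 1e-12)
  }
})

test_that("noise cut-offs are strict inequalities", {
  expect_true(noiseFlag(-30))
  expect_false(noiseFlag(-10))
  expect_true(noiseFlag(6))
  expect_false(noiseFlag(-25))  # boundary passes
  expect_false(noiseFlag(5))
  set.seed(23)
  x <- runif(500, -60, 40)
  expect_identical(noiseFlag(x), x < -25 | x > 5)
  expect_identical(noiseFlag(x, cutoffs = c(-10, 2)), x < -10 | x > 2)
})

test_that("noise area fraction is area-weighted over non-discarded cells", {
  expect_equal(noiseAreaFraction(c(TRUE, rep(FALSE, 9)), rep(1, 10)), 10)
  expect_equal(noiseAreaFraction(rep(FALSE, 4), rep(2, 4)), 0)
  expect_equal(noiseAreaFraction(c(TRUE, FALSE, FALSE), c(2, 1, 1)), 50)
  # discarded cells leave numerator and denominator
  expect_equal(noiseAreaFraction(c(TRUE, TRUE, FALSE), c(5, 1, 1),
                                 discard = c(TRUE, FALSE, FALSE)), 50)
  expect_error(noiseAreaFraction(logical(0), numeric(0)), "area")
})

test_that("per-segment metrics are internally consistent", {
  rep <- fixNormalReport()
  m <- segmentTable(rep)
  expect_equal(nrow(m), 16L)
  # systole window is a subset of the cycle: both minima of the same trace
  expect_true(all(m$peakSystolicStrain >= m$peakCycleStrain - 1e-9))
  expect_true(all(m$psi >= 0))
  expect_false(any(m$noiseFlag))
})
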