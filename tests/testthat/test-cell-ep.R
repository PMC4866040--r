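test_that("grey-zone remodelling scales the four target currents once", {
  base <- cellParams()
  gz <- makeGzParams(base)
  expect_equal(gz@gNa / base@gNa, 0.38)      # 62% peak sodium reduction
  expect_equal(gz@gCaL / base@gCaL, 0.31)    # 69% L-type calcium reduction
  expect_equal(gz@gKr / base@gKr, 0.30)      # 70% I_Kr reduction
  expect_equal(gz@gKs / base@gKs, 0.20)      # 80% I_Ks reduction
  expect_equal(gz@gK1, base@gK1)
  expect_equal(gz@gto, base@gto)
  # idempotent: applying the remodelling twice changes nothing
  expect_equal(makeGzParams(gz), gz)
})

test_that("the quiescent membrane is at equilibrium", {
  # equilibrate from the published paced state, then check drift
  s0 <- stepCell(initialCellState(), cellParams(), nSteps = 30L * 40000L)
  s1 <- stepCell(s0, cellParams(), nSteps = 40000L)   # 1000 ms
  expect_lt(abs(s1[["Vm"]] - s0[["Vm"]]), 0.1)
})

test_that("a suprathreshold stimulus elicits an action potential", {
  s <- initialCellState()
  s <- stepCell(s, cellParams(), iStim = 52, nSteps = 40L)   # 1 ms pulse
  s <- stepCell(s, cellParams(), nSteps = 200L)
  expect_gt(s[["Vm"]], 0)
})

test_that("time-step refinement changes APD90 by less than 1 ms", {
  a <- runCellTrain(cellParams(), nBeats = 2, dt = 0.025,
                    sampleInterval = 0.05)$features$apd90
  b <- runCellTrain(cellParams(), nBeats = 2, dt = 0.0125,
                    sampleInterval = 0.05)$features$apd90
  expect_lt(abs(a - b), 1)
  expect_error(stepCell(initialCellState(), cellParams(), dt = 0.05),
               "<= 0.025")
})

test_that("grey-zone APs are longer, slower-rising and lower-peaked than
          normal", {
  n <- runCellTrain(cellParams(), nBeats = 3)
  g <- runCellTrain(makeGzParams(cellParams()), nBeats = 3)
  expect_gt(g$features$apd90, n$features$apd90)
  expect_lt(g$features$dvdtMax, n$features$dvdtMax)
  expect_lt(g$features$peakVm, n$features$peakVm)
})

test_that("identical inputs give bit-identical trajectories", {
  a <- runCellTrain(cellParams(), nBeats = 2)
  b <- runCellTrain(cellParams(), nBeats = 2)
  expect_identical(a$vm, b$vm)
  expect_identical(a$state, b$state)
})

test_that("gates stay in [0,1] under random paced protocols", {
  gateIdx <- 7:19   # m h j xr1 xr2 xs r s d f f2 fCass RR
  set.seed(42)
  for (p in list(cellParams(), makeGzParams(cellParams()))) {
    s <- initialCellState()
    for (seg in 1:20) {
      stimOn <- runif(1) < 0.5
      s <- stepCell(s, p, iStim = if (stimOn) runif(1, 20, 60) else 0,
                    nSteps = sample(400:20000, 1))
      expect_true(all(s[gateIdx] >= 0 & s[gateIdx] <= 1))
      expect_true(all(s[2:6] > 0))          # concentrations positive
    }
  }
})

test_that("AP features of a synthetic triangle wave are exact", {
  t <- seq(0, 450, by = 0.5)
  v <- ifelse(t <= 2, -85 + 60 * t,
              pmax(-85, 35 - (t - 2) * 120 / 398))
  f <- apFeatures(t, v)
  expect_true(f$detected)
  expect_equal(f$peakVm, 35, tolerance = 1e-6)
  expect_equal(f$restingVm, -85)
  expect_equal(f$dvdtMax, 60, tolerance = 1e-6)
  # 90% repolarization toward -85 is at v = -73, reached at
  # t = 2 + 0.9 * 398 on the linear downstroke; the maximum-upstroke time
  # is the first sample of the constant-slope rise (t = 0)
  expect_equal(f$apd90, 2 + 0.9 * 398, tolerance = 0.5)
})

test_that("a constant trace yields an explicit no-AP result", {
  f <- apFeatures(seq(0, 100), rep(-85, 101))
  expect_false(f$detected)
  expect_true(is.na(f$apd90))
})

test_that("features agree between coarse and fine trace sampling", {
  a <- runCellTrain(cellParams(), nBeats = 1, tail = 450,
                    sampleInterval = 0.1)$features
  b <- runCellTrain(cellParams(), nBeats = 1, tail = 450,
                    sampleInterval = 0.025)$features
  expect_lt(abs(a$apd90 - b$apd90), 1)
  expect_lt(abs(a$peakVm - b$peakVm), 1)
})

test_that("trace export writes the two-column CSV", {
  tr <- runCellTrain(cellParams(), nBeats = 1, tail = 100,
                     sampleInterval = 1)
  path <- file.path(withr::local_tempdir(), "trace.csv")
  exportTrace(tr$time, tr$vm, path)
  back <- utils::read.csv(path)
  expect_identical(names(back), c("time_ms", "vm_mV"))
  expect_equal(back$vm_mV, tr$vm)
})
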