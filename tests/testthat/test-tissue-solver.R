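# most tissue tests run on small sheets so the whole file stays fast

test_that("an unstimulated resting sheet stays quiescent", {
  sheet <- smallSheet(12)
  rec <- runMonodomain(sheet, sheetFibersX(sheet), duration = 50,
                       config = simConfig(outputInterval = 10))
  expect_equal(sum(lengths(activationTimes(rec))), 0L)
  expect_lt(max(abs(vmFrames(rec) - initialCellState()[["Vm"]])), 1)
})

test_that("scar tissue is inviolable and excluded from the domain", {
  mesh <- infarctedSheet(n = 30, dx = 0.5, rScar = 4, rim = 1.5)
  fib <- sheetFibersX(mesh)
  rec <- runMonodomain(mesh, fib, duration = 120,
    stimuli = list(stimulusSpec(center = c(1, 1), amplitude = 60)),
    config = simConfig(outputInterval = Inf))
  scar <- which(rec@nodeLabels == 2L)
  expect_gt(length(scar), 0)
  expect_true(all(lengths(activationTimes(rec)[scar]) == 0L))
  # the wave does propagate through the rest of the tissue
  ok <- which(rec@nodeLabels != 2L)
  expect_gt(mean(lengths(activationTimes(rec)[ok]) > 0), 0.95)
})

test_that("isochrones are elongated along the fibre axis", {
  sheet <- generateSheet(40, 40, 0.5)
  fib <- sheetFibersX(sheet)
  rec <- runMonodomain(sheet, fib, duration = 60,
    stimuli = list(stimulusSpec(center = c(10, 10), amplitude = 60)),
    config = simConfig(outputInterval = Inf))
  lat <- suppressWarnings(computeActivationMap(rec))
  nd <- meshNodes(sheet)
  atxy <- function(x, y) lat[which.min((nd[, 1] - x)^2 + (nd[, 2] - y)^2)]
  tAlong <- atxy(18, 10)
  tAcross <- atxy(10, 18)
  expect_true(is.finite(tAlong) && is.finite(tAcross))
  expect_gt(tAcross / tAlong, 1.4)    # faster along the fibre
})

test_that("conduction velocity arithmetic on a synthetic recording", {
  mesh <- generateSheet(20, 1, 0.5)
  acts <- rep(list(numeric(0)), nNodes(mesh))
  nd <- meshNodes(mesh)
  ia <- which(nd[, 1] == 2.5 & nd[, 2] == 0)
  ib <- which(nd[, 1] == 7.5 & nd[, 2] == 0)
  acts[[ia]] <- 10; acts[[ib]] <- 20
  rec <- syntheticRecording(acts)
  expect_equal(measureCv(rec, mesh, c(2.5, 0), c(7.5, 0)), 0.5)
  expect_error(measureCv(rec, mesh, c(0, 0), c(7.5, 0)),
               "activated exactly once")
})

test_that("the CV anisotropy ratio approaches sqrt(sigma_l/sigma_t) at
          refined resolution", {
  cvL <- varpsim:::.strandCv(0.255, cellParams(), simConfig(), 0.175)
  cvT <- varpsim:::.strandCv(0.0775, cellParams(), simConfig(), 0.175)
  expect_lt(abs(cvL / cvT - sqrt(0.255 / 0.0775)) / sqrt(0.255 / 0.0775),
            0.10)
})

test_that("CV at the working resolution is within 15% of the refined
          value", {
  cv35 <- varpsim:::.strandCv(0.255, cellParams(), simConfig(), 0.35)
  cv17 <- varpsim:::.strandCv(0.255, cellParams(), simConfig(), 0.175)
  expect_lt(abs(cv35 - cv17) / cv17, 0.15)
})

test_that("conductivity tuning is a fixed point at its own targets and
          follows the square-root law", {
  cfg <- simConfig(outputInterval = Inf)
  cvL <- varpsim:::.strandCv(0.255, cellParams(), cfg, 0.35)
  cvT <- varpsim:::.strandCv(0.0775, cellParams(), cfg, 0.35)
  fix <- tuneConductivities(cvL, cvT, dx = 0.35)
  expect_true(fix$converged)
  expect_lt(abs(fix$cond@normal[1] - 0.255) / 0.255, 0.02)
  expect_lt(abs(fix$cond@normal[2] - 0.0775) / 0.0775, 0.02)
  # grey zone keeps the 90% transverse reduction
  expect_equal(fix$cond@gz[2], 0.1 * fix$cond@normal[2])

  # doubling the longitudinal target quadruples sigma (within 10% at the
  # refined resolution, where the continuum CV ~ sqrt(sigma) law holds)
  cvLr <- varpsim:::.strandCv(0.255, cellParams(), cfg, 0.175)
  dbl <- tuneConductivities(2 * cvLr, cvLr / 1.8, dx = 0.175)
  expect_lt(abs(dbl$cond@normal[1] - 4 * 0.255) / (4 * 0.255), 0.10)

  expect_error(tuneConductivities(0, 0.3), "positive")
})

test_that("diffusion conserves the mass-weighted mean under no-flux
          boundaries", {
  sheet <- generateSheet(15, 15, 0.5)
  fib <- sheetFibersX(sheet)
  state <- matrix(rep(as.numeric(initialCellState()), nNodes(sheet)),
                  nrow = 19)
  set.seed(5)
  state[1, ] <- -85 + runif(nNodes(sheet), -15, 15)
  cfg <- simConfig(outputInterval = Inf, freezeIonic = TRUE)
  rec <- runMonodomain(sheet, fib, duration = 20, config = cfg,
                       state = state)
  m <- varpsim:::.lumpedMass(sheet)
  before <- sum(m * state[1, ]) / sum(m)
  after <- sum(m * rec@finalState[1, ]) / sum(m)
  expect_equal(after, before, tolerance = 1e-8)
  # and the field is smoothed, not frozen
  expect_lt(stats::sd(rec@finalState[1, ]), stats::sd(state[1, ]))
})

test_that("a centred stimulus on a fibre-aligned square sheet respects the
          axis symmetries", {
  n <- 21
  sheet <- generateSheet(n, n, 0.5)
  fib <- sheetFibersX(sheet)
  mid <- n * 0.5 / 2
  rec <- runMonodomain(sheet, fib, duration = 16,
    stimuli = list(stimulusSpec(center = c(mid, mid), amplitude = 60)),
    config = simConfig(outputInterval = 8))
  v <- vmFrames(rec)[, 2]
  grid <- matrix(v, n + 1, n + 1)   # x fastest in node ordering
  expect_equal(grid, grid[(n + 1):1, ], tolerance = 1e-6)
  expect_equal(grid, grid[, (n + 1):1], tolerance = 1e-6)
})

test_that("numerical instability aborts with time and node named", {
  sheet <- smallSheet(6)
  expect_error(
    runMonodomain(sheet, sheetFibersX(sheet), duration = 10,
      stimuli = list(stimulusSpec(center = c(1, 1), amplitude = 5000,
                                  duration = 5)),
      config = simConfig(outputInterval = Inf)),
    "instability.*node")
})

test_that("an all-scar mesh is rejected as an empty conductive domain", {
  sheet <- smallSheet(4)
  sheet@labels <- rep(2L, nElements(sheet))
  expect_error(runMonodomain(sheet, sheetFibersX(sheet), duration = 1,
                             config = simConfig()),
               "empty conductive domain")
})
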