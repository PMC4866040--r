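test_that("the biventricular panel carries exactly 19 labeled sites", {
  bv <- generateLVEllipsoid(9, 30, 70, dx = 1.5, withRV = TRUE)
  sites <- placePacingSites(bv)
  expect_equal(nrow(sites), 19L)
  expect_setequal(sites$site, c(as.character(1:17), "RV_APEX", "RV_OT"))
  # all sites on conductive endocardium
  expect_true(all(sites$node %in%
    c(meshSurfaces(bv)$endo, meshSurfaces(bv)$rv_endo)))
})

test_that("the LV-only panel has 17 sites and a missing RV is an explicit
          error", {
  lv <- generateLVEllipsoid(9, 30, 70, dx = 1.5)
  expect_error(placePacingSites(lv), "17-site LV panel")
  sites <- placePacingSites(lv, lvOnly = TRUE)
  expect_equal(nrow(sites), 17L)
})

test_that("a site whose segment centroid lies in scar is relocated to
          conductive endocardium", {
  lv <- generateLVEllipsoid(9, 30, 70, dx = 1.5)
  s0 <- placePacingSites(lv, lvOnly = TRUE)
  # bury one site's neighbourhood in scar
  target <- s0[s0$site == "3", ]
  lvInf <- addInfarct(lv, infarctSpec(
    center = c(target$x, target$y, target$z),
    radii = c(8, 8, 8), gzRimWidth = 0))
  expect_message(s1 <- placePacingSites(lvInf, lvOnly = TRUE), "relocated")
  moved <- s1[s1$site == "3", ]
  expect_true(moved$relocated)
  lab <- varpsim:::.nodeLabels(lvInf)
  expect_true(all(lab[s1$node] != 2L))
})

test_that("pulse-train scheduling follows the S1-S4 arithmetic", {
  train <- pulseTrain()
  s1 <- schedulePulseTrain(train)
  expect_length(s1, 8L)
  expect_equal(s1[7], 3600)
  expect_equal(s1[8], 4200)
  expect_equal(tail(schedulePulseTrain(train, 300), 1), 4500)
  expect_equal(tail(schedulePulseTrain(train, c(280, 300)), 2),
               c(4480, 4780))
  expect_error(schedulePulseTrain(pulseTrain(minCoupling = 200), 150),
               "floor")
  expect_error(schedulePulseTrain(train, c(300, 300, 300, 300)),
               "at most")
  expect_error(pulseTrain(prematureInitial = 700), "shorter")
})

test_that("re-entry detection implements the outcome trichotomy", {
  tLast <- 4500
  quiet <- rep(list(numeric(0)), 30)
  evoked <- lapply(1:30, function(i) tLast + 5 + i)   # one evoked beat

  expect_equal(detectReentry(syntheticRecording(quiet, tEnd = 7000),
                             tLast)$classification, "NONINDUCIBLE")
  expect_equal(detectReentry(syntheticRecording(evoked, tEnd = 7000),
                             tLast)$classification, "NONINDUCIBLE")

  # one extra re-activation wave ending at +600 ms: a single beat
  sb <- lapply(1:30, function(i) tLast + c(5, 580) + i / 2)
  expect_equal(detectReentry(syntheticRecording(sb, tEnd = 7000),
                             tLast)$classification, "SINGLE_BEAT")

  # periodic activity every 300 ms through the whole window: sustained
  per <- lapply(1:30, function(i) tLast + i / 3 + seq(5, 1995, by = 300))
  out <- detectReentry(syntheticRecording(per, tEnd = 7000), tLast)
  expect_equal(out$classification, "SUSTAINED")
  expect_equal(out$vtCycleLength, 300, tolerance = 1e-6)

  # activity ceasing at T = 1200 ms: unsustained (still a positive call)
  un <- lapply(1:30, function(i) tLast + i / 3 + seq(5, 1250, by = 300))
  outU <- detectReentry(syntheticRecording(un, tEnd = 7000), tLast)
  expect_equal(outU$classification, "UNSUSTAINED")
  expect_false(is.na(outU$vtCycleLength))

  expect_error(detectReentry(syntheticRecording(quiet, tEnd = 5000),
                             tLast), "extend")
})

test_that("activation maps report first activations and flag silent
          nodes", {
  acts <- list(c(10), c(20, 400), numeric(0), c(30))
  rec <- syntheticRecording(acts, tEnd = 500)
  lat <- computeActivationMap(rec, 0, 100)
  expect_equal(lat, c(10, 20, NA, 30))
  expect_error(computeActivationMap(rec, 700, 600), "from < to")
  expect_error(computeActivationMap(syntheticRecording(
    rep(list(numeric(0)), 4), tEnd = 500), 0, 100), "no activations")
})

test_that("capture detection distinguishes refractory from recovered
          tissue and is deterministic", {
  sheet <- generateSheet(30, 30, 0.5)
  fib <- sheetFibersX(sheet)
  ctr <- c(7.5, 7.5)
  cfg <- simConfig(outputInterval = Inf)
  stim <- function(t) stimulusSpec(center = ctr, onset = t, amplitude = 60)
  # S2 well inside the refractory period of the first beat
  r <- runMonodomain(sheet, fib, stimuli = list(stim(0), stim(150)),
                     duration = 310, config = cfg)
  expect_true(detectCapture(r, sheet, ctr, 0))
  expect_false(detectCapture(r, sheet, ctr, 150))
  # identical rerun gives identical capture flags
  r2 <- runMonodomain(sheet, fib, stimuli = list(stim(0), stim(150)),
                      duration = 310, config = cfg)
  expect_identical(vapply(list(r, r2), detectCapture, logical(1),
                          mesh = sheet, center = ctr, stimOnset = 150),
                   c(FALSE, FALSE))
})

test_that("a healthy sheet is non-inducible and the scan ladder is
          monotone", {
  sheet <- generateSheet(24, 24, 0.5)
  fib <- sheetFibersX(sheet)
  # compressed drive train keeps the test fast; the decrement logic is
  # identical to the full protocol
  train <- pulseTrain(nS1 = 2L, s1CL = 450, prematureInitial = 400,
                      decrement = 20, maxExtrastimuli = 2L)
  out <- runSiteProtocol(sheet, fib, conductivities(),
                         list(normal = cellParams()), c(6, 6),
                         train = train, config = simConfig(outputInterval = Inf),
                         amplitude = 40, window = 600)
  expect_equal(out$classification, "NONINDUCIBLE")
  tested <- out$tested
  for (lv in unique(tested$level)) {
    cp <- tested$coupling[tested$level == lv]
    expect_equal(cp, seq(400, by = -20, length.out = length(cp)))
    # the scan never went below a coupling it had already failed
    if (any(!tested$captured[tested$level == lv]))
      expect_false(tested$captured[tested$level == lv][length(cp)])
  }
})

test_that("runVarp aggregates site outcomes with an OR and survives site
          failures", {
  sheet <- generateSheet(24, 24, 0.5)
  fib <- sheetFibersX(sheet)
  train <- pulseTrain(nS1 = 1L, s1CL = 450, prematureInitial = 380,
                      decrement = 20, maxExtrastimuli = 1L)
  res <- suppressWarnings(runVarp(sheet, fib, sites = list(
      a = c(3, 3), bad = c(1e6, 1e6)),
    train = train, config = simConfig(outputInterval = Inf),
    amplitude = 40, window = 600, seed = 1))
  so <- siteOutcomes(res)
  expect_equal(overallCall(res), "negative")
  expect_equal(so$classification[so$site == "a"], "NONINDUCIBLE")
  expect_equal(so$classification[so$site == "bad"], "FAILED")
})

test_that("the cohort schedule enumerates 41 x 19 = 779 simulations", {
  plan <- planVarpStudy(41)
  expect_equal(nrow(plan), 779L)
  expect_equal(length(unique(plan$site)), 19L)
})

test_that("result reports round-trip through the JSON schema", {
  sites <- data.frame(
    site = c("1", "2", "RV_APEX"),
    classification = c("NONINDUCIBLE", "UNSUSTAINED", "SINGLE_BEAT"),
    vtCycleLength = c(NA, 342.5, NA),
    couplings = c("", "340/300", "320"))
  res <- new("VarpResult", sites = sites, overall = "positive",
             provenance = list(seed = 7))
  path <- file.path(withr::local_tempdir(), "res.json")
  out <- utils::capture.output(varpReport(res, path))
  expect_true(any(grepl("POSITIVE", out)))
  back <- parseVarpReport(path)
  expect_equal(overallCall(back), "positive")
  expect_equal(siteOutcomes(back)$classification,
               sites$classification)
  expect_equal(siteOutcomes(back)$vtCycleLength, sites$vtCycleLength)
})

test_that("adding a non-inducible site never flips the overall call", {
  sites <- data.frame(site = "1", classification = "UNSUSTAINED",
                      vtCycleLength = 350, couplings = "300")
  res <- new("VarpResult", sites = sites, overall = "positive",
             provenance = list())
  sites2 <- rbind(sites, data.frame(site = "2",
    classification = "NONINDUCIBLE", vtCycleLength = NA, couplings = ""))
  res2 <- new("VarpResult", sites = sites2, overall = "positive",
              provenance = list())
  expect_equal(overallCall(res2), overallCall(res))
  # and the validity check refuses an inconsistent overall call
  expect_error(new("VarpResult", sites = sites2, overall = "negative",
                   provenance = list()), "inconsistent")
})
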