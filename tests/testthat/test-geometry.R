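test_that("sheet generator obeys grid arithmetic", {
  s <- generateSheet(10, 10, 0.35)
  expect_equal(nNodes(s), 121L)
  expect_equal(nElements(s), 100L)
  expect_equal(apply(meshNodes(s), 2, max), c(x = 3.5, y = 3.5))

  s1 <- generateSheet(1, 1, 0.35)
  expect_equal(nNodes(s1), 4L)
  expect_equal(nElements(s1), 1L)

  big <- generateSheet(142, 142, 0.35)
  expect_equal(nNodes(big), 143L^2)
  expect_equal(max(meshNodes(big)[, 1]), 142 * 0.35)

  expect_error(generateSheet(0, 5), "must be >= 1")
  expect_error(generateSheet(5, 5, -1), "positive")
})

test_that("slab generator obeys grid arithmetic", {
  s <- generateSlab(10, 10, 3, 0.35)
  expect_equal(nNodes(s), 484L)
  expect_equal(nElements(s), 300L)

  cube <- generateSlab(1, 1, 1, 1.0)
  expect_equal(nNodes(cube), 8L)
  expect_equal(nElements(cube), 1L)

  s2 <- generateSlab(57, 57, 8, 0.35)
  expect_equal(nElements(s2), 57L * 57L * 8L)
  expect_equal(max(meshNodes(s2)[, 3]), 8 * 0.35)

  expect_error(generateSlab(3, 3, 0, 0.35), ">= 1")
})

test_that("grid node/element counts match closed forms for random sizes", {
  set.seed(7)
  for (k in 1:8) {
    nx <- sample(1:9, 1); ny <- sample(1:9, 1); nz <- sample(1:4, 1)
    sh <- generateSheet(nx, ny, 0.5)
    expect_equal(nNodes(sh), (nx + 1L) * (ny + 1L))
    expect_equal(nElements(sh), nx * ny)
    sl <- generateSlab(nx, ny, nz, 0.5)
    expect_equal(nNodes(sl), (nx + 1L) * (ny + 1L) * (nz + 1L))
    expect_equal(nElements(sl), nx * ny * nz)
    expect_equal(sum(labelFractions(sl)), 1)
  }
})

test_that("idealized LV shell exposes consistent geometric surfaces", {
  lv <- generateLVEllipsoid(10, 30, 70, dx = 2)
  surf <- meshSurfaces(lv)
  expect_true(all(c("endo", "epi", "base", "apex") %in% names(surf)))
  expect_gt(length(surf$endo), 0)
  expect_gt(length(surf$epi), 0)
  expect_length(intersect(surf$endo, surf$epi), 0)

  # every wall element centroid lies between the two ellipsoid surfaces
  cent <- varpsim:::.elementCentroids(lv)
  eEpi <- (cent[, 1] / 30)^2 + (cent[, 2] / 30)^2 + (cent[, 3] / 70)^2
  eEndo <- (cent[, 1] / 20)^2 + (cent[, 2] / 20)^2 + (cent[, 3] / 60)^2
  expect_true(all(eEpi <= 1 + 1e-9))
  expect_true(all(eEndo >= 1 - 1e-9))

  expect_error(generateLVEllipsoid(1, 30, 70, dx = 1), "fewer than 3")
  expect_error(generateLVEllipsoid(40, 30, 70, dx = 1), "smaller")
})

test_that("biventricular shell classifies RV surface against the analytic
          ellipsoids", {
  bv <- generateLVEllipsoid(9, 30, 70, dx = 1.5, withRV = TRUE)
  surf <- meshSurfaces(bv)
  expect_true("rv_endo" %in% names(surf))
  expect_gt(length(surf$rv_endo), 0)
  # rv_endo nodes must be closer to the RV endocardial ellipsoid than to
  # either LV surface (the geometric oracle used for classification)
  nd <- meshNodes(bv)[surf$rv_endo, , drop = FALSE]
  # RV endocardial ellipsoid: offset 0.9*30, semi-axes (27 - wall, 52.5 - wall)
  rvWall <- max(9 / 3, 3 * 1.5)
  eRvEndo <- ((nd[, 1] - 27) / (27 - rvWall))^2 + (nd[, 2] / (27 - rvWall))^2 +
    (nd[, 3] / (52.5 - rvWall))^2
  expect_lt(stats::median(abs(eRvEndo - 1)), 0.3)
  # apex anchor resolvable and on the epicardium
  expect_true(surf$apex %in% surf$epi)
  # outflow-region anchor: basal-most RV endocardial node exists
  expect_gte(max(meshNodes(bv)[surf$rv_endo, 3]), -10)
})

test_that("infarct insertion builds scar core, GZ annulus and isthmus", {
  mesh <- infarctedSheet(n = 40, dx = 0.5, rScar = 5, rim = 2)
  fr <- labelFractions(mesh)
  expect_gt(fr[["SCAR"]], 0)
  expect_gt(fr[["GZ"]], 0)
  expect_equal(sum(fr), 1)
  # GZ forms a connected annulus around the scar
  expect_true(labelsConnected(mesh, 1L))
  # scar connected too, and strictly inside the GZ bounding box
  expect_true(labelsConnected(mesh, 2L))

  # rim width 0: no GZ at all
  m0 <- addInfarct(generateSheet(40, 40, 0.5),
                   infarctSpec(c(10, 10), c(5, 5), gzRimWidth = 0))
  expect_equal(labelFractions(m0)[["GZ"]], 0)

  # labels outside the grown footprint untouched
  mesh2 <- generateSheet(40, 40, 0.5)
  spec <- infarctSpec(c(10, 10), c(4, 4), gzRimWidth = 1.5)
  out <- addInfarct(mesh2, spec)
  cent <- varpsim:::.elementCentroids(mesh2)
  d2 <- (cent[, 1] - 10)^2 + (cent[, 2] - 10)^2
  outside <- d2 > (4 + 1.5 + 0.8)^2
  expect_true(all(out@labels[outside] == 0L))
})

test_that("a NORMAL isthmus keeps the normal tissue globally connected", {
  mesh <- generateSheet(40, 40, 0.5)
  # scar band bisecting the sheet, 1.4 mm NORMAL channel in the middle
  spec <- infarctSpec(center = c(10, 10), radii = c(100, 3), gzRimWidth = 1,
                      isthmusWidth = 1.4, isthmusLabel = "NORMAL",
                      isthmusAxis = 1L, isthmusCenter = 10)
  cut <- addInfarct(mesh, spec)
  expect_true(labelsConnected(cut, 0L))
  # without the channel the normal tissue is split in two
  noChan <- addInfarct(mesh, infarctSpec(center = c(10, 10),
                                         radii = c(100, 3), gzRimWidth = 1))
  expect_false(labelsConnected(noChan, 0L))
})

test_that("a non-intersecting infarct warns and leaves the mesh unchanged", {
  mesh <- generateSheet(10, 10, 0.5)
  expect_warning(out <- addInfarct(mesh, infarctSpec(c(100, 100), c(2, 2))),
                 "does not intersect")
  expect_identical(out@labels, mesh@labels)
})
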