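test_that("Laplace solve on a slab is the exact linear through-thickness
          coordinate", {
  slab <- generateSlab(4, 4, 6, 0.5)
  phi <- solveLaplace(slab, c(endo = 0, epi = 1))
  z <- meshNodes(slab)[, 3]
  expect_equal(phi, z / 3, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("equal Dirichlet values give a constant harmonic field", {
  slab <- generateSlab(3, 3, 3, 0.5)
  phi <- solveLaplace(slab, c(endo = 0.4, epi = 0.4))
  expect_equal(phi, rep(0.4, nNodes(slab)), tolerance = 1e-10)
})

test_that("the discrete maximum principle holds on the LV shell", {
  lv <- generateLVEllipsoid(10, 30, 70, dx = 2.5)
  phi <- solveLaplace(lv, c(endo = 0, epi = 1))
  fixed <- c(meshSurfaces(lv)$endo, meshSurfaces(lv)$epi)
  interior <- setdiff(seq_len(nNodes(lv)), fixed)
  expect_true(all(phi[interior] > 0 & phi[interior] < 1))
  expect_true(all(phi >= 0 & phi <= 1 + 1e-12))
})

test_that("a component with no boundary condition is rejected", {
  # two disconnected quads; Dirichlet data only on the first
  nodes <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1),
                 c(5, 0), c(6, 0), c(6, 1), c(5, 1))
  el <- rbind(1:4, 5:8); storage.mode(el) <- "integer"
  mesh <- new("LabeledMesh", nodes = nodes, elements = el,
              labels = c(0L, 0L), resolution = 1,
              surfaces = list(left = 1:2), dims = integer(0))
  expect_error(solveLaplace(mesh, c(left = 0)), "no Dirichlet|singular")
  slab <- generateSlab(2, 2, 2, 0.5)
  expect_error(solveLaplace(slab, c(nosuch = 0, epi = 1)), "unknown surface")
})

test_that("bidirectional slerp is an interpolation with sign invariance", {
  q <- varpsim:::.quatAxisAngle(c(0, 0, 1), 0.7)
  expect_equal(bislerp(q, q, 0.3), q, tolerance = 1e-12)
  # q and -q encode the same rotation: interpolation result must match
  v <- c(1, 0, 0)
  r1 <- varpsim:::.quatRotate(bislerp(q, q, 0.5), v)
  r2 <- varpsim:::.quatRotate(bislerp(q, -q, 0.5), v)
  expect_equal(r1, r2, tolerance = 1e-9)
  # coaxial rotations interpolate linearly in angle
  qa <- varpsim:::.quatAxisAngle(c(0, 0, 1), 60 * pi / 180)
  qb <- varpsim:::.quatAxisAngle(c(0, 0, 1), -60 * pi / 180)
  mid <- bislerp(qa, qb, 0.5)
  expect_equal(varpsim:::.quatRotate(mid, v), v, tolerance = 1e-9)
})

test_that("slab fibre rules produce the linear transmural helix", {
  slab <- generateSlab(6, 6, 9, 0.5)   # odd layer count: phi = 0.5 attained
  ff <- assignFibers(slab, fiberRules(60, -60))
  dirs <- fiberDirections(ff)
  expect_true(all(abs(sqrt(rowSums(dirs^2)) - 1) <= 1e-9))
  # zero rotation: all fibres along the circumferential (x) axis
  f0 <- assignFibers(slab, fiberRules(0, 0))
  expect_equal(max(abs(fiberDirections(f0)[, 2:3])), 0, tolerance = 1e-9)
  # mid-wall angle vanishes for the symmetric +-60 rule
  mid <- which(abs(ff@phi - 0.5) < 1e-9)
  expect_gt(length(mid), 0)
  expect_lt(max(abs(slabHelixAngles(ff)[mid])), 1e-6)
  # recovered helix angle matches alpha(phi) within 2 degrees everywhere
  expected <- 60 * (1 - ff@phi) - 60 * ff@phi
  expect_lt(max(abs(slabHelixAngles(ff) - expected)), 2)
  # fibre orthogonal to the transmural gradient (z on the slab)
  expect_lt(max(abs(dirs[, 3])), 1e-9)
})

test_that("default rule angles span the expected transmural range", {
  slab <- generateSlab(4, 4, 10, 0.5)
  ff <- assignFibers(slab)    # +40 endo, -50 epi
  ha <- slabHelixAngles(ff)
  expect_lt(max(ha), 40)
  expect_gt(max(ha), 30)
  expect_gt(min(ha), -50)
  expect_lt(min(ha), -40)
})

test_that("LV shell fibres are unit norm and transverse to the wall
          gradient", {
  lv <- generateLVEllipsoid(10, 30, 70, dx = 2.5)
  ff <- suppressWarnings(assignFibers(lv))
  dirs <- fiberDirections(ff)
  expect_true(all(abs(sqrt(rowSums(dirs^2)) - 1) <= 1e-9))
  phiN <- solveLaplace(lv, c(endo = 0, epi = 1))
  g <- varpsim:::.elementGradients(lv, phiN)
  gn <- sqrt(rowSums(g^2))
  ok <- gn > 0.5 * stats::median(gn)
  cosang <- abs(rowSums(dirs[ok, ] * g[ok, ] / gn[ok]))
  expect_lt(stats::quantile(cosang, 0.95), 0.2)
})

test_that("grey-zone fibre perturbation is bounded, local and
          deterministic", {
  mesh <- infarctedSheet(n = 24, dx = 0.5, rScar = 3, rim = 2)
  ff <- sheetFibersX(mesh)
  p0 <- perturbGzFibers(ff, mesh, maxAngle = 0, seed = 3)
  expect_equal(fiberDirections(p0), fiberDirections(ff))

  p1 <- perturbGzFibers(ff, mesh, maxAngle = 25, seed = 3)
  p2 <- perturbGzFibers(ff, mesh, maxAngle = 25, seed = 3)
  expect_identical(fiberDirections(p1), fiberDirections(p2))

  gz <- which(mesh@labels == 1L)
  notGz <- which(mesh@labels != 1L)
  expect_equal(fiberDirections(p1)[notGz, ],
               fiberDirections(ff)[notGz, ])
  dots <- rowSums(fiberDirections(p1)[gz, ] * fiberDirections(ff)[gz, ])
  expect_true(all(dots >= cos(25 * pi / 180) - 1e-9))
  expect_gt(max(acos(pmin(1, dots))), 0)   # something actually moved

  p3 <- perturbGzFibers(ff, mesh, maxAngle = 25, seed = 4)
  expect_false(identical(fiberDirections(p1), fiberDirections(p3)))
})
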