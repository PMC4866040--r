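test_that("CARP-style write/read round-trips nodes, labels and fibres", {
  mesh <- infarctedSheet(n = 10, dx = 0.5, rScar = 2, rim = 1)
  fib <- sheetFibersX(mesh)
  base <- file.path(withr::local_tempdir(), "m")
  writeMesh(mesh, base, fibers = fib)
  back <- readMesh(base)
  expect_equal(meshNodes(back$mesh), meshNodes(mesh), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_identical(meshElements(back$mesh), meshElements(mesh))
  expect_identical(back$mesh@labels, mesh@labels)
  expect_equal(fiberDirections(back$fibers), fiberDirections(fib),
               tolerance = 1e-8, ignore_attr = TRUE)
  # write(read(x)) == x at file level
  base2 <- file.path(withr::local_tempdir(), "m2")
  writeMesh(back$mesh, base2, fibers = back$fibers)
  expect_identical(readLines(paste0(base, ".elem")),
                   readLines(paste0(base2, ".elem")))
  expect_identical(readLines(paste0(base, ".pts")),
                   readLines(paste0(base2, ".pts")))
})

test_that("element region tags map bijectively to tissue labels", {
  mesh <- generateSheet(3, 1, 0.5)
  mesh@labels <- c(0L, 1L, 2L)
  base <- file.path(withr::local_tempdir(), "tags")
  writeMesh(mesh, base)
  tags <- vapply(strsplit(readLines(paste0(base, ".elem"))[-1], " "),
                 function(x) x[[length(x)]], "")
  expect_identical(tags, c("0", "1", "2"))
  expect_identical(readMesh(base)$mesh@labels, c(0L, 1L, 2L))
})

test_that("3D slab round-trips through hex element records", {
  slab <- generateSlab(3, 2, 2, 1)
  base <- file.path(withr::local_tempdir(), "slab")
  writeMesh(slab, base)
  back <- readMesh(base)$mesh
  expect_equal(meshNodes(back), meshNodes(slab), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_identical(meshElements(back), meshElements(slab))
})

test_that("malformed files fail with the file and line named", {
  mesh <- generateSheet(4, 4, 0.5)
  base <- file.path(withr::local_tempdir(), "bad")
  writeMesh(mesh, base)

  pts <- readLines(paste0(base, ".pts"))
  writeLines(pts[1:10], paste0(base, ".pts"))
  expect_error(readMesh(base), "pts, line 11.*truncated")

  writeLines(pts, paste0(base, ".pts"))
  el <- readLines(paste0(base, ".elem"))
  el[3] <- "Qd 0 1 999 5 0"           # out-of-range node index
  writeLines(el, paste0(base, ".elem"))
  expect_error(readMesh(base), "line 3.*out of range")
})

test_that("legacy VTK export writes a loadable cell/point structure", {
  mesh <- infarctedSheet(n = 6, dx = 0.5, rScar = 1, rim = 0.5)
  path <- file.path(withr::local_tempdir(), "m.vtk")
  writeVTK(mesh, path, pointData = list(lat = seq_len(nNodes(mesh))))
  ln <- readLines(path)
  expect_true(any(grepl("^POINTS 49 float", ln)))
  expect_true(any(grepl("^CELLS 36 180", ln)))
  expect_true(any(grepl("SCALARS tissue int", ln)))
  expect_true(any(grepl("SCALARS lat float", ln)))
})
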