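# three-level phantom: remote 100, rim 300, core 1000 (on an 8 x 8 grid)
phantom <- function(core = 1000, rim = 300, remote = 100) {
  si <- array(remote, c(8, 8, 1))
  si[3:6, 3:6, 1] <- rim
  si[4:5, 4:5, 1] <- core
  rr <- array(FALSE, dim(si)); rr[1:2, 1:2, 1] <- TRUE
  intensityVolume(si, remoteRegion = rr)
}

test_that("FWHM classification matches the constructed phantom counts", {
  lab <- fwhmClassify(phantom())
  # max SI = 1000, half max = 500, peak remote = 100:
  # core (4 voxels) >= 500 -> SCAR; rim (12 voxels) in (100, 500) -> GZ
  expect_equal(sum(lab == 2L, na.rm = TRUE), 4L)
  expect_equal(sum(lab == 1L, na.rm = TRUE), 12L)
  expect_equal(sum(lab == 0L, na.rm = TRUE), 64L - 16L)
})

test_that("uniform signal yields all NORMAL with a warning", {
  vol <- phantom(core = 100, rim = 100, remote = 100)
  expect_warning(lab <- fwhmClassify(vol), "no hyperenhancement")
  expect_true(all(lab == 0L, na.rm = TRUE))
})

test_that("the half-maximum cutoff is inclusive", {
  # core exactly at 50% of max: max = 1000 from one hottest voxel
  si <- array(100, c(8, 8, 1))
  si[3:6, 3:6, 1] <- 500
  si[4, 4, 1] <- 1000
  rr <- array(FALSE, dim(si)); rr[1:2, 1:2, 1] <- TRUE
  lab <- fwhmClassify(intensityVolume(si, remoteRegion = rr))
  expect_true(all(lab[3:6, 3:6, 1] == 2L))   # 500 >= 1000/2 is SCAR
})

test_that("classification is invariant under positive affine rescaling", {
  vol <- phantom()
  lab1 <- fwhmClassify(vol)
  for (c_ in c(0.25, 3, 1700)) {
    vol2 <- intensityVolume(vol@values * c_,
                            remoteRegion = vol@remoteRegion)
    expect_identical(fwhmClassify(vol2), lab1)
  }
})

test_that("raising a voxel's intensity never demotes its label", {
  set.seed(11)
  base <- phantom()
  lab1 <- fwhmClassify(base)
  for (k in 1:10) {
    idx <- cbind(sample(8, 1), sample(8, 1), 1)
    si2 <- base@values
    if (base@remoteRegion[idx]) next        # keep the reference fixed
    si2[idx] <- si2[idx] * runif(1, 1, 3)
    lab2 <- fwhmClassify(intensityVolume(si2,
                                         remoteRegion = base@remoteRegion))
    expect_gte(lab2[idx], lab1[idx])
  }
})

test_that("voxel labels transfer to the mesh with severity tie-breaks", {
  mesh <- generateSheet(4, 4, 1)
  # identity mapping when the grids coincide
  lab <- array(rep(c(0L, 1L, 2L, 0L), 4), c(4, 4))
  out <- labelsToMesh(lab, mesh)
  expect_identical(out@labels, as.integer(lab))

  # 2x refinement: majority vote and severity tie-break
  mesh1 <- generateSheet(1, 1, 1)
  v <- array(0L, c(2, 2))
  v[1, 1] <- 2L                              # 3 NORMAL + 1 SCAR -> NORMAL
  expect_identical(labelsToMesh(v, mesh1)@labels, 0L)
  v2 <- array(c(1L, 1L, 2L, 2L), c(2, 2))    # 2 GZ + 2 SCAR -> SCAR
  expect_identical(labelsToMesh(v2, mesh1)@labels, 2L)

  expect_error(labelsToMesh(array(0L, c(3, 3)), mesh), "integer refinement")
})

test_that("classifier plus transfer writes an annulus onto the mesh", {
  mesh <- generateSheet(8, 8, 1)
  lab <- fwhmClassify(phantom())
  out <- labelsToMesh(lab[, , 1], mesh)
  fr <- labelFractions(out)
  expect_equal(fr[["SCAR"]], 4 / 64)
  expect_equal(fr[["GZ"]], 12 / 64)
})
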