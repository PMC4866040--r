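#' @include AllClasses.R
NULL

# node index helper for structured grids (1-based)
.gridNodeId <- function(i, j, k = NULL, nx, ny) {
  if (is.null(k)) i + 1L + (nx + 1L) * j
  else i + 1L + (nx + 1L) * (j + (ny + 1L) * k)
}

#' Generate a regular 2D tissue sheet
#'
#' A regular quad grid of \code{nx} x \code{ny} elements with edge length
#' \code{dx} (mm), all elements labeled NORMAL.
#'
#' @param nx,ny element counts along x and y (>= 1).
#' @param dx element edge length in mm (default 0.35, the working
#'   resolution of the tissue models).
#' @return a \code{\link{LabeledMesh}} with \code{(nx+1)(ny+1)} nodes and
#'   \code{nx*ny} quad elements.
#' @export
#' @examples
#' sheet <- generateSheet(10, 10)
#' nNodes(sheet)     # 121
#' nElements(sheet)  # 100
generateSheet <- function(nx, ny, dx = 0.35) {
  if (nx < 1 || ny < 1) stop("element counts nx, ny must be >= 1")
  if (dx <= 0) stop("element edge dx must be positive")
  nx <- as.integer(nx); ny <- as.integer(ny)
  xs <- seq(0, nx) * dx
  ys <- seq(0, ny) * dx
  nodes <- cbind(x = rep(xs, times = ny + 1L), y = rep(ys, each = nx + 1L))
  i <- rep(seq_len(nx) - 1L, times = ny)
  j <- rep(seq_len(ny) - 1L, each = nx)
  elements <- cbind(.gridNodeId(i, j, NULL, nx, ny),
                    .gridNodeId(i + 1L, j, NULL, nx, ny),
                    .gridNodeId(i + 1L, j + 1L, NULL, nx, ny),
                    .gridNodeId(i, j + 1L, NULL, nx, ny))
  storage.mode(elements) <- "integer"
  .LabeledMesh(nodes, elements, rep(.LBL_NORMAL, nx * ny), dx,
               dims = c(nx, ny))
}

#' Generate a regular 3D tissue slab
#'
#' The 3D analogue of \code{\link{generateSheet}}: a regular hexahedral grid
#' of \code{nx} x \code{ny} x \code{nz} elements, all NORMAL.
#'
#' @param nx,ny,nz element counts (>= 1).
#' @param dx element edge length in mm.
#' @return a \code{\link{LabeledMesh}} with hex elements.
#' @export
#' @examples
#' slab <- generateSlab(10, 10, 3)
#' nNodes(slab)     # 484
#' nElements(slab)  # 300
generateSlab <- function(nx, ny, nz, dx = 0.35) {
  if (nx < 1 || ny < 1 || nz < 1) stop("element counts must be >= 1")
  if (dx <= 0) stop("element edge dx must be positive")
  nx <- as.integer(nx); ny <- as.integer(ny); nz <- as.integer(nz)
  xs <- seq(0, nx) * dx; ys <- seq(0, ny) * dx; zs <- seq(0, nz) * dx
  nodes <- cbind(x = rep(xs, times = (ny + 1L) * (nz + 1L)),
                 y = rep(rep(ys, each = nx + 1L), times = nz + 1L),
                 z = rep(zs, each = (nx + 1L) * (ny + 1L)))
  i <- rep(seq_len(nx) - 1L, times = ny * nz)
  j <- rep(rep(seq_len(ny) - 1L, each = nx), times = nz)
  k <- rep(seq_len(nz) - 1L, each = nx * ny)
  elements <- cbind(.gridNodeId(i, j, k, nx, ny),
                    .gridNodeId(i + 1L, j, k, nx, ny),
                    .gridNodeId(i + 1L, j + 1L, k, nx, ny),
                    .gridNodeId(i, j + 1L, k, nx, ny),
                    .gridNodeId(i, j, k + 1L, nx, ny),
                    .gridNodeId(i + 1L, j, k + 1L, nx, ny),
                    .gridNodeId(i + 1L, j + 1L, k + 1L, nx, ny),
                    .gridNodeId(i, j + 1L, k + 1L, nx, ny))
  storage.mode(elements) <- "integer"
  # conventional surfaces for the fibre rules: transmural across z,
  # apicobasal along y
  zc <- nodes[, 3]; yc <- nodes[, 2]
  surfaces <- list(endo = which(zc == 0), epi = which(zc == nz * dx),
                   apex = which(yc == 0), base = which(yc == ny * dx))
  .LabeledMesh(nodes, elements, rep(.LBL_NORMAL, nx * ny * nz), dx,
               surfaces = surfaces, dims = c(nx, ny, nz))
}

# element centroids (E x dim)
.elementCentroids <- function(mesh) {
  el <- mesh@elements
  d <- ncol(mesh@nodes)
  out <- matrix(0, nrow(el), d)
  for (c_ in seq_len(d)) {
    xc <- matrix(mesh@nodes[el, c_], nrow(el), ncol(el))
    out[, c_] <- rowMeans(xc)
  }
  out
}

#' Generate an idealized left-ventricular (optionally biventricular) shell
#'
#' The ventricle is a truncated-ellipsoid shell voxelized on a structured
#' hexahedral grid: elements whose centroid lies between the endocardial
#' and epicardial ellipsoid surfaces (below the basal plane z = 0) are kept.
#' With \code{withRV = TRUE} a thinner-walled partial ellipsoid, offset
#' laterally and truncated below two thirds of the apex-to-base distance,
#' is fused to the LV to provide an RV cavity surface. This is an idealized
#' stand-in for patient anatomy, sufficient for pacing-site placement and
#' fibre rules. Surfaces are identified geometrically on boundary faces:
#' \code{endo}, \code{epi}, \code{base}, \code{apex} and (with RV)
#' \code{rv_endo}.
#'
#' @param wallThickness LV wall thickness, mm.
#' @param baseRadius LV epicardial equatorial radius, mm.
#' @param apexToBase LV epicardial apex-to-base distance, mm.
#' @param dx element edge, mm.
#' @param withRV add the simplified right ventricle.
#' @return a \code{\link{LabeledMesh}} (all elements NORMAL).
#' @export
#' @examples
#' lv <- generateLVEllipsoid(10, 30, 70, dx = 2)
#' names(meshSurfaces(lv))
generateLVEllipsoid <- function(wallThickness, baseRadius, apexToBase,
                                dx = 0.35, withRV = FALSE) {
  if (wallThickness <= 0 || baseRadius <= 0 || apexToBase <= 0 || dx <= 0)
    stop("geometric parameters must be positive")
  if (wallThickness >= baseRadius)
    stop("wall thickness must be smaller than the base radius")
  if (wallThickness < 3 * dx)
    stop("wall too thin for the requested resolution: fewer than 3 ",
         "elements transmurally; decrease dx or thicken the wall")

  aEpi <- baseRadius; cEpi <- apexToBase
  aEndo <- baseRadius - wallThickness
  cEndo <- apexToBase - wallThickness

  # RV: thinner partial shell, offset along +x, truncated below the apex
  rvWall <- max(wallThickness / 3, 3 * dx)
  aRvEpi <- 0.9 * baseRadius; cRvEpi <- 0.75 * apexToBase
  rvOffset <- 0.9 * baseRadius
  aRvEndo <- aRvEpi - rvWall; cRvEndo <- cRvEpi - rvWall

  ex <- function(p, a, c_, x0 = 0)
    ((p[, 1] - x0) / a)^2 + (p[, 2] / a)^2 + (p[, 3] / c_)^2

  xmax <- if (withRV) rvOffset + aRvEpi else aEpi
  nx <- ceiling((xmax + aEpi) / dx)
  ny <- ceiling(2 * aEpi / dx)
  nz <- ceiling(cEpi / dx)
  slab <- generateSlab(nx, ny, nz, dx)
  # shift so the LV is centred at the origin with the base at z = 0
  nodes <- sweep(slab@nodes, 2, c(aEpi, aEpi, nz * dx), "-")

  el <- slab@elements
  cent <- .elementCentroids(.LabeledMesh(nodes, el, slab@labels, dx))
  inLVwall <- ex(cent, aEpi, cEpi) <= 1 & ex(cent, aEndo, cEndo) >= 1 &
    cent[, 3] <= 0
  keep <- inLVwall
  inRVwall <- rep(FALSE, nrow(cent))
  if (withRV) {
    inRVwall <- ex(cent, aRvEpi, cRvEpi, rvOffset) <= 1 &
      ex(cent, aRvEndo, cRvEndo, rvOffset) >= 1 &
      cent[, 3] <= 0 & cent[, 3] >= -2 / 3 * cEpi &
      ex(cent, aEndo, cEndo) >= 1       # never intrude into the LV cavity
    keep <- keep | inRVwall
  }
  if (!any(keep)) stop("degenerate ventricular geometry: empty wall")

  elKeep <- el[keep, , drop = FALSE]
  usedNodes <- sort(unique(as.vector(elKeep)))
  remap <- integer(nrow(nodes)); remap[usedNodes] <- seq_along(usedNodes)
  elKeep[] <- remap[elKeep]
  nodesKeep <- nodes[usedNodes, , drop = FALSE]

  mesh <- .LabeledMesh(nodesKeep, elKeep,
                       rep(.LBL_NORMAL, nrow(elKeep)), dx)

  # boundary faces: faces that belong to exactly one kept element
  faces <- .hexBoundaryFaces(elKeep)
  fc <- (nodesKeep[faces[, 1], ] + nodesKeep[faces[, 2], ] +
         nodesKeep[faces[, 3], ] + nodesKeep[faces[, 4], ]) / 4
  eEndo <- ex(fc, aEndo, cEndo)
  eEpi <- ex(fc, aEpi, cEpi)
  isBase <- abs(fc[, 3]) < dx / 2
  cls <- ifelse(isBase, "base",
                ifelse(abs(eEndo - 1) < abs(eEpi - 1), "endo", "epi"))
  if (withRV) {
    eRvEndo <- ex(fc, aRvEndo, cRvEndo, rvOffset)
    eRvEpi <- ex(fc, aRvEpi, cRvEpi, rvOffset)
    # faces nearer the RV surfaces than either LV surface
    dLv <- pmin(abs(eEndo - 1), abs(eEpi - 1))
    dRv <- pmin(abs(eRvEndo - 1), abs(eRvEpi - 1))
    rvSide <- fc[, 1] > aEndo * 0.7 & dRv < dLv & !isBase
    cls[rvSide] <- ifelse(abs(eRvEndo - 1)[rvSide] < abs(eRvEpi - 1)[rvSide],
                          "rv_endo", "epi")
  }
  surf <- lapply(split(seq_len(nrow(faces)), cls), function(idx)
    sort(unique(as.vector(faces[idx, , drop = FALSE]))))
  # enforce disjoint endo/epi (corner nodes go to endo)
  if (!is.null(surf$epi) && !is.null(surf$endo))
    surf$epi <- setdiff(surf$epi, surf$endo)
  if (!is.null(surf$rv_endo)) {
    surf$rv_endo <- setdiff(surf$rv_endo, c(surf$endo, surf$epi))
    if (!length(surf$rv_endo)) surf$rv_endo <- NULL
  }
  # apex anchor: epicardial node closest to the apex pole (0, 0, -cEpi)
  epiN <- surf$epi
  apexDist <- rowSums(sweep(nodesKeep[epiN, , drop = FALSE], 2,
                            c(0, 0, -cEpi), "-")^2)
  surf$apex <- epiN[which.min(apexDist)]
  mesh@surfaces <- surf
  validObject(mesh)
  mesh
}

# boundary (free) faces of a hex mesh; returns a matrix of 4 node columns
.hexBoundaryFaces <- function(el) {
  # local faces of the hexahedron in the node ordering used by generateSlab
  lf <- rbind(c(1, 2, 3, 4), c(5, 6, 7, 8), c(1, 2, 6, 5),
              c(4, 3, 7, 8), c(1, 4, 8, 5), c(2, 3, 7, 6))
  fa <- do.call(rbind, lapply(seq_len(nrow(lf)), function(f)
    el[, lf[f, ], drop = FALSE]))
  key <- apply(fa, 1L, function(r) paste(sort(r), collapse = "-"))
  fa[key %in% names(which(table(key) == 1L)), , drop = FALSE]
}

#' Superimpose an infarct (scar + grey-zone rim + optional isthmus)
#'
#' Elements whose centroid falls inside the ellipsoidal scar footprint are
#' labeled SCAR; elements within the grey-zone rim (the footprint grown by
#' \code{gzRimWidth} on every semi-axis) are labeled GZ; an optional
#' conducting isthmus channel re-labels infarct elements within a straight
#' slab across the scar. Labels outside the footprint are untouched.
#'
#' @param mesh a \code{\link{LabeledMesh}}.
#' @param spec an \code{\link{InfarctSpec}}.
#' @return the relabeled \code{LabeledMesh}. If the footprint does not
#'   intersect the mesh a warning is raised and the mesh is returned
#'   unchanged.
#' @export
#' @examples
#' sheet <- generateSheet(40, 40, 0.5)
#' inf <- addInfarct(sheet, infarctSpec(c(10, 10), c(5, 5), gzRimWidth = 2))
#' labelFractions(inf)
addInfarct <- function(mesh, spec) {
  stopifnot(is(mesh, "LabeledMesh"), is(spec, "InfarctSpec"))
  d <- ncol(mesh@nodes)
  if (length(spec@center) != d)
    stop("infarct centre dimension does not match the mesh")
  cent <- .elementCentroids(mesh)
  rel <- sweep(cent, 2, spec@center, "-")
  inScar <- rowSums(sweep(rel, 2, spec@radii, "/")^2) <= 1
  rimR <- spec@radii + spec@gzRimWidth
  inRim <- rowSums(sweep(rel, 2, rimR, "/")^2) <= 1 & !inScar
  if (!any(inScar | inRim)) {
    warning("infarct footprint does not intersect the mesh; mesh unchanged")
    return(mesh)
  }
  labels <- mesh@labels
  labels[inScar] <- .LBL_SCAR
  if (spec@gzRimWidth > 0) labels[inRim] <- .LBL_GZ
  if (length(spec@isthmus)) {
    it <- spec@isthmus
    inChan <- abs(cent[, it$axis] - it$center) <= it$width / 2
    chan <- inChan & (inScar | inRim)
    labels[chan] <- if (it$label == "NORMAL") .LBL_NORMAL else .LBL_GZ
  }
  mesh@labels <- labels
  validObject(mesh)
  mesh
}
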