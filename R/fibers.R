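#' @include AllClasses.R fem.R
NULL

#' Solve a Laplace-Dirichlet problem on a mesh
#'
#' Computes the discrete harmonic field with fixed values on named surface
#' node sets; used to define the transmural and apicobasal coordinates of
#' the rule-based fibre method. The discrete maximum principle holds: the
#' solution attains its extrema on the Dirichlet sets.
#'
#' @param mesh a \code{\link{LabeledMesh}} with named surfaces.
#' @param dirichlet named numeric vector mapping surface names to boundary
#'   values, e.g. \code{c(endo = 0, epi = 1)}; alternatively a list of
#'   \code{list(nodes =, value =)} entries with explicit node indices.
#' @return numeric per-node field.
#' @export
#' @examples
#' slab <- generateSlab(4, 4, 4, 1)
#' phi <- solveLaplace(slab, c(endo = 0, epi = 1))
#' range(phi)
solveLaplace <- function(mesh, dirichlet) {
  stopifnot(is(mesh, "LabeledMesh"))
  if (is.numeric(dirichlet)) {
    missing <- setdiff(names(dirichlet), names(mesh@surfaces))
    if (length(missing))
      stop("unknown surface(s): ", paste(missing, collapse = ", "))
    sets <- lapply(names(dirichlet),
                   function(nm) list(nodes = mesh@surfaces[[nm]],
                                     value = dirichlet[[nm]]))
  } else sets <- dirichlet
  if (length(sets) < 1L || !all(lengths(lapply(sets, `[[`, "nodes")) > 0))
    stop("at least one non-empty Dirichlet set is required")

  n <- nNodes(mesh)
  fixed <- integer(0); vals <- numeric(0)
  for (s in sets) {
    fixed <- c(fixed, s$nodes)
    vals <- c(vals, rep(s$value, length(s$nodes)))
  }
  if (anyDuplicated(fixed)) {
    dup <- duplicated(fixed)
    fixed <- fixed[!dup]; vals <- vals[!dup]
  }
  d <- ncol(mesh@nodes)
  Dcomp <- matrix(0, nElements(mesh), d + choose(d, 2))
  Dcomp[, seq_len(d)] <- 1     # isotropic unit tensor
  K <- .assembleStiffness(mesh, Dcomp)
  # every node must be reachable from a Dirichlet node, otherwise the
  # harmonic extension is undefined on the unreached component
  reached <- numeric(n); reached[fixed] <- 1
  P <- abs(K)
  repeat {
    nxt <- as.numeric(P %*% reached > 0 | reached > 0)
    if (identical(nxt, reached)) break
    reached <- nxt
  }
  if (any(reached == 0))
    stop("Laplace system is singular: the mesh has a connected ",
         "component with no Dirichlet boundary condition", call. = FALSE)
  free <- setdiff(seq_len(n), fixed)
  u <- numeric(n)
  u[fixed] <- vals
  if (length(free)) {
    rhs <- -K[free, fixed, drop = FALSE] %*% vals
    sol <- tryCatch(
      Matrix::solve(K[free, free], rhs),
      error = function(e)
        stop("Laplace system is singular: the mesh has a connected ",
             "component with no Dirichlet boundary condition", call. = FALSE))
    u[free] <- as.numeric(sol)
    # a singular block can also "solve" to non-finite values
    if (any(!is.finite(u)))
      stop("Laplace system is singular: the mesh has a connected ",
           "component with no Dirichlet boundary condition", call. = FALSE)
  }
  u
}

# quaternion helpers (w, x, y, z)
.quatAxisAngle <- function(axis, angleRad) {
  c(cos(angleRad / 2), sin(angleRad / 2) * axis)
}

.quatRotate <- function(q, v) {
  w <- q[1]; u <- q[2:4]
  2 * sum(u * v) * u + (w^2 - sum(u * u)) * v + 2 * w * .cross3(u, v)
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Bidirectional spherical linear interpolation of two rotations
#'
#' Slerp between unit quaternions treating q and -q as the same rotation:
#' the sign of \code{qb} is flipped when the quaternion dot product is
#' negative so interpolation always follows the shorter arc.
#'
#' @param qa,qb unit quaternions (w, x, y, z).
#' @param t interpolation parameter in [0, 1].
#' @return a unit quaternion.
#' @export
bislerp <- function(qa, qb, t) {
  d <- sum(qa * qb)
  if (d < 0) { qb <- -qb; d <- -d }
  if (d > 1 - 1e-12) {
    q <- (1 - t) * qa + t * qb
    return(q / sqrt(sum(q^2)))
  }
  th <- acos(min(1, d))
  (sin((1 - t) * th) * qa + sin(t * th) * qb) / sin(th)
}

#' Assign per-element fibre orientations
#'
#' For ventricular geometries (and slabs, whose conventional surfaces make
#' z transmural and y apicobasal) the rule-based method is used: transmural
#' (endo = 0, epi = 1) and apicobasal Laplace-Dirichlet fields define a
#' local orthonormal frame per element (transmural axis from the gradient
#' of phi, apicobasal axis orthogonalized against it, circumferential axis
#' as their cross product); the fibre is the circumferential axis rotated
#' about the transmural axis by the helix angle interpolated between the
#' endocardial and epicardial rule angles, with the two surface rotations
#' combined by bidirectional spherical linear interpolation at the
#' element's transmural coordinate. For 2D sheets (or when
#' \code{constantDirection} is given) a constant unit direction is
#' assigned.
#'
#' Elements with a degenerate (near-zero) transmural gradient fall back to
#' the average frame of their valid face-neighbours, with a warning.
#'
#' @param mesh a \code{\link{LabeledMesh}}.
#' @param rules a \code{\link{fiberRules}} object.
#' @param constantDirection optional unit vector; assigns this direction to
#'   every element (the 2D-sheet path).
#' @return a \code{\link{FiberField}}.
#' @export
#' @examples
#' slab <- generateSlab(4, 4, 6, 0.5)
#' ff <- assignFibers(slab, fiberRules(60, -60))
#' range(sqrt(rowSums(fiberDirections(ff)^2)))
assignFibers <- function(mesh, rules = fiberRules(),
                         constantDirection = NULL) {
  stopifnot(is(mesh, "LabeledMesh"))
  nE <- nElements(mesh)
  d <- ncol(mesh@nodes)
  if (!is.null(constantDirection)) {
    v <- constantDirection / sqrt(sum(constantDirection^2))
    dirs <- matrix(rep(v, each = nE), nE, d)
    return(new("FiberField", directions = dirs,
               phi = rep(NA_real_, nE), psi = rep(NA_real_, nE)))
  }
  if (d == 2L)
    return(assignFibers(mesh, constantDirection = c(1, 0)))
  need <- c("endo", "epi", "apex", "base")
  if (!all(need %in% names(mesh@surfaces)))
    stop("rule-based fibres require surfaces endo/epi/apex/base; ",
         "pass constantDirection for simple geometries")

  phiN <- solveLaplace(mesh, c(endo = 0, epi = 1))
  psiN <- solveLaplace(mesh, c(apex = 0, base = 1))
  el <- mesh@elements
  phi <- rowMeans(matrix(phiN[el], nrow(el)))
  psi <- rowMeans(matrix(psiN[el], nrow(el)))
  gphi <- .elementGradients(mesh, phiN)
  gpsi <- .elementGradients(mesh, psiN)

  aE <- rules@alphaEndo * pi / 180
  aP <- rules@alphaEpi * pi / 180

  dirs <- matrix(NA_real_, nE, 3L)
  gnorm <- sqrt(rowSums(gphi^2))
  degenerate <- gnorm < 1e-8 * max(gnorm)
  for (e in which(!degenerate)) {
    et <- gphi[e, ] / gnorm[e]
    ea <- gpsi[e, ] - sum(gpsi[e, ] * et) * et
    na <- sqrt(sum(ea^2))
    if (na < 1e-12) { degenerate[e] <- TRUE; next }
    ea <- ea / na
    ec <- .cross3(ea, et)
    qa <- .quatAxisAngle(et, aE)
    qb <- .quatAxisAngle(et, aP)
    q <- bislerp(qa, qb, min(1, max(0, phi[e])))
    f <- .quatRotate(q, ec)
    dirs[e, ] <- f / sqrt(sum(f^2))
  }
  if (any(degenerate)) {
    warning(sum(degenerate), " element(s) with a degenerate transmural ",
            "gradient; using neighbour-averaged directions")
    nb <- .elementNeighbours(mesh)
    for (e in which(degenerate)) {
      cand <- dirs[nb[[e]], , drop = FALSE]
      cand <- cand[stats::complete.cases(cand), , drop = FALSE]
      v <- if (nrow(cand)) colMeans(cand) else c(1, 0, 0)
      if (sqrt(sum(v^2)) < 1e-12) v <- c(1, 0, 0)
      dirs[e, ] <- v / sqrt(sum(v^2))
    }
  }
  new("FiberField", directions = dirs,
      phi = pmin(1, pmax(0, phi)), psi = pmin(1, pmax(0, psi)))
}

# face-sharing element neighbours via shared nodes (>= nodes per face)
.elementNeighbours <- function(mesh) {
  el <- mesh@elements
  nen <- ncol(el)
  faceN <- if (nen == 4L) 2L else 4L
  byNode <- split(rep(seq_len(nrow(el)), nen), as.vector(el))
  nb <- vector("list", nrow(el))
  for (e in seq_len(nrow(el))) {
    cand <- unlist(byNode[as.character(el[e, ])], use.names = FALSE)
    tab <- table(cand)
    nb[[e]] <- as.integer(names(tab)[tab >= faceN & names(tab) != e])
  }
  nb
}

#' Randomly perturb grey-zone fibre orientations
#'
#' Rotates the fibre of every GZ element by a uniform random angle up to
#' \code{maxAngle} degrees about a random axis (in-plane rotation for 2D
#' meshes); NORMAL and SCAR elements are untouched. Deterministic for a
#' fixed seed. Used for robustness analyses of the inducibility call under
#' fibre-orientation uncertainty in the border zone.
#'
#' @param field a \code{\link{FiberField}}.
#' @param mesh the matching \code{\link{LabeledMesh}}.
#' @param maxAngle maximum rotation angle, degrees.
#' @param seed RNG seed.
#' @return the perturbed \code{FiberField}.
#' @export
perturbGzFibers <- function(field, mesh, maxAngle = 25, seed = 1L) {
  stopifnot(is(field, "FiberField"), is(mesh, "LabeledMesh"))
  gz <- which(mesh@labels == .LBL_GZ)
  if (!length(gz)) return(field)
  dirs <- field@directions
  d <- ncol(dirs)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  ang <- runif(length(gz), 0, maxAngle) * pi / 180
  if (d == 2L) {
    sgn <- sample(c(-1, 1), length(gz), replace = TRUE)
    a <- ang * sgn
    dirs[gz, ] <- cbind(cos(a) * dirs[gz, 1] - sin(a) * dirs[gz, 2],
                        sin(a) * dirs[gz, 1] + cos(a) * dirs[gz, 2])
  } else {
    for (k in seq_along(gz)) {
      ax <- stats::rnorm(3)
      ax <- ax / sqrt(sum(ax^2))
      q <- .quatAxisAngle(ax, ang[k])
      v <- .quatRotate(q, dirs[gz[k], ])
      dirs[gz[k], ] <- v / sqrt(sum(v^2))
    }
  }
  field@directions <- dirs
  validObject(field)
  field
}

#' Helix angle of an assigned fibre field on a slab benchmark
#'
#' Recovers the per-element helix angle (degrees) of a fibre field with
#' respect to the local frame implied by the slab convention (z transmural,
#' y apicobasal, x circumferential); used to verify the transmural
#' helix-angle rule.
#'
#' @param field a \code{\link{FiberField}} on a slab mesh.
#' @return numeric vector of angles in degrees.
#' @export
slabHelixAngles <- function(field) {
  f <- field@directions
  stopifnot(ncol(f) == 3L)
  atan2(f[, 2], f[, 1]) * 180 / pi
}
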