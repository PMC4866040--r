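#' @include AllClasses.R
NULL

# Finite-element machinery for the structured quad/hex grids.
# All elements are congruent axis-aligned squares/cubes of edge h, so the
# reference integrals of shape-function derivative products are computed
# once (Gauss quadrature) and element stiffness matrices are linear
# combinations weighted by the element's diffusion-tensor components.

# signs of the reference nodes, matching the connectivity ordering of
# generateSheet / generateSlab
.refSigns <- function(d) {
  if (d == 2L)
    rbind(c(-1, -1), c(1, -1), c(1, 1), c(-1, 1))
  else
    rbind(c(-1, -1, -1), c(1, -1, -1), c(1, 1, -1), c(-1, 1, -1),
          c(-1, -1, 1), c(1, -1, 1), c(1, 1, 1), c(-1, 1, 1))
}

# shape functions and derivatives at reference point xi (in [-1,1]^d)
.shapeDeriv <- function(xi, d) {
  s <- .refSigns(d)
  nen <- nrow(s)
  B <- matrix(0, d, nen)
  for (i in seq_len(nen)) {
    terms <- (1 + s[i, ] * xi) / 2
    for (a in seq_len(d)) {
      pr <- prod(terms[-a])
      B[a, i] <- s[i, a] / 2 * pr
    }
  }
  B
}

# reference matrices S_ab[i,j] = int dNi/da dNj/db over the element of
# edge h, symmetrized for off-diagonal tensor components
.femRefMats <- function(d, h) {
  g <- 1 / sqrt(3)
  pts <- as.matrix(expand.grid(rep(list(c(-g, g)), d)))
  nen <- if (d == 2L) 4L else 8L
  S <- vector("list", d * d)
  dim(S) <- c(d, d)
  for (a in seq_len(d)) for (b in seq_len(d))
    S[[a, b]] <- matrix(0, nen, nen)
  jac <- (h / 2)^d          # volume scale
  dscale <- 2 / h           # d/dx = (2/h) d/dxi
  for (q in seq_len(nrow(pts))) {
    B <- .shapeDeriv(pts[q, ], d) * dscale
    for (a in seq_len(d)) for (b in seq_len(d))
      S[[a, b]] <- S[[a, b]] + jac * (B[a, ] %o% B[b, ])
  }
  S
}

# Assemble the global stiffness matrix sum_e int grad Ni . D_e grad Nj
# over the given elements. Dcomp: matrix with one row per used element and
# columns (xx, yy[, zz], xy[, xz, yz]).
.assembleStiffness <- function(mesh, Dcomp, elems = seq_len(nElements(mesh))) {
  d <- ncol(mesh@nodes)
  nen <- ncol(mesh@elements)
  S <- .femRefMats(d, mesh@resolution)
  el <- mesh@elements[elems, , drop = FALSE]
  pairsDiag <- seq_len(d)
  offPairs <- if (d == 2L) list(c(1L, 2L)) else
    list(c(1L, 2L), c(1L, 3L), c(2L, 3L))
  nE <- nrow(el)
  ii <- jj <- integer(nE * nen * nen)
  xx <- numeric(nE * nen * nen)
  pos <- 0L
  for (i in seq_len(nen)) for (j in seq_len(nen)) {
    val <- numeric(nE)
    for (a in pairsDiag)
      val <- val + Dcomp[, a] * S[[a, a]][i, j]
    for (pidx in seq_along(offPairs)) {
      a <- offPairs[[pidx]][1]; b <- offPairs[[pidx]][2]
      val <- val + Dcomp[, d + pidx] * (S[[a, b]][i, j] + S[[b, a]][i, j])
    }
    idx <- pos + seq_len(nE)
    ii[idx] <- el[, i]; jj[idx] <- el[, j]; xx[idx] <- val
    pos <- pos + nE
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = c(nNodes(mesh), nNodes(mesh)))
}

# lumped mass (row-sum) per node over the given elements, units mm^d
.lumpedMass <- function(mesh, elems = seq_len(nElements(mesh))) {
  nen <- ncol(mesh@elements)
  vol <- mesh@resolution^ncol(mesh@nodes) / nen
  el <- mesh@elements[elems, , drop = FALSE]
  m <- numeric(nNodes(mesh))
  tab <- tabulate(as.vector(el), nbins = nNodes(mesh))
  m + tab * vol
}

# per-element diffusion-tensor components D = Dt I + (Dl - Dt) f f^T,
# rows ordered like .assembleStiffness expects
.tensorComponents <- function(fibers, Dl, Dt) {
  f <- fibers
  d <- ncol(f)
  if (d == 2L) {
    cbind(Dt + (Dl - Dt) * f[, 1]^2,
          Dt + (Dl - Dt) * f[, 2]^2,
          (Dl - Dt) * f[, 1] * f[, 2])
  } else {
    cbind(Dt + (Dl - Dt) * f[, 1]^2,
          Dt + (Dl - Dt) * f[, 2]^2,
          Dt + (Dl - Dt) * f[, 3]^2,
          (Dl - Dt) * f[, 1] * f[, 2],
          (Dl - Dt) * f[, 1] * f[, 3],
          (Dl - Dt) * f[, 2] * f[, 3])
  }
}

# FEM gradient of a nodal field at element centres (E x d)
.elementGradients <- function(mesh, nodal) {
  d <- ncol(mesh@nodes)
  B0 <- .shapeDeriv(rep(0, d), d) * (2 / mesh@resolution)
  el <- mesh@elements
  out <- matrix(0, nrow(el), d)
  for (a in seq_len(d)) {
    acc <- numeric(nrow(el))
    for (i in seq_len(ncol(el)))
      acc <- acc + B0[a, i] * nodal[el[, i]]
    out[, a] <- acc
  }
  out
}
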