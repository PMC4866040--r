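#' @include AllClasses.R
NULL

# On disk the CARP-style dialect is followed: .pts coordinates in
# micrometres, .elem with 0-based node indices and a region tag
# (0 NORMAL, 1 GZ, 2 SCAR), .lon with one unit vector per element after a
# leading "1" header. In memory everything is mm and 1-based.

.ioStop <- function(path, line, fmt, ...) {
  stop(sprintf("%s, line %d: %s", path, line, sprintf(fmt, ...)),
       call. = FALSE)
}

#' Write a mesh (and optional fibre field) in CARP-style text formats
#'
#' Writes \code{<base>.pts} (node coordinates in micrometres after a count
#' header), \code{<base>.elem} (element connectivity, 0-based, with the
#' tissue label as region tag) and, when \code{fibers} is given,
#' \code{<base>.lon}.
#'
#' @param mesh a \code{\link{LabeledMesh}}.
#' @param basePath path prefix; the three files get their extensions
#'   appended.
#' @param fibers optional \code{\link{FiberField}}.
#' @return invisibly, the paths written.
#' @export
writeMesh <- function(mesh, basePath, fibers = NULL) {
  stopifnot(is(mesh, "LabeledMesh"))
  d <- ncol(mesh@nodes)
  pts <- paste0(basePath, ".pts")
  um <- mesh@nodes * 1000
  if (d == 2L) um <- cbind(um, 0)
  con <- file(pts, "w")
  writeLines(as.character(nrow(um)), con)
  writeLines(sprintf("%.4f %.4f %.4f", um[, 1], um[, 2], um[, 3]), con)
  close(con)

  elem <- paste0(basePath, ".elem")
  el0 <- mesh@elements - 1L
  tag <- if (ncol(mesh@elements) == 4L) "Qd" else "Hx"
  con <- file(elem, "w")
  writeLines(as.character(nrow(el0)), con)
  writeLines(paste(tag, apply(el0, 1L, paste, collapse = " "),
                   mesh@labels), con)
  close(con)

  paths <- c(pts, elem)
  if (!is.null(fibers)) {
    stopifnot(is(fibers, "FiberField"))
    lon <- paste0(basePath, ".lon")
    dir <- fibers@directions
    if (ncol(dir) == 2L) dir <- cbind(dir, 0)
    con <- file(lon, "w")
    writeLines("1", con)
    writeLines(sprintf("%.9f %.9f %.9f", dir[, 1], dir[, 2], dir[, 3]), con)
    close(con)
    paths <- c(paths, lon)
  }
  invisible(paths)
}

#' Read a mesh (and optional fibre field) from CARP-style text files
#'
#' @param basePath path prefix of \code{.pts} / \code{.elem} (and optional
#'   \code{.lon}) files.
#' @param resolution element edge length in mm; when \code{NULL} it is
#'   estimated from the first element's first edge.
#' @return a list with components \code{mesh} (a
#'   \code{\link{LabeledMesh}}) and \code{fibers} (a
#'   \code{\link{FiberField}} or NULL).
#' @export
readMesh <- function(basePath, resolution = NULL) {
  pts <- paste0(basePath, ".pts")
  elem <- paste0(basePath, ".elem")

  ln <- readLines(pts)
  if (!length(ln)) .ioStop(pts, 1L, "empty file")
  n <- suppressWarnings(as.integer(ln[1]))
  if (is.na(n)) .ioStop(pts, 1L, "expected a node count header")
  if (length(ln) < n + 1L)
    .ioStop(pts, length(ln) + 1L,
            "file truncated: header declares %d nodes, found %d",
            n, length(ln) - 1L)
  co <- utils::read.table(text = ln[2:(n + 1L)],
                          col.names = c("x", "y", "z"))
  nodes <- as.matrix(co) / 1000

  ln <- readLines(elem)
  if (!length(ln)) .ioStop(elem, 1L, "empty file")
  ne <- suppressWarnings(as.integer(ln[1]))
  if (is.na(ne)) .ioStop(elem, 1L, "expected an element count header")
  if (length(ln) < ne + 1L)
    .ioStop(elem, length(ln) + 1L,
            "file truncated: header declares %d elements, found %d",
            ne, length(ln) - 1L)
  toks <- strsplit(trimws(ln[2:(ne + 1L)]), "\\s+")
  kinds <- vapply(toks, `[[`, "", 1L)
  nn <- ifelse(kinds == "Qd", 4L, ifelse(kinds == "Hx", 8L, NA_integer_))
  if (anyNA(nn))
    .ioStop(elem, which(is.na(nn))[1] + 1L,
            "unsupported element kind '%s'", kinds[which(is.na(nn))[1]])
  if (length(unique(nn)) != 1L)
    .ioStop(elem, 2L, "mixed element kinds are not supported")
  want <- nn[1] + 2L
  bad <- which(lengths(toks) != want)
  if (length(bad))
    .ioStop(elem, bad[1] + 1L, "expected %d fields, found %d",
            want, length(toks[[bad[1]]]))
  num <- matrix(as.integer(unlist(lapply(toks, `[`, -1L))),
                ncol = nn[1] + 1L, byrow = TRUE)
  el <- num[, seq_len(nn[1]), drop = FALSE] + 1L
  labels <- num[, nn[1] + 1L]
  if (any(el < 1L) || any(el > nrow(nodes))) {
    bad <- which(rowSums(el < 1L | el > nrow(nodes)) > 0)[1]
    .ioStop(elem, bad + 1L, "node index out of range")
  }
  if (!all(labels %in% 0:2))
    .ioStop(elem, which(!labels %in% 0:2)[1] + 1L,
            "region tag must be 0 (NORMAL), 1 (GZ) or 2 (SCAR)")

  is2d <- all(nodes[, 3] == 0) && nn[1] == 4L
  if (is2d) nodes <- nodes[, 1:2, drop = FALSE]
  if (is.null(resolution))
    resolution <- sqrt(sum((nodes[el[1, 2], ] - nodes[el[1, 1], ])^2))
  mesh <- .LabeledMesh(nodes, el, labels, resolution)

  fib <- NULL
  lon <- paste0(basePath, ".lon")
  if (file.exists(lon)) {
    ln <- readLines(lon)
    if (length(ln) < ne + 1L)
      .ioStop(lon, length(ln) + 1L,
              "file truncated: expected %d fibre vectors", ne)
    v <- utils::read.table(text = ln[2:(ne + 1L)],
                           col.names = c("x", "y", "z"))
    dir <- as.matrix(v)
    if (is2d) dir <- dir[, 1:2, drop = FALSE]
    dir <- dir / sqrt(rowSums(dir^2))
    fib <- new("FiberField", directions = dir,
               phi = rep(NA_real_, ne), psi = rep(NA_real_, ne))
  }
  list(mesh = mesh, fibers = fib)
}

#' Export a mesh to a legacy-VTK unstructured grid for visualization
#'
#' Writes tissue labels as cell data and optional named per-node scalar
#' fields (for example an activation map) as point data.
#'
#' @param mesh a \code{\link{LabeledMesh}}.
#' @param path output file path.
#' @param pointData optional named list of per-node numeric vectors.
#' @return invisibly, \code{path}.
#' @export
writeVTK <- function(mesh, path, pointData = list()) {
  stopifnot(is(mesh, "LabeledMesh"))
  nd <- mesh@nodes
  if (ncol(nd) == 2L) nd <- cbind(nd, 0)
  el <- mesh@elements - 1L
  npe <- ncol(el)
  ctype <- if (npe == 4L) 9L else 12L   # VTK_QUAD / VTK_HEXAHEDRON
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "tissue model", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d float", nrow(nd))), con)
  writeLines(sprintf("%g %g %g", nd[, 1], nd[, 2], nd[, 3]), con)
  writeLines(sprintf("CELLS %d %d", nrow(el), nrow(el) * (npe + 1L)), con)
  writeLines(paste(npe, apply(el, 1L, paste, collapse = " ")), con)
  writeLines(sprintf("CELL_TYPES %d", nrow(el)), con)
  writeLines(as.character(rep(ctype, nrow(el))), con)
  writeLines(sprintf("CELL_DATA %d", nrow(el)), con)
  writeLines(c("SCALARS tissue int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(mesh@labels), con)
  if (length(pointData)) {
    writeLines(sprintf("POINT_DATA %d", nrow(nd)), con)
    for (nm in names(pointData)) {
      writeLines(c(sprintf("SCALARS %s float 1", nm),
                   "LOOKUP_TABLE default"), con)
      writeLines(sprintf("%g", pointData[[nm]]), con)
    }
  }
  invisible(path)
}
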