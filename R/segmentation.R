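#' @include AllClasses.R
NULL

#' Full-width-at-half-maximum tissue classification
#'
#' Classifies a signal-intensity volume into NORMAL / GZ / SCAR. The
#' hyperenhanced region is the set of myocardial voxels with signal
#' intensity above the peak intensity of the remote (known non-infarcted)
#' reference region; scar is every voxel at or above 50 percent of the
#' maximum intensity of the hyperenhanced region (the half-maximum cutoff
#' is inclusive); grey zone is the remaining hyperenhanced tissue; all
#' other myocardial voxels are NORMAL. Because both thresholds are relative
#' the classification is invariant under positive rescaling of the signal.
#'
#' @param vol an \code{\link{IntensityVolume}}.
#' @param medianFilter apply a 3x3(x3) median pre-filter to the signal
#'   before thresholding (default FALSE).
#' @return integer array of label codes (0 NORMAL, 1 GZ, 2 SCAR) with the
#'   dimensions of the volume; non-myocardial voxels are NA.
#' @export
#' @examples
#' si <- array(100, c(8, 8, 1))
#' si[5:7, 5:7, 1] <- 1000                      # core
#' si[4, 4:7, 1] <- 300                         # rim
#' remote <- array(FALSE, dim(si)); remote[1:2, 1:2, 1] <- TRUE
#' lab <- fwhmClassify(intensityVolume(si, remoteRegion = remote))
#' table(tissueLabelFactor(lab[!is.na(lab)]))
fwhmClassify <- function(vol, medianFilter = FALSE) {
  stopifnot(is(vol, "IntensityVolume"))
  if (!any(vol@remoteRegion)) stop("remote reference region is empty")
  si <- vol@values
  if (medianFilter) si <- .medianFilter(si, vol@myocardiumMask)
  mask <- vol@myocardiumMask
  peakRemote <- max(si[vol@remoteRegion])
  lab <- array(NA_integer_, dim(si))
  lab[mask] <- .LBL_NORMAL
  hyper <- mask & si > peakRemote
  if (!any(hyper)) {
    warning("no hyperenhancement above the remote reference; all NORMAL")
    return(lab)
  }
  simax <- max(si[hyper])
  lab[hyper] <- .LBL_GZ
  lab[mask & si >= simax / 2 & hyper] <- .LBL_SCAR
  lab
}

# separable-window median filter (3 voxels per in-use dimension)
.medianFilter <- function(si, mask) {
  dm <- dim(si)
  out <- si
  idx <- which(mask, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    lo <- pmax(idx[r, ] - 1L, 1L)
    hi <- pmin(idx[r, ] + 1L, dm)
    block <- do.call(`[`, c(list(si), Map(seq, lo, hi)))
    out[matrix(idx[r, ], 1L)] <- stats::median(block)
  }
  out
}

#' Transfer voxel labels onto a mesh
#'
#' Assigns each element the majority label of the voxels covering it; ties
#' are broken toward the more severe label (SCAR > GZ > NORMAL). The voxel
#' grid must be co-registered with the structured element grid: identical,
#' or finer by an integer factor per dimension.
#'
#' @param labels integer label array from \code{\link{fwhmClassify}}.
#' @param mesh a structured-grid \code{\link{LabeledMesh}} (as produced by
#'   \code{\link{generateSheet}} / \code{\link{generateSlab}}).
#' @return the mesh with per-element labels replaced.
#' @export
labelsToMesh <- function(labels, mesh) {
  stopifnot(is(mesh, "LabeledMesh"))
  if (!length(mesh@dims))
    stop("labelsToMesh requires a structured-grid mesh")
  dims <- mesh@dims
  vd <- dim(labels)
  if (length(vd) == length(dims) + 1L && vd[length(vd)] == 1L)
    vd <- vd[-length(vd)]
  if (length(vd) != length(dims))
    stop("voxel grid dimensionality does not match the mesh grid")
  fac <- vd / dims
  if (any(fac != as.integer(fac)))
    stop("voxel grid is not an integer refinement of the element grid")
  fac <- as.integer(fac)
  labv <- array(labels, dim = c(vd, rep(1L, 3 - length(vd))))
  facv <- c(fac, rep(1L, 3 - length(fac)))
  dimsv <- c(dims, rep(1L, 3 - length(dims)))

  newLab <- integer(prod(dims))
  e <- 0L
  for (k in seq_len(dimsv[3])) for (j in seq_len(dimsv[2]))
    for (i in seq_len(dimsv[1])) {
      e <- e + 1L
      vox <- labv[((i - 1L) * facv[1] + 1L):(i * facv[1]),
                  ((j - 1L) * facv[2] + 1L):(j * facv[2]),
                  ((k - 1L) * facv[3] + 1L):(k * facv[3])]
      vox <- vox[!is.na(vox)]
      if (!length(vox)) { newLab[e] <- .LBL_NORMAL; next }
      cnt <- tabulate(vox + 1L, 3L)
      # majority with severity tie-break: scan from SCAR down
      best <- max(cnt)
      newLab[e] <- max(which(cnt == best)) - 1L
    }
  # element ordering of generateSheet/generateSlab is i fastest, then j, k
  mesh@labels <- newLab
  validObject(mesh)
  mesh
}
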