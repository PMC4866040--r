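#' @include AllGenerics.R
NULL

# ---------------------------------------------------------------------------
# LabeledMesh
# ---------------------------------------------------------------------------

#' LabeledMesh: a structured finite-element tissue model with tissue labels
#'
#' Nodes (mm), quad/hex element connectivity (1-based), a per-element tissue
#' label (NORMAL / GZ / SCAR), the grid resolution (element edge length, mm)
#' and named surface node sets (\code{endo}, \code{epi}, \code{base},
#' \code{apex}, \code{rv_endo} where present).
#'
#' @slot nodes numeric matrix, one row per node (2 or 3 columns, mm).
#' @slot elements integer matrix, one row per element (4 columns for quads,
#'   8 for hexahedra), 1-based node indices.
#' @slot labels integer vector of per-element tissue codes (0 NORMAL, 1 GZ,
#'   2 SCAR).
#' @slot resolution numeric(1), element edge length in mm.
#' @slot surfaces named list of integer node-index vectors.
#' @slot dims integer grid dimensions in elements (length 2 or 3), kept for
#'   structured-grid meshes; \code{integer(0)} otherwise.
#' @export
setClass("LabeledMesh",
  representation(nodes = "matrix", elements = "matrix", labels = "integer",
                 resolution = "numeric", surfaces = "list", dims = "integer"))

setValidity("LabeledMesh", function(object) {
  msg <- character()
  nn <- nrow(object@nodes)
  el <- object@elements
  if (!ncol(object@nodes) %in% c(2L, 3L))
    msg <- c(msg, "nodes must have 2 or 3 coordinate columns")
  if (!ncol(el) %in% c(4L, 8L))
    msg <- c(msg, "elements must be quads (4 nodes) or hexahedra (8 nodes)")
  if (nrow(el) > 0 && (min(el) < 1L || max(el) > nn))
    msg <- c(msg, "element connectivity refers to non-existent nodes")
  if (length(object@labels) != nrow(el))
    msg <- c(msg, "labels must have one entry per element")
  if (length(object@labels) && !all(object@labels %in% c(0L, 1L, 2L)))
    msg <- c(msg, "labels must be 0 (NORMAL), 1 (GZ) or 2 (SCAR)")
  if (length(object@resolution) != 1L || !is.finite(object@resolution) ||
      object@resolution <= 0)
    msg <- c(msg, "resolution must be a single positive number (mm)")
  if (length(object@surfaces)) {
    idx <- unlist(object@surfaces, use.names = FALSE)
    if (length(idx) && (min(idx) < 1L || max(idx) > nn))
      msg <- c(msg, "surface node sets refer to non-existent nodes")
    if (all(c("endo", "epi") %in% names(object@surfaces)) &&
        length(intersect(object@surfaces$endo, object@surfaces$epi)))
      msg <- c(msg, "endo and epi surface node sets must be disjoint")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn LabeledMesh node coordinate matrix (mm)
#' @param x a \code{LabeledMesh}
#' @export
setMethod("meshNodes", "LabeledMesh", function(x) x@nodes)

#' @describeIn LabeledMesh element connectivity matrix (1-based)
#' @export
setMethod("meshElements", "LabeledMesh", function(x) x@elements)

#' @describeIn LabeledMesh per-element tissue labels as a factor
#' @export
setMethod("tissueLabels", "LabeledMesh",
          function(x) tissueLabelFactor(x@labels))

#' @describeIn LabeledMesh element edge length (mm)
#' @export
setMethod("meshResolution", "LabeledMesh", function(x) x@resolution)

#' @describeIn LabeledMesh named surface node sets
#' @export
setMethod("meshSurfaces", "LabeledMesh", function(x) x@surfaces)

#' @describeIn LabeledMesh number of nodes
#' @export
setMethod("nNodes", "LabeledMesh", function(x) nrow(x@nodes))

#' @describeIn LabeledMesh number of elements
#' @export
setMethod("nElements", "LabeledMesh", function(x) nrow(x@elements))

#' @describeIn LabeledMesh fraction of elements carrying each tissue label
#' @export
setMethod("labelFractions", "LabeledMesh", function(x) {
  tab <- table(tissueLabels(x))
  fr <- as.numeric(tab) / max(1L, nElements(x))
  names(fr) <- names(tab)
  fr
})

setMethod("show", "LabeledMesh", function(object) {
  d <- ncol(object@nodes)
  fr <- labelFractions(object)
  cat(sprintf("LabeledMesh: %dD, %d nodes, %d %s elements, dx = %g mm\n",
              d, nNodes(object), nElements(object),
              if (ncol(object@elements) == 4L) "quad" else "hex",
              object@resolution))
  cat("  label fractions:",
      paste(sprintf("%s %.3f", names(fr), fr), collapse = ", "), "\n")
  if (length(object@surfaces))
    cat("  surfaces:", paste(sprintf("%s (%d)", names(object@surfaces),
        lengths(object@surfaces)), collapse = ", "), "\n")
  invisible(NULL)
})

# internal constructor (validity checked)
.LabeledMesh <- function(nodes, elements, labels, resolution,
                         surfaces = list(), dims = integer(0)) {
  new("LabeledMesh", nodes = nodes, elements = elements,
      labels = as.integer(labels), resolution = resolution,
      surfaces = surfaces, dims = as.integer(dims))
}

# ---------------------------------------------------------------------------
# InfarctSpec
# ---------------------------------------------------------------------------

#' InfarctSpec: parameterized scar / grey-zone morphology
#'
#' Describes an ellipsoidal scar footprint (centre + radii, mm), a grey-zone
#' rim of given width around it, and an optional conducting isthmus: a
#' straight channel of given width cut through the scar (and its rim) along
#' one coordinate axis, relabeled NORMAL or GZ.
#'
#' @slot center numeric, scar centre (mm), length equal to mesh dimension.
#' @slot radii numeric, scar semi-axes (mm); radii may exceed the mesh so a
#'   scar band can bisect a sheet.
#' @slot gzRimWidth numeric(1), grey-zone rim width (mm), >= 0.
#' @slot isthmus list; empty, or \code{list(width=, label=, axis=, center=)}
#'   where \code{axis} is the coordinate axis (1 = x, ...) across which the
#'   channel extends and \code{center} its coordinate on that axis (mm).
#' @export
setClass("InfarctSpec",
  representation(center = "numeric", radii = "numeric",
                 gzRimWidth = "numeric", isthmus = "list"))

setValidity("InfarctSpec", function(object) {
  msg <- character()
  if (length(object@center) != length(object@radii))
    msg <- c(msg, "center and radii must have the same length")
  if (any(object@radii <= 0)) msg <- c(msg, "radii must be positive")
  if (object@gzRimWidth < 0) msg <- c(msg, "gzRimWidth must be >= 0")
  if (length(object@isthmus)) {
    it <- object@isthmus
    need <- c("width", "label", "axis", "center")
    if (!all(need %in% names(it)))
      msg <- c(msg, "isthmus needs fields width, label, axis, center")
    else {
      if (!it$label %in% c("NORMAL", "GZ"))
        msg <- c(msg, "isthmus label must be NORMAL or GZ")
      if (it$width <= 0) msg <- c(msg, "isthmus width must be positive")
      if (it$width >= 2 * max(object@radii))
        msg <- c(msg, "isthmus width must be smaller than the scar extent")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct an infarct morphology specification
#'
#' @param center scar centre (mm).
#' @param radii scar semi-axes (mm); one per mesh dimension.
#' @param gzRimWidth grey-zone rim width in mm (default 2).
#' @param isthmusWidth optional conducting-channel width (mm); \code{NULL}
#'   for no isthmus.
#' @param isthmusLabel label of the channel tissue, \code{"NORMAL"} or
#'   \code{"GZ"}.
#' @param isthmusAxis coordinate axis along which the channel crosses the
#'   scar (1 = constant-x channel plane normal ... ); the channel is the set
#'   of infarct elements whose coordinate on this axis is within
#'   \code{isthmusWidth/2} of \code{isthmusCenter}.
#' @param isthmusCenter channel centre coordinate on \code{isthmusAxis} (mm);
#'   defaults to the scar centre coordinate.
#' @return an \code{InfarctSpec}.
#' @export
#' @examples
#' infarctSpec(center = c(10, 10), radii = c(5, 5), gzRimWidth = 2)
infarctSpec <- function(center, radii, gzRimWidth = 2,
                        isthmusWidth = NULL, isthmusLabel = "GZ",
                        isthmusAxis = 1L, isthmusCenter = NULL) {
  it <- list()
  if (!is.null(isthmusWidth)) {
    if (is.null(isthmusCenter)) isthmusCenter <- center[isthmusAxis]
    it <- list(width = isthmusWidth, label = isthmusLabel,
               axis = as.integer(isthmusAxis), center = isthmusCenter)
  }
  new("InfarctSpec", center = as.numeric(center), radii = as.numeric(radii),
      gzRimWidth = gzRimWidth, isthmus = it)
}

setMethod("show", "InfarctSpec", function(object) {
  cat(sprintf("InfarctSpec: centre (%s) mm, radii (%s) mm, GZ rim %.2g mm\n",
              paste(object@center, collapse = ", "),
              paste(object@radii, collapse = ", "), object@gzRimWidth))
  if (length(object@isthmus))
    cat(sprintf("  isthmus: %.2g mm %s channel across axis %d at %.2g mm\n",
                object@isthmus$width, object@isthmus$label,
                object@isthmus$axis, object@isthmus$center))
  invisible(NULL)
})

# ---------------------------------------------------------------------------
# FiberField / FiberRules
# ---------------------------------------------------------------------------

#' FiberField: per-element unit fibre directions
#'
#' @slot directions numeric matrix (elements x dim) of unit vectors.
#' @slot phi numeric per-element transmural coordinate in [0,1] (or NA).
#' @slot psi numeric per-element apicobasal coordinate in [0,1] (or NA).
#' @export
setClass("FiberField",
  representation(directions = "matrix", phi = "numeric", psi = "numeric"))

setValidity("FiberField", function(object) {
  msg <- character()
  nrm <- sqrt(rowSums(object@directions^2))
  if (length(nrm) && any(abs(nrm - 1) > 1e-9))
    msg <- c(msg, "fibre directions must be unit vectors (|norm - 1| <= 1e-9)")
  ok <- function(v) !length(v) || all(is.na(v) | (v >= -1e-12 & v <= 1 + 1e-12))
  if (!ok(object@phi)) msg <- c(msg, "phi must lie in [0,1]")
  if (!ok(object@psi)) msg <- c(msg, "psi must lie in [0,1]")
  if (length(msg)) msg else TRUE
})

#' @describeIn FiberField matrix of per-element unit fibre vectors
#' @param x a \code{FiberField}
#' @export
setMethod("fiberDirections", "FiberField", function(x) x@directions)

setMethod("show", "FiberField", function(object) {
  cat(sprintf("FiberField: %d elements, %dD%s\n", nrow(object@directions),
              ncol(object@directions),
              if (all(is.na(object@phi))) "" else ", with transmural field"))
  invisible(NULL)
})

#' Fibre orientation rules (helix angles at the endo/epi surfaces)
#'
#' The transmural helix-angle rule alpha(phi) = alphaEndo * (1 - phi) +
#' alphaEpi * phi, applied about the transmural axis; intermediate frames are
#' obtained by bidirectional spherical linear interpolation of the two
#' surface rotations.
#'
#' @slot alphaEndo helix angle at the endocardium (degrees).
#' @slot alphaEpi helix angle at the epicardium (degrees).
#' @export
setClass("FiberRules",
  representation(alphaEndo = "numeric", alphaEpi = "numeric"))

setValidity("FiberRules", function(object) {
  if (abs(object@alphaEndo) >= 90 || abs(object@alphaEpi) >= 90)
    "helix angles must lie in (-90, 90) degrees" else TRUE
})

#' @param alphaEndo,alphaEpi helix angles in degrees, in (-90, 90).
#' @return a \code{FiberRules} object.
#' @rdname FiberRules-class
#' @export
#' @examples
#' fiberRules()  # default +40 / -50 degrees
fiberRules <- function(alphaEndo = 40, alphaEpi = -50) {
  new("FiberRules", alphaEndo = alphaEndo, alphaEpi = alphaEpi)
}

setMethod("show", "FiberRules", function(object) {
  cat(sprintf("FiberRules: alpha_endo = %+g deg, alpha_epi = %+g deg\n",
              object@alphaEndo, object@alphaEpi))
  invisible(NULL)
})

# ---------------------------------------------------------------------------
# IntensityVolume
# ---------------------------------------------------------------------------

#' IntensityVolume: a signal-intensity grid for tissue classification
#'
#' A scalar signal-intensity volume co-registered with a structured mesh
#' grid, a myocardium mask and a remote (known non-infarcted) reference
#' region used by the full-width-at-half-maximum classifier.
#'
#' @slot values numeric array (2D or 3D) of signal intensities.
#' @slot myocardiumMask logical array, same dim as \code{values}.
#' @slot remoteRegion logical array, subset of the myocardium mask.
#' @export
setClass("IntensityVolume",
  representation(values = "array", myocardiumMask = "array",
                 remoteRegion = "array"))

setValidity("IntensityVolume", function(object) {
  msg <- character()
  if (!all(is.finite(object@values[object@myocardiumMask])))
    msg <- c(msg, "signal intensities must be finite within the myocardium")
  if (!identical(dim(object@values), dim(object@myocardiumMask)) ||
      !identical(dim(object@values), dim(object@remoteRegion)))
    msg <- c(msg, "values, myocardiumMask and remoteRegion dims must match")
  if (any(object@remoteRegion & !object@myocardiumMask))
    msg <- c(msg, "remoteRegion must be a subset of myocardiumMask")
  if (length(msg)) msg else TRUE
})

#' Construct an intensity volume
#'
#' @param values numeric array of signal intensities (arbitrary units).
#' @param myocardiumMask logical array flagging myocardial voxels; defaults
#'   to all voxels.
#' @param remoteRegion logical array flagging the remote non-infarcted
#'   reference voxels.
#' @return an \code{IntensityVolume}.
#' @export
intensityVolume <- function(values, myocardiumMask = NULL, remoteRegion) {
  values <- as.array(values)
  if (is.null(myocardiumMask))
    myocardiumMask <- array(TRUE, dim(values))
  new("IntensityVolume", values = values,
      myocardiumMask = myocardiumMask, remoteRegion = remoteRegion)
}

setMethod("show", "IntensityVolume", function(object) {
  cat(sprintf("IntensityVolume: %s grid, %d myocardial voxels, %d remote\n",
              paste(dim(object@values), collapse = " x "),
              sum(object@myocardiumMask), sum(object@remoteRegion)))
  invisible(NULL)
})

# ---------------------------------------------------------------------------
# Cell / solver configuration classes
# ---------------------------------------------------------------------------

#' CellParams: maximal conductances of the ventricular ionic model
#'
#' Maximal conductances/permeabilities of the major currents of the human
#' ventricular membrane model, the transmural cell variant, and the
#' grey-zone region scaling factors (applied multiplicatively to I_Na,
#' I_CaL, I_Kr, I_Ks when \code{gz} is TRUE).
#'
#' @slot gNa,gCaL,gKr,gKs,gK1,gto maximal conductances (model units).
#' @slot variant one of \code{"epicardial"}, \code{"endocardial"},
#'   \code{"mid-myocardial"}.
#' @slot scaling numeric(4): the grey-zone factors (sNa, sCaL, sKr, sKs).
#' @slot gz logical(1): whether the scaling has been applied (guards
#'   idempotence of \code{\link{makeGzParams}}).
#' @export
setClass("CellParams",
  representation(gNa = "numeric", gCaL = "numeric", gKr = "numeric",
                 gKs = "numeric", gK1 = "numeric", gto = "numeric",
                 variant = "character", scaling = "numeric",
                 gz = "logical"))

setValidity("CellParams", function(object) {
  msg <- character()
  g <- c(object@gNa, object@gCaL, object@gKr, object@gKs, object@gK1,
         object@gto)
  if (any(g < 0)) msg <- c(msg, "conductances must be >= 0")
  if (!object@variant %in% c("epicardial", "endocardial", "mid-myocardial"))
    msg <- c(msg, "unknown cell variant")
  if (length(object@scaling) != 4L ||
      any(object@scaling <= 0 | object@scaling > 1))
    msg <- c(msg, "scaling factors must be 4 values in (0, 1]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "CellParams", function(object) {
  cat(sprintf("CellParams (%s%s): gNa=%.4g gCaL=%.4g gKr=%.4g gKs=%.4g\n",
              object@variant, if (object@gz) ", GZ-remodelled" else "",
              object@gNa, object@gCaL, object@gKr, object@gKs))
  invisible(NULL)
})

#' Conductivities: per-label longitudinal/transverse tissue conductivities
#'
#' Transversely isotropic monodomain conductivities in S/m per tissue label.
#' Defaults: non-infarcted 0.255 (longitudinal) and 0.0775 (transverse);
#' grey zone with a 90 percent reduction of the transverse conductivity
#' (0.00775) reflecting gap-junction remodelling; scar non-conductive.
#'
#' @slot normal numeric(2): (longitudinal, transverse) S/m.
#' @slot gz numeric(2): (longitudinal, transverse) S/m.
#' @export
setClass("Conductivities",
  representation(normal = "numeric", gz = "numeric"))

setValidity("Conductivities", function(object) {
  if (length(object@normal) != 2L || length(object@gz) != 2L ||
      any(c(object@normal, object@gz) < 0))
    "conductivities must be two non-negative values (l, t) per label"
  else TRUE
})

#' @param normal,gz numeric(2): (longitudinal, transverse) conductivity in
#'   S/m for non-infarcted and grey-zone tissue. Scar is always
#'   non-conductive.
#' @return a \code{Conductivities} object.
#' @rdname Conductivities-class
#' @export
#' @examples
#' conductivities()
conductivities <- function(normal = c(0.255, 0.0775),
                           gz = c(0.255, 0.00775)) {
  new("Conductivities", normal = as.numeric(normal), gz = as.numeric(gz))
}

setMethod("show", "Conductivities", function(object) {
  cat(sprintf(
    "Conductivities (S/m): NORMAL (%.4g, %.4g)  GZ (%.4g, %.4g)  SCAR (0, 0)\n",
    object@normal[1], object@normal[2], object@gz[1], object@gz[2]))
  invisible(NULL)
})

#' SimConfig: monodomain solver configuration
#'
#' @slot dt time step in ms (default 0.025, i.e. 25 microseconds).
#' @slot outputInterval sampling interval for stored Vm frames in ms
#'   (\code{Inf} disables frame storage; activation times are always
#'   recorded exactly at the solver step).
#' @slot beta membrane surface-to-volume ratio (1/cm).
#' @slot cm membrane capacitance (uF/cm^2).
#' @slot actThreshold activation-detection threshold (mV): a node's local
#'   activation time is the upward crossing of this value.
#' @slot lockout per-node refractory lockout for activation detection (ms).
#' @slot freezeIonic logical: if TRUE the membrane reaction term is frozen
#'   to zero (pure diffusion), used by conservation diagnostics.
#' @export
setClass("SimConfig",
  representation(dt = "numeric", outputInterval = "numeric",
                 beta = "numeric", cm = "numeric",
                 actThreshold = "numeric", lockout = "numeric",
                 freezeIonic = "logical"))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@dt <= 0) msg <- c(msg, "dt must be positive")
  if (object@beta <= 0 || object@cm <= 0)
    msg <- c(msg, "beta and cm must be positive")
  if (length(msg)) msg else TRUE
})

#' @param dt solver time step, ms.
#' @param outputInterval Vm frame sampling interval, ms (\code{Inf}: none).
#' @param beta surface-to-volume ratio, 1/cm.
#' @param cm membrane capacitance, uF/cm^2.
#' @param actThreshold activation threshold, mV.
#' @param lockout activation refractory lockout, ms.
#' @param freezeIonic freeze the reaction term (diffusion-only runs).
#' @return a \code{SimConfig} object.
#' @rdname SimConfig-class
#' @export
#' @examples
#' simConfig(outputInterval = 5)
simConfig <- function(dt = 0.025, outputInterval = 1, beta = 1400, cm = 1,
                      actThreshold = 0, lockout = 50, freezeIonic = FALSE) {
  new("SimConfig", dt = dt, outputInterval = outputInterval, beta = beta,
      cm = cm, actThreshold = actThreshold, lockout = lockout,
      freezeIonic = freezeIonic)
}

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(
    "SimConfig: dt=%g ms, output every %g ms, beta=%g /cm, Cm=%g uF/cm^2\n",
    object@dt, object@outputInterval, object@beta, object@cm))
  invisible(NULL)
})

#' StimulusSpec: a transmembrane-current pacing stimulus
#'
#' Current is injected into all conductive nodes within a cubic electrode
#' of edge \code{extent} centred at \code{center} (default 1 x 1 x 1 mm).
#'
#' @slot center electrode centre (mm).
#' @slot extent electrode cube edge (mm).
#' @slot amplitude transmembrane current density (uA/uF).
#' @slot duration pulse duration (ms).
#' @slot onset pulse onset time (ms).
#' @export
setClass("StimulusSpec",
  representation(center = "numeric", extent = "numeric",
                 amplitude = "numeric", duration = "numeric",
                 onset = "numeric"))

setValidity("StimulusSpec", function(object) {
  msg <- character()
  if (!is.na(object@amplitude) && object@amplitude <= 0)
    msg <- c(msg, "stimulus amplitude must be positive")
  if (object@duration <= 0) msg <- c(msg, "stimulus duration must be positive")
  if (object@extent <= 0) msg <- c(msg, "electrode extent must be positive")
  if (length(msg)) msg else TRUE
})

#' @param center electrode centre, mm (length = mesh dimension).
#' @param onset pulse onset, ms.
#' @param amplitude current density, uA/uF; \code{NA} requests the package
#'   default (1.5 x the diastolic strand threshold found by bisection).
#' @param duration pulse duration, ms.
#' @param extent electrode cube edge, mm.
#' @return a \code{StimulusSpec} object.
#' @rdname StimulusSpec-class
#' @export
#' @examples
#' stimulusSpec(center = c(1, 1), onset = 0, amplitude = 80)
stimulusSpec <- function(center, onset = 0, amplitude = NA_real_,
                         duration = 2, extent = 1) {
  new("StimulusSpec", center = as.numeric(center), extent = extent,
      amplitude = amplitude, duration = duration, onset = onset)
}

# ---------------------------------------------------------------------------
# Recording
# ---------------------------------------------------------------------------

#' Recording: sampled Vm frames and exact per-node activation times
#'
#' @slot frames numeric matrix (nodes x frames) of Vm samples (mV); may have
#'   zero columns when frame storage is disabled.
#' @slot frameTimes numeric vector of frame times (ms).
#' @slot activations list of strictly increasing per-node activation times
#'   (ms), recorded at the solver step as upward crossings of the activation
#'   threshold.
#' @slot stimLog data.frame logging the delivered stimuli.
#' @slot finalState numeric matrix (19 x nodes): membrane state at the end
#'   of the run, reusable as the initial state of a continuation run.
#' @slot nodeLabels integer per-node region code (0 NORMAL, 1 GZ,
#'   2 excluded/scar).
#' @slot tStart,tEnd simulated interval (ms).
#' @slot dt solver step (ms).
#' @export
setClass("Recording",
  representation(frames = "matrix", frameTimes = "numeric",
                 activations = "list", stimLog = "data.frame",
                 finalState = "matrix", nodeLabels = "integer",
                 tStart = "numeric", tEnd = "numeric", dt = "numeric"))

setValidity("Recording", function(object) {
  msg <- character()
  bad <- vapply(object@activations,
                function(a) length(a) > 1 && any(diff(a) <= 0), logical(1))
  if (any(bad))
    msg <- c(msg, "per-node activation lists must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' @describeIn Recording list of per-node activation times (ms)
#' @param x a \code{Recording}
#' @export
setMethod("activationTimes", "Recording", function(x) x@activations)

#' @describeIn Recording sampled Vm frames (nodes x frames, mV)
#' @export
setMethod("vmFrames", "Recording", function(x) x@frames)

#' @describeIn Recording frame sample times (ms)
#' @export
setMethod("frameTimes", "Recording", function(x) x@frameTimes)

setMethod("show", "Recording", function(object) {
  nact <- sum(lengths(object@activations))
  cat(sprintf(
    "Recording: %d nodes, t = [%g, %g] ms, %d frames, %d activations\n",
    length(object@activations), object@tStart, object@tEnd,
    ncol(object@frames), nact))
  invisible(NULL)
})

# ---------------------------------------------------------------------------
# Protocol classes
# ---------------------------------------------------------------------------

#' PulseTrain: the programmed-stimulation schedule parameters
#'
#' Eight conditioning stimuli (S1) at a 600 ms cycle length, then up to
#' three decremental extrastimuli (S2, S3, S4) starting at a 300 ms coupling
#' interval and shortened in 10 ms steps until arrhythmia induction or
#' capture failure.
#'
#' @slot nS1 number of S1 beats (8).
#' @slot s1CL S1 cycle length, ms (600).
#' @slot prematureInitial initial extrastimulus coupling interval, ms (300).
#' @slot decrement coupling decrement per step, ms (10).
#' @slot maxExtrastimuli maximum number of extrastimuli (3: S2, S3, S4).
#' @slot minCoupling hard floor on coupling intervals, ms (0 disables; the
#'   scan normally terminates on capture failure).
#' @export
setClass("PulseTrain",
  representation(nS1 = "integer", s1CL = "numeric",
                 prematureInitial = "numeric", decrement = "numeric",
                 maxExtrastimuli = "integer", minCoupling = "numeric"))

setValidity("PulseTrain", function(object) {
  msg <- character()
  if (object@decrement <= 0) msg <- c(msg, "decrement must be positive")
  if (object@prematureInitial >= object@s1CL)
    msg <- c(msg, "prematureInitial must be shorter than the S1 cycle length")
  if (object@nS1 < 1L) msg <- c(msg, "at least one S1 beat is required")
  if (length(msg)) msg else TRUE
})

#' @param nS1 number of S1 beats.
#' @param s1CL S1 cycle length (ms).
#' @param prematureInitial initial extrastimulus coupling (ms).
#' @param decrement scan decrement (ms).
#' @param maxExtrastimuli maximum extrastimuli count.
#' @param minCoupling coupling floor (ms); 0 disables the floor.
#' @return a \code{PulseTrain} object.
#' @rdname PulseTrain-class
#' @export
#' @examples
#' pulseTrain()
pulseTrain <- function(nS1 = 8L, s1CL = 600, prematureInitial = 300,
                       decrement = 10, maxExtrastimuli = 3L,
                       minCoupling = 0) {
  new("PulseTrain", nS1 = as.integer(nS1), s1CL = s1CL,
      prematureInitial = prematureInitial, decrement = decrement,
      maxExtrastimuli = as.integer(maxExtrastimuli),
      minCoupling = minCoupling)
}

setMethod("show", "PulseTrain", function(object) {
  cat(sprintf(
    "PulseTrain: %d x S1 @ %g ms; extrastimuli from %g ms in -%g ms steps (max %d)\n",
    object@nS1, object@s1CL, object@prematureInitial, object@decrement,
    object@maxExtrastimuli))
  invisible(NULL)
})

#' VarpResult: per-site outcomes and the overall inducibility call
#'
#' @slot sites data.frame with one row per pacing site: \code{site},
#'   \code{classification} (NONINDUCIBLE / SINGLE_BEAT / UNSUSTAINED /
#'   SUSTAINED / FAILED), the coupling intervals at induction and
#'   \code{vtCycleLength} (ms; NA unless UNSUSTAINED or SUSTAINED).
#' @slot overall \code{"positive"} iff any site is UNSUSTAINED or SUSTAINED,
#'   else \code{"negative"}.
#' @slot provenance list with configuration fingerprint and seed.
#' @export
setClass("VarpResult",
  representation(sites = "data.frame", overall = "character",
                 provenance = "list"))

setValidity("VarpResult", function(object) {
  msg <- character()
  pos <- any(object@sites$classification %in% c("UNSUSTAINED", "SUSTAINED"))
  if (object@overall != ifelse(pos, "positive", "negative"))
    msg <- c(msg, "overall call inconsistent with per-site outcomes")
  cl <- object@sites$classification
  hascl <- !is.na(object@sites$vtCycleLength)
  if (any(hascl & !cl %in% c("UNSUSTAINED", "SUSTAINED")))
    msg <- c(msg, "vtCycleLength may only be present for UNSUSTAINED/SUSTAINED")
  if (length(msg)) msg else TRUE
})

#' @describeIn VarpResult per-site outcome table
#' @param x a \code{VarpResult}
#' @export
setMethod("siteOutcomes", "VarpResult", function(x) x@sites)

#' @describeIn VarpResult overall positive/negative inducibility call
#' @export
setMethod("overallCall", "VarpResult", function(x) x@overall)

setMethod("show", "VarpResult", function(object) {
  tab <- table(object@sites$classification)
  cat(sprintf("VarpResult: %s (%d sites: %s)\n", toupper(object@overall),
              nrow(object@sites),
              paste(sprintf("%s %d", names(tab), tab), collapse = ", ")))
  invisible(NULL)
})
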