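#' @include AllClasses.R fem.R cell.R
NULL

# monodomain diffusivity (mm^2/ms) from conductivity (S/m), surface-to-
# volume ratio (1/cm) and capacitance (uF/cm^2)
.diffusivity <- function(sigma, beta, cm) 1000 * sigma / (beta * cm)

# per-node region code from element labels: majority over adjacent
# elements, ties toward the more severe label; nodes touching only scar
# are excluded from the conductive domain (code 2)
.nodeLabels <- function(mesh) {
  el <- mesh@elements
  n <- nNodes(mesh)
  cnt <- matrix(0L, n, 3L)
  for (lb in 0:2) {
    rows <- which(mesh@labels == lb)
    if (length(rows))
      cnt[, lb + 1L] <- tabulate(as.vector(el[rows, , drop = FALSE]),
                                 nbins = n)
  }
  out <- integer(n)
  conductive <- cnt[, 1] + cnt[, 2]
  out[conductive == 0L] <- 2L
  active <- conductive > 0L
  gzWins <- cnt[, 2] >= cnt[, 1]       # tie -> more severe (GZ)
  out[active] <- ifelse(gzWins[active], 1L, 0L)
  out
}

# nodes inside the cubic electrode of a StimulusSpec, restricted to the
# conductive domain
.electrodeNodes <- function(mesh, nodeLab, stim) {
  nd <- mesh@nodes
  half <- stim@extent / 2
  ok <- rep(TRUE, nrow(nd))
  for (c_ in seq_len(ncol(nd)))
    ok <- ok & abs(nd[, c_] - stim@center[c_]) <= half + 1e-9
  which(ok & nodeLab != 2L)
}

# assemble the dt-scaled explicit diffusion operator A (V <- V + A V)
.assembleOperator <- function(mesh, fibers, cond, config) {
  lab <- mesh@labels
  conductive <- which(lab != .LBL_SCAR)
  if (!length(conductive)) stop("empty conductive domain")
  f <- fibers@directions[conductive, , drop = FALSE]
  Dl <- ifelse(lab[conductive] == .LBL_GZ,
               .diffusivity(cond@gz[1], config@beta, config@cm),
               .diffusivity(cond@normal[1], config@beta, config@cm))
  Dt <- ifelse(lab[conductive] == .LBL_GZ,
               .diffusivity(cond@gz[2], config@beta, config@cm),
               .diffusivity(cond@normal[2], config@beta, config@cm))
  Dcomp <- .tensorComponents(f, Dl, Dt)
  K <- .assembleStiffness(mesh, Dcomp, conductive)
  m <- .lumpedMass(mesh, conductive)
  m[m == 0] <- 1                          # excluded nodes, never used
  A <- -config@dt * Matrix::Diagonal(x = 1 / m) %*% K
  A <- methods::as(A, "CsparseMatrix")
  # explicit stability: substep the diffusion update when the operator
  # norm exceeds the forward-Euler envelope (a Gershgorin bound on the
  # dt-scaled Laplacian); nSub = 1 at the default conductivities and
  # resolution
  normA <- max(Matrix::rowSums(abs(A)))
  nSub <- max(1L, ceiling(normA / 1.5))
  list(A = A / nSub, nSub = as.integer(nSub))
}

#' Run a monodomain simulation
#'
#' Integrates the anisotropic monodomain reaction-diffusion system
#' beta * Cm * dV/dt = div(sigma grad V) - beta * I_ion + I_stim on a
#' labeled mesh by first-order operator splitting: an explicit
#' (mass-lumped finite element) diffusion step followed by the membrane
#' update at each time step. Scar elements are removed from the assembly
#' (no-flux boundary at the scar border); nodes adjacent only to scar are
#' excluded from the conductive domain entirely and never activate.
#' Activation times are recorded exactly at the solver step as upward
#' crossings of the activation threshold, with a per-node refractory
#' lockout.
#'
#' @param mesh a \code{\link{LabeledMesh}}.
#' @param fibers a \code{\link{FiberField}} on the same mesh.
#' @param cond a \code{\link{conductivities}} object.
#' @param cells list with \code{normal} and \code{gz}
#'   \code{\link{CellParams}} entries (the \code{gz} entry defaults to
#'   \code{makeGzParams(cells$normal)}).
#' @param stimuli list of \code{\link{stimulusSpec}} objects.
#' @param duration simulated time, ms.
#' @param config a \code{\link{simConfig}} object.
#' @param state optional 19 x nNodes state matrix to continue from (as
#'   stored in a previous \code{Recording}'s \code{finalState}).
#' @param tStart simulation clock at the start of this run, ms.
#' @return a \code{\link{Recording}}.
#' @export
#' @examples
#' sheet <- generateSheet(20, 20)
#' fib <- assignFibers(sheet, constantDirection = c(1, 0))
#' rec <- runMonodomain(sheet, fib, duration = 10,
#'   stimuli = list(stimulusSpec(center = c(0, 0), amplitude = 150)),
#'   config = simConfig(outputInterval = 5))
#' sum(lengths(activationTimes(rec)) > 0) > 0
runMonodomain <- function(mesh, fibers, cond = conductivities(),
                          cells = list(normal = cellParams()),
                          stimuli = list(), duration,
                          config = simConfig(), state = NULL,
                          tStart = 0) {
  stopifnot(is(mesh, "LabeledMesh"), is(fibers, "FiberField"),
            duration >= 0)
  if (nrow(fibers@directions) != nElements(mesh))
    stop("fibre field does not match the mesh")
  if (is.null(cells$gz)) cells$gz <- makeGzParams(cells$normal)
  if (cells$normal@variant != cells$gz@variant)
    stop("normal and grey-zone cells must use the same variant")

  nodeLab <- .nodeLabels(mesh)
  if (all(nodeLab == 2L)) stop("empty conductive domain")
  op <- .assembleOperator(mesh, fibers, cond, config)
  A <- op$A

  n <- nNodes(mesh)
  if (is.null(state)) {
    state <- matrix(rep(as.numeric(initialCellState()), n), nrow = 19L)
  }
  stopifnot(nrow(state) == 19L, ncol(state) == n)

  stimNodes <- list(); onset <- dur <- amp <- numeric(0)
  for (s in stimuli) {
    stopifnot(is(s, "StimulusSpec"))
    nds <- .electrodeNodes(mesh, nodeLab, s)
    if (!length(nds))
      stop("stimulus electrode does not intersect conductive tissue")
    a <- s@amplitude
    if (is.na(a))
      a <- 1.5 * strandDiastolicThreshold(cells$normal, cond, config,
                                          dx = mesh@resolution)
    stimNodes <- c(stimNodes, list(as.integer(nds)))
    onset <- c(onset, s@onset); dur <- c(dur, s@duration)
    amp <- c(amp, a)
  }

  r <- .monodomain_run(A@p, A@i, A@x, op$nSub, state, nodeLab,
                       .paramVector(cells$normal),
                       .paramVector(cells$gz),
                       .VARIANT_CODE[[cells$normal@variant]],
                       stimNodes, onset, dur, amp, config@dt, tStart,
                       duration, config@outputInterval,
                       config@actThreshold, config@lockout,
                       config@freezeIonic)
  stimLog <- if (length(onset))
    data.frame(onset = onset, duration = dur, amplitude = amp,
               nNodes = lengths(stimNodes))
  else data.frame(onset = numeric(0), duration = numeric(0),
                  amplitude = numeric(0), nNodes = integer(0))
  new("Recording", frames = r$frames, frameTimes = r$frameTimes,
      activations = r$activations, stimLog = stimLog,
      finalState = r$state, nodeLabels = nodeLab, tStart = tStart,
      tEnd = r$tEnd, dt = config@dt)
}

#' Diastolic pacing threshold on a calibration strand
#'
#' Finds, by bisection, the minimum transmembrane stimulus current (2 ms
#' pulse into a 1 mm electrode at the end of a thin fibre-aligned strand)
#' that elicits a propagating excitation. The default tissue stimulus
#' amplitude is 1.5 x this threshold.
#'
#' @param cells a \code{\link{CellParams}} object for the strand tissue.
#' @param cond a \code{\link{conductivities}} object.
#' @param config a \code{\link{simConfig}} object.
#' @param dx strand resolution, mm.
#' @param lower,upper bisection bracket, uA/uF.
#' @param tol relative bracket tolerance.
#' @return threshold amplitude, uA/uF.
#' @export
strandDiastolicThreshold <- function(cells = cellParams(),
                                     cond = conductivities(),
                                     config = simConfig(),
                                     dx = 0.35, lower = 5, upper = 120,
                                     tol = 0.05) {
  nx <- max(20L, ceiling(10 / dx))
  strand <- generateSheet(nx, 2L, dx)
  fib <- assignFibers(strand, constantDirection = c(1, 0))
  cfg <- simConfig(dt = config@dt, outputInterval = Inf,
                   beta = config@beta, cm = config@cm)
  fires <- function(a) {
    rec <- tryCatch(
      runMonodomain(strand, fib, cond, list(normal = cells),
        stimuli = list(stimulusSpec(center = c(0, dx), amplitude = a)),
        duration = 30, config = cfg),
      error = function(e) NULL)   # instability: definitely suprathreshold
    if (is.null(rec)) return(TRUE)
    far <- which(strand@nodes[, 1] >= 5)
    any(lengths(rec@activations[far]) > 0)
  }
  if (fires(lower)) return(lower)
  if (!fires(upper)) stop("no capture even at the upper bracket")
  while (upper / lower > 1 + tol) {
    mid <- sqrt(lower * upper)
    if (fires(mid)) upper <- mid else lower <- mid
  }
  upper
}

#' Conduction velocity between two probes
#'
#' @param recording a \code{\link{Recording}}.
#' @param mesh the simulated \code{\link{LabeledMesh}}.
#' @param probeA,probeB probe positions, mm.
#' @return conduction velocity in m/s (mm/ms).
#' @export
measureCv <- function(recording, mesh, probeA, probeB) {
  stopifnot(is(recording, "Recording"), is(mesh, "LabeledMesh"))
  near <- function(p) {
    d2 <- rowSums(sweep(mesh@nodes, 2, p, "-")^2)
    which.min(d2)
  }
  ia <- near(probeA); ib <- near(probeB)
  aa <- recording@activations[[ia]]; ab <- recording@activations[[ib]]
  if (length(aa) != 1L || length(ab) != 1L)
    stop("each probe must have activated exactly once (probe A: ",
         length(aa), ", probe B: ", length(ab), ")")
  dist <- sqrt(sum((mesh@nodes[ib, ] - mesh@nodes[ia, ])^2))
  dist / (ab - aa)
}

#' Tune conductivities to match target conduction velocities
#'
#' Iteratively rescales the longitudinal and transverse conductivities on
#' a fibre-aligned calibration strand using the square-root law CV ~
#' sqrt(sigma): sigma <- sigma * (CV_target / CV_measured)^2, until the
#' measured velocity is within \code{tol} of the target (at most
#' \code{maxIter} iterations per axis). The grey-zone conductivities keep
#' the same longitudinal value with the 90 percent transverse reduction.
#'
#' @param targetCvL,targetCvT target longitudinal and transverse
#'   velocities, m/s.
#' @param start starting \code{\link{conductivities}}.
#' @param cells strand cell parameters.
#' @param config solver configuration.
#' @param dx calibration strand resolution, mm.
#' @param tol relative CV tolerance (default 0.02).
#' @param maxIter maximum iterations per axis.
#' @return a list with \code{cond} (the tuned
#'   \code{\link{Conductivities}}), \code{cv} (achieved velocities) and
#'   \code{converged}.
#' @export
tuneConductivities <- function(targetCvL, targetCvT,
                               start = conductivities(),
                               cells = cellParams(),
                               config = simConfig(outputInterval = Inf),
                               dx = 0.35, tol = 0.02, maxIter = 10L) {
  if (targetCvL <= 0 || targetCvT <= 0)
    stop("target conduction velocities must be positive")
  tuneAxis <- function(sigma, target) {
    conv <- FALSE; cv <- NA_real_
    for (it in seq_len(maxIter)) {
      cv <- .strandCv(sigma, cells, config, dx)
      if (abs(cv - target) <= tol * target) { conv <- TRUE; break }
      sigma <- sigma * (target / cv)^2
    }
    list(sigma = sigma, cv = cv, converged = conv)
  }
  rl <- tuneAxis(start@normal[1], targetCvL)
  rt <- tuneAxis(start@normal[2], targetCvT)
  if (!rl$converged || !rt$converged)
    warning("conductivity tuning did not converge to ", tol * 100,
            "% ; returning the best iterate")
  list(cond = conductivities(normal = c(rl$sigma, rt$sigma),
                             gz = c(rl$sigma, 0.1 * rt$sigma)),
       cv = c(longitudinal = rl$cv, transverse = rt$cv),
       converged = rl$converged && rt$converged)
}

# planar-wave CV on a thin strand with sigma as the along-strand
# conductivity (fibres along x, so sigma enters as the longitudinal value)
.strandCv <- function(sigma, cells, config, dx) {
  len <- 25
  nx <- ceiling(len / dx)
  strand <- generateSheet(nx, 4L, dx)
  fib <- assignFibers(strand, constantDirection = c(1, 0))
  cnd <- conductivities(normal = c(sigma, sigma), gz = c(sigma, sigma))
  cfg <- simConfig(dt = config@dt, outputInterval = Inf,
                   beta = config@beta, cm = config@cm)
  # plane-wave initiation: stimulate the whole left edge
  rec <- runMonodomain(strand, fib, cnd, list(normal = cells),
    stimuli = list(stimulusSpec(center = c(0, 2 * dx), extent = 2,
                                amplitude = 60)),
    duration = 150, config = cfg)
  yMid <- 2 * dx
  measureCv(rec, strand, c(8, yMid), c(20, yMid))
}
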