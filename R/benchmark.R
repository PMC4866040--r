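#' @include AllClasses.R geometry.R varp.R
NULL

#' The figure-of-8 re-entry benchmark substrate
#'
#' A 2D sheet carrying a scar band bisecting the tissue, crossed by a
#' slow-conducting grey-zone isthmus channel (optionally several) and
#' flanked by narrow normal-tissue side corridors: the classic substrate
#' of figure-of-8 infarct re-entry. Fibres run along x (across the
#' sheet), so conduction along the vertical channel is mostly cross-fibre
#' and slow. A premature beat fails by decremental conduction at the
#' channel's proximal mouth (the hard zone) while still conducting
#' around the scar through the corridors; the delayed wavefront then
#' re-enters the channel retrogradely from the distal side, crosses it
#' while the mouth recovers, and exits through the proximal funnel into
#' excitable tissue - a figure-of-8 rotation around the two scar limbs.
#' The funnel-shaped mouth gives the exiting wavefront a broad source, so
#' successive transits survive the source-sink mismatch that a narrow
#' slow-channel exit would fail.
#'
#' @param width,height sheet extent, mm.
#' @param dx resolution, mm.
#' @param bandY vertical extent (min, max) of the scar band, mm.
#' @param corridor width of the normal side corridors, mm.
#' @param isthmusX x positions of the channel centres, mm (one entry per
#'   channel).
#' @param isthmusWidth channel width(s), mm.
#' @param gzRim width of the grey-zone rim around the scar, mm.
#' @param isthmusFiberAngle per-channel fibre angles (degrees from x) at
#'   the proximal (bottom) and distal (top) channel ends, linearly graded
#'   in between (a list with one angle pair per channel). The oblique angles emulate the zigzag
#'   course of surviving bundles in an infarct isthmus: they yield
#'   effective along-channel conductivities in the few-hundredths S/m
#'   range and hence the decimetre-per-second conduction typical of VT
#'   isthmuses (a purely cross-fibre channel would not conduct at all
#'   under the grey zone's 90 percent transverse conductivity reduction).
#'   A small proximal angle makes that channel's mouth the failure point
#'   of premature antegrade wavefronts - the unidirectional block that
#'   starts re-entry.
#' @param mouthWidth per-channel width of the proximal channel mouth, mm;
#'   widths above \code{isthmusWidth} flare the exit into a funnel.
#' @param flareLength length of the proximal funnel, mm.
#' @param mouthFiberAngle optional fibre-angle override inside the
#'   funnel mouth (degrees from x; NA keeps the graded channel angles
#'   there).
#' @param isthmusGradePower per-channel exponent of the angle grading;
#'   values below 1 concentrate the poorly conducting zone near the
#'   proximal mouth (a short hard segment recovers conduction safety
#'   quickly between re-entrant transits).
#' @return list with \code{mesh} (a \code{\link{LabeledMesh}}),
#'   \code{fibers} (a \code{\link{FiberField}}, along x) and
#'   \code{pacingSite} (electrode centre, mm, proximal to the channels).
#' @export
#' @examples
#' b <- figureOfEightSheet(dx = 0.7)
#' labelFractions(b$mesh)
figureOfEightSheet <- function(width = 36, height = 46, dx = 0.35,
                               bandY = c(10, 34), corridor = 3,
                               isthmusX = width / 2,
                               isthmusWidth = 3.2, gzRim = 1,
                               isthmusFiberAngle = list(c(15, 18)),
                               isthmusGradePower = 0.3,
                               mouthWidth = 6, flareLength = 3,
                               mouthFiberAngle = NA) {
  nx <- round(width / dx); ny <- round(height / dx)
  mesh <- generateSheet(nx, ny, dx)
  cent <- .elementCentroids(mesh)
  lab <- mesh@labels
  bandCore <- cent[, 2] >= bandY[1] & cent[, 2] <= bandY[2]
  bandRim <- cent[, 2] >= bandY[1] - gzRim & cent[, 2] <= bandY[2] + gzRim
  inCorridor <- cent[, 1] <= corridor | cent[, 1] >= width - corridor
  lab[bandRim & !inCorridor] <- .LBL_GZ
  lab[bandCore & !inCorridor] <- .LBL_SCAR

  nCh <- length(isthmusX)
  if (!is.list(isthmusFiberAngle))
    isthmusFiberAngle <- rep(list(isthmusFiberAngle), nCh)
  isthmusWidth <- rep_len(isthmusWidth, nCh)
  isthmusGradePower <- rep_len(isthmusGradePower, nCh)
  mouthWidth <- rep_len(mouthWidth, nCh)
  chans <- vector("list", nCh)
  for (k in seq_len(nCh)) {
    # proximal funnel: the channel flares from isthmusWidth to mouthWidth
    # over flareLength above the proximal band edge, so the exiting
    # wavefront presents a broad source to the recovered tissue below
    # (a narrow slow-channel exit fails by source-sink mismatch)
    hw <- isthmusWidth[k] / 2 +
      pmax(0, (mouthWidth[k] - isthmusWidth[k]) / 2 *
             (1 - (cent[, 2] - (bandY[1] - gzRim)) / flareLength))
    chan <- abs(cent[, 1] - isthmusX[k]) <= hw & bandRim & !inCorridor
    lab[chan] <- .LBL_GZ
    chans[[k]] <- chan
  }
  mesh@labels <- lab

  fibers <- assignFibers(mesh, constantDirection = c(1, 0))
  y0 <- bandY[1] - gzRim; y1 <- bandY[2] + gzRim
  mouthFiberAngle <- rep_len(mouthFiberAngle, nCh)
  for (k in seq_len(nCh)) {
    ang <- isthmusFiberAngle[[k]]
    if (length(ang) == 1L) ang <- rep(ang, 2L)
    chan <- chans[[k]]
    frac <- pmin(1, pmax(0, (cent[chan, 2] - y0) / (y1 - y0)))
    frac <- frac^isthmusGradePower[k]
    a <- (ang[1] * (1 - frac) + ang[2] * frac) * pi / 180
    # optionally override the fibre angle inside the funnel mouth (NA
    # keeps the graded angles there)
    if (!is.na(mouthFiberAngle[k])) {
      inMouth <- cent[chan, 2] < y0 + flareLength
      a[inMouth] <- mouthFiberAngle[k] * pi / 180
    }
    fibers@directions[chan, ] <- cbind(cos(a), sin(a))
  }
  list(mesh = mesh, fibers = fibers,
       pacingSite = c(mean(isthmusX), max(2, bandY[1] / 4)))
}

#' Run the re-entry induction benchmark
#'
#' Builds the \code{\link{figureOfEightSheet}} substrate and applies the
#' programmed-stimulation ladder from the site proximal to the isthmus,
#' returning the site outcome, the induced VT cycle length and the
#' recording of the inducing trial.
#'
#' @param dx resolution, mm.
#' @param train the \code{\link{pulseTrain}} schedule. The benchmark's
#'   default is a scaled-down drive: 2 conditioning beats at the 600 ms
#'   cycle length and a ladder starting at a 360 ms coupling. The ladder
#'   start reflects the ionic model's effective refractory period at the
#'   600 ms drive (about 335 ms; a scan from 300 ms would fail to
#'   capture at its first step), and the shortened drive preserves the
#'   border-zone action-potential prolongation that rate adaptation in
#'   this membrane model otherwise erodes - without it no coupling
#'   interval can produce unidirectional block; see the methods
#'   vignette.
#' @param cond tissue \code{\link{conductivities}}.
#' @param cells cell parameter list (normal; grey zone derived).
#' @param config solver configuration.
#' @param recordFinal keep Vm frames of the inducing trial.
#' @param verbose print scan progress.
#' @param ... further arguments to \code{\link{figureOfEightSheet}}.
#' @return the \code{\link{runSiteProtocol}} result, plus elements
#'   \code{mesh} and \code{fibers}.
#' @export
runReentryBenchmark <- function(dx = 0.35,
                                train = pulseTrain(nS1 = 2L,
                                                   prematureInitial = 360),
                                cond = conductivities(),
                                cells = list(normal = cellParams()),
                                config = simConfig(outputInterval = Inf),
                                recordFinal = FALSE, verbose = FALSE,
                                ...) {
  b <- figureOfEightSheet(dx = dx, ...)
  out <- runSiteProtocol(b$mesh, b$fibers, cond, cells, b$pacingSite,
                         train = train, config = config,
                         recordFinal = recordFinal, verbose = verbose)
  out$mesh <- b$mesh
  out$fibers <- b$fibers
  out
}
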