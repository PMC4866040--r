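#' @include AllClasses.R
NULL

.VARIANT_CODE <- c(epicardial = 0L, endocardial = 1L, "mid-myocardial" = 2L)

# grey-zone remodelling factors: 62% reduction of peak I_Na, 69% of I_CaL,
# 70% of I_Kr and 80% of I_Ks, from patch-clamp studies of border-zone
# myocytes
.GZ_SCALING <- c(sNa = 0.38, sCaL = 0.31, sKr = 0.30, sKs = 0.20)

#' Construct ventricular cell parameters
#'
#' Maximal conductances of the human ventricular ionic model. Defaults are
#' the published values of the model for the chosen transmural variant
#' (epicardial by default).
#'
#' @param variant \code{"epicardial"}, \code{"endocardial"} or
#'   \code{"mid-myocardial"}.
#' @param gNa,gCaL,gKr,gKs,gK1,gto maximal conductances; defaults are the
#'   model's published values (gKs and gto depend on the variant).
#' @return a \code{\link{CellParams}} object (non-remodelled, NORMAL
#'   tissue).
#' @export
#' @examples
#' cellParams()
cellParams <- function(variant = "epicardial", gNa = 14.838,
                       gCaL = 3.98e-5, gKr = 0.153, gKs = NULL,
                       gK1 = 5.405, gto = NULL) {
  variant <- match.arg(variant,
                       c("epicardial", "endocardial", "mid-myocardial"))
  if (is.null(gKs)) gKs <- if (variant == "mid-myocardial") 0.098 else 0.392
  if (is.null(gto)) gto <- if (variant == "endocardial") 0.073 else 0.294
  new("CellParams", gNa = gNa, gCaL = gCaL, gKr = gKr, gKs = gKs,
      gK1 = gK1, gto = gto, variant = variant,
      scaling = unname(.GZ_SCALING), gz = FALSE)
}

#' Apply grey-zone ionic remodelling to a parameter set
#'
#' Scales the maximal conductances of I_Na, I_CaL, I_Kr and I_Ks by the
#' border-zone remodelling factors (0.38, 0.31, 0.30, 0.20): a 62 percent
#' reduction of peak sodium current, 69 percent of L-type calcium current
#' and 70 / 80 percent reductions of the rapid and slow delayed-rectifier
#' potassium currents. Idempotent: a parameter set already flagged as
#' grey-zone is returned unchanged.
#'
#' @param base a \code{\link{CellParams}} object.
#' @return the remodelled \code{CellParams} with the \code{gz} flag set.
#' @export
#' @examples
#' gz <- makeGzParams(cellParams())
#' gz@gNa / cellParams()@gNa   # 0.38
makeGzParams <- function(base) {
  stopifnot(is(base, "CellParams"))
  if (base@gz) return(base)
  s <- base@scaling
  new("CellParams", gNa = base@gNa * s[1], gCaL = base@gCaL * s[2],
      gKr = base@gKr * s[3], gKs = base@gKs * s[4], gK1 = base@gK1,
      gto = base@gto, variant = base@variant, scaling = s, gz = TRUE)
}

# conductance vector passed to the compiled kernels
.paramVector <- function(p) {
  c(p@gNa, p@gCaL, p@gKr, p@gKs, p@gK1, p@gto)
}

#' Published resting/paced steady state of the ionic model
#'
#' The 19-variable membrane state (Vm, gates, intracellular and
#' sarcoplasmic-reticulum concentrations) at the model's published 1 Hz
#' paced steady state, used as the initial condition everywhere.
#'
#' @return named numeric vector of length 19.
#' @export
initialCellState <- function() {
  s <- .tp06_initial_state()
  names(s) <- c("Vm", "Cai", "CaSR", "CaSS", "Nai", "Ki", "m", "h", "j",
                "xr1", "xr2", "xs", "r", "s", "d", "f", "f2", "fCass", "RR")
  s
}

#' Advance a single cell
#'
#' Integrates the membrane ODEs for \code{nSteps} steps of \code{dt} under
#' a constant stimulus current. Gates use the Rush-Larsen exponential
#' update, other states forward Euler.
#'
#' @param state numeric(19) membrane state (see
#'   \code{\link{initialCellState}}).
#' @param params a \code{\link{CellParams}} object.
#' @param dt time step, ms (must be <= 0.025 for the coupled solve).
#' @param iStim stimulus current density, uA/uF (positive depolarizes).
#' @param nSteps number of steps.
#' @return the advanced state vector.
#' @export
#' @examples
#' s <- stepCell(initialCellState(), cellParams(), nSteps = 400)
stepCell <- function(state, params, dt = 0.025, iStim = 0, nSteps = 1L) {
  stopifnot(is(params, "CellParams"))
  if (dt > 0.025 + 1e-12)
    stop("dt must be <= 0.025 ms for the coupled membrane solve")
  out <- .cell_steps(as.numeric(state), .paramVector(params),
                     .VARIANT_CODE[[params@variant]], dt,
                     as.integer(nSteps), iStim)
  names(out) <- names(initialCellState())
  out
}

#' Run a paced single-cell train
#'
#' Delivers \code{nBeats} stimuli at the given cycle length from the
#' published steady state (or a supplied state) and returns the sampled
#' membrane-potential trace together with last-beat action-potential
#' features and a per-beat capture flag.
#'
#' @param params a \code{\link{CellParams}} object.
#' @param cycleLength pacing cycle length, ms.
#' @param nBeats number of beats (>= 1).
#' @param dt integration step, ms.
#' @param stimAmplitude stimulus current, uA/uF (the model's published
#'   pacing stimulus, 52 uA/uF for 1 ms, by default).
#' @param stimDuration stimulus duration, ms.
#' @param sampleInterval trace sampling interval, ms (<= 1 ms).
#' @param tail extra quiescent time simulated after the last beat, ms.
#' @param state optional initial state.
#' @return list with \code{time} (ms), \code{vm} (mV), \code{features}
#'   (an \code{\link{apFeatures}} result for the last beat),
#'   \code{captured} (logical per beat) and \code{state} (final state).
#' @export
#' @examples
#' tr <- runCellTrain(cellParams(), nBeats = 1, tail = 400)
#' tr$features
runCellTrain <- function(params, cycleLength = 600, nBeats = 8L,
                         dt = 0.025, stimAmplitude = 52, stimDuration = 1,
                         sampleInterval = 0.1, tail = 500,
                         state = initialCellState()) {
  stopifnot(is(params, "CellParams"), nBeats >= 1)
  if (sampleInterval > 1)
    stop("the trace must be sampled at 1 ms or finer")
  r <- .cell_train(as.numeric(state), .paramVector(params),
                   .VARIANT_CODE[[params@variant]], dt, cycleLength,
                   as.integer(nBeats), stimAmplitude, stimDuration,
                   sampleInterval, tail)
  captured <- vapply(seq_len(nBeats), function(b) {
    w <- r$time >= (b - 1) * cycleLength & r$time < b * cycleLength
    any(r$vm[w] > 0)
  }, logical(1))
  if (!all(captured))
    warning("failure to capture at beat(s) ",
            paste(which(!captured), collapse = ", "))
  lastWin <- r$time >= (nBeats - 1) * cycleLength
  feats <- apFeatures(r$time[lastWin], r$vm[lastWin])
  list(time = r$time, vm = r$vm, features = feats, captured = captured,
       state = r$state)
}

#' Extract action-potential features from a Vm trace
#'
#' Detects action potentials as upward crossings of 0 mV and reports, for
#' the last one: \code{apd90}, the interval from the time of maximum
#' upstroke velocity to 90 percent repolarization toward the pre-stimulus
#' diastolic level (sub-sample precision by linear interpolation);
#' \code{dvdtMax} (V/s); \code{peakVm} and \code{restingVm} (mV). When no
#' AP is present an explicit no-AP result is returned (\code{detected =
#' FALSE}), never zeros.
#'
#' @param time time samples, ms.
#' @param vm membrane potential samples, mV.
#' @return a list with elements \code{detected}, \code{apd90},
#'   \code{dvdtMax}, \code{peakVm}, \code{restingVm}.
#' @export
#' @examples
#' t <- seq(0, 500, by = 0.5)
#' v <- ifelse(t < 2, -85 + 60 * t, pmax(-85, 35 - (t - 2) * 120 / 398))
#' apFeatures(t, v)$peakVm
apFeatures <- function(time, vm) {
  stopifnot(length(time) == length(vm), length(time) >= 3)
  up <- which(vm[-1] >= 0 & vm[-length(vm)] < 0)
  if (!length(up))
    return(list(detected = FALSE, apd90 = NA_real_, dvdtMax = NA_real_,
                peakVm = NA_real_, restingVm = NA_real_))
  cross <- up[length(up)]
  dvdt <- diff(vm) / diff(time)
  # upstroke window: 10 ms before the 0-crossing to 5 ms after
  w <- which(time[-length(time)] >= time[cross] - 10 &
             time[-length(time)] <= time[cross] + 5)
  iUp <- w[which.max(dvdt[w])]
  tUp <- time[iUp]
  pre <- vm[time >= tUp - 50 & time < tUp - 1e-9]
  restingVm <- if (length(pre)) min(pre) else vm[1]
  after <- which(time >= tUp)
  iPk <- after[which.max(vm[after])]
  peakVm <- vm[iPk]
  v90 <- peakVm - 0.9 * (peakVm - restingVm)
  post <- which(time > time[iPk] & vm <= v90)
  apd90 <- NA_real_
  if (length(post)) {
    i2 <- post[1]; i1 <- i2 - 1L
    # linear interpolation of the crossing
    tCross <- time[i1] + (v90 - vm[i1]) * (time[i2] - time[i1]) /
      (vm[i2] - vm[i1])
    apd90 <- tCross - tUp
  }
  # mV/ms is numerically V/s
  list(detected = TRUE, apd90 = apd90, dvdtMax = max(dvdt[w]),
       peakVm = peakVm, restingVm = restingVm)
}

#' Export a Vm trace as CSV
#'
#' @param time,vm the trace (ms, mV).
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
exportTrace <- function(time, vm, path) {
  utils::write.csv(data.frame(time_ms = time, vm_mV = vm), path,
                   row.names = FALSE)
  invisible(path)
}
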