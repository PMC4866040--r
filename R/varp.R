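#' @include AllClasses.R solver.R
NULL

#' Place the endocardial pacing-site panel
#'
#' Partitions the LV endocardium into the standard 17 AHA segments (six
#' basal, six mid-cavity, four apical sectors and the apical cap) by
#' apicobasal thirds and circumferential sectors, and places one pacing
#' site at each segment's endocardial centroid (snapped to the nearest
#' conductive endocardial node; sites whose centroid lands in scar are
#' relocated to the nearest conductive endocardial node and flagged).
#' When the geometry carries an RV endocardial surface, two further sites
#' are added: the RV apex and a central location near the RV outflow
#' region, for the full 19-site biventricular panel.
#'
#' @param mesh a ventricular \code{\link{LabeledMesh}} with an \code{endo}
#'   surface (and \code{rv_endo} for the biventricular panel).
#' @param lvOnly if TRUE, return the 17-site LV panel without requiring an
#'   RV surface.
#' @return data.frame with columns \code{site}, \code{node}, \code{x},
#'   \code{y}, \code{z}, \code{relocated}.
#' @export
placePacingSites <- function(mesh, lvOnly = FALSE) {
  stopifnot(is(mesh, "LabeledMesh"))
  surf <- mesh@surfaces
  if (is.null(surf$endo))
    stop("pacing-site placement requires an 'endo' surface; pass explicit ",
         "stimulus locations for sheet/slab geometries")
  if (!lvOnly && is.null(surf$rv_endo))
    stop("the 19-site biventricular panel requires an RV endocardial ",
         "surface; use lvOnly = TRUE for the 17-site LV panel")
  nodeLab <- .nodeLabels(mesh)
  nd <- mesh@nodes
  endo <- surf$endo
  z <- nd[endo, 3]
  v <- (z - min(z)) / (max(z) - min(z))     # 0 apex .. 1 base
  th <- atan2(nd[endo, 2], nd[endo, 1])     # circumferential angle

  seg <- integer(length(endo))
  cap <- v < 0.10
  basal <- v >= 2 / 3
  mid <- v >= 1 / 3 & v < 2 / 3
  apical <- !cap & v < 1 / 3
  sec6 <- pmin(5L, pmax(0L, floor((th + pi) / (2 * pi / 6))))
  sec4 <- pmin(3L, pmax(0L, floor((th + pi) / (2 * pi / 4))))
  seg[basal] <- 1L + sec6[basal]
  seg[mid] <- 7L + sec6[mid]
  seg[apical] <- 13L + sec4[apical]
  seg[cap] <- 17L

  conductiveEndo <- endo[nodeLab[endo] != 2L]
  if (!length(conductiveEndo))
    stop("no conductive endocardial nodes")
  pick <- function(targetXYZ, pool) {
    d2 <- rowSums(sweep(nd[pool, , drop = FALSE], 2, targetXYZ, "-")^2)
    pool[which.min(d2)]
  }
  rows <- lapply(1:17, function(s) {
    nodes <- endo[seg == s]
    if (!length(nodes)) return(NULL)
    ctr <- colMeans(nd[nodes, , drop = FALSE])
    cand <- pick(ctr, nodes)
    relocated <- FALSE
    if (nodeLab[cand] == 2L) {            # centroid node inside scar
      cand <- pick(ctr, conductiveEndo)
      relocated <- TRUE
      message("site ", s, " relocated to the nearest conductive ",
              "endocardial node")
    }
    data.frame(site = as.character(s), node = cand,
               x = nd[cand, 1], y = nd[cand, 2], z = nd[cand, 3],
               relocated = relocated)
  })
  out <- do.call(rbind, rows)
  if (!lvOnly) {
    rv <- surf$rv_endo
    rvPool <- rv[nodeLab[rv] != 2L]
    apexN <- rvPool[which.min(nd[rvPool, 3])]
    otN <- rvPool[which.max(nd[rvPool, 3])]
    out <- rbind(out,
      data.frame(site = "RV_APEX", node = apexN, x = nd[apexN, 1],
                 y = nd[apexN, 2], z = nd[apexN, 3], relocated = FALSE),
      data.frame(site = "RV_OT", node = otN, x = nd[otN, 1],
                 y = nd[otN, 2], z = nd[otN, 3], relocated = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Stimulus onset times of a programmed-stimulation pulse train
#'
#' S1 onsets at 0, CL, ..., (nS1-1)*CL; each extrastimulus follows the
#' previous stimulus by its coupling interval.
#'
#' @param train a \code{\link{pulseTrain}}.
#' @param couplings numeric vector of current extrastimulus couplings
#'   (S2, S3, S4 ...), ms; may be empty.
#' @return numeric vector of stimulus onsets, ms, strictly increasing.
#' @export
#' @examples
#' schedulePulseTrain(pulseTrain(), couplings = c(300, 280))
schedulePulseTrain <- function(train, couplings = numeric(0)) {
  stopifnot(is(train, "PulseTrain"))
  if (length(couplings) > train@maxExtrastimuli)
    stop("at most ", train@maxExtrastimuli, " extrastimuli are allowed")
  if (any(couplings < train@minCoupling))
    stop("coupling interval below the ", train@minCoupling, " ms floor")
  s1 <- (seq_len(train@nS1) - 1L) * train@s1CL
  on <- c(s1, s1[length(s1)] + cumsum(couplings))
  stopifnot(all(diff(on) > 0))
  on
}

#' Detect capture of a stimulus
#'
#' A stimulus captured if tissue at 2-5 mm from the electrode centre
#' activates within 150 ms of the stimulus onset (an excitation wave was
#' initiated and propagated away from the pacing location). On meshes too
#' small to contain the probe shell, any activation outside the electrode
#' counts.
#'
#' @param recording a \code{\link{Recording}} covering
#'   \code{[stimOnset, stimOnset + 150]}.
#' @param mesh the simulated mesh.
#' @param center electrode centre, mm.
#' @param stimOnset stimulus onset, ms.
#' @param extent electrode cube edge, mm.
#' @return logical: captured or not.
#' @export
detectCapture <- function(recording, mesh, center, stimOnset, extent = 1) {
  stopifnot(is(recording, "Recording"))
  d <- sqrt(rowSums(sweep(mesh@nodes, 2, center, "-")^2))
  shell <- which(d >= 2 & d <= 5)
  if (!length(shell)) shell <- which(d > extent / 2)
  if (!length(shell)) stop("mesh too small to probe capture")
  any(vapply(recording@activations[shell], function(a)
    any(a > stimOnset & a <= stimOnset + 150), logical(1)))
}

#' Classify post-pacing activity and measure the VT cycle length
#'
#' Implements the arrhythmia trichotomy of the pacing protocol. Let T be
#' the time, measured from the last stimulus, of the last activation
#' anywhere in the tissue excluding the directly stimulus-evoked beat
#' (each node's first post-stimulus activation). The outcome is
#' NONINDUCIBLE when no re-activation occurs at all; SINGLE_BEAT when
#' re-entrant activity dies out with T <= 1000 ms (an incomplete
#' re-entry); UNSUSTAINED when T > 1000 ms but the tissue is quiescent
#' before the observation window closes; SUSTAINED when activity persists
#' to the end of the window (an activation within one \code{sustainedGap}
#' of the window end). For UNSUSTAINED/SUSTAINED outcomes the VT cycle
#' length is the median inter-activation interval at the 10 most
#' re-activated nodes over the final 1000 ms of activity.
#'
#' @param recording a \code{\link{Recording}} extending at least
#'   \code{window} ms past \code{tLastStim}.
#' @param tLastStim onset of the last delivered stimulus, ms.
#' @param window post-pacing observation window, ms (2000).
#' @param sustainedGap maximum quiescent gap before the window end still
#'   counted as persisting activity, ms.
#' @param minReactivationFraction the evoked beat is excluded by requiring
#'   a full re-activation of previously activated tissue: at least this
#'   fraction of the nodes reached by the evoked beat must activate a
#'   second time, otherwise local electrode wavelets do not count and the
#'   outcome is NONINDUCIBLE.
#' @return list with \code{classification} and \code{vtCycleLength} (ms,
#'   NA unless UNSUSTAINED or SUSTAINED).
#' @export
detectReentry <- function(recording, tLastStim, window = 2000,
                          sustainedGap = 300,
                          minReactivationFraction = 0.1) {
  stopifnot(is(recording, "Recording"))
  if (recording@tEnd < tLastStim + window - 1e-6)
    stop("recording must extend at least ", window, " ms past the last ",
         "stimulus (ends at ", recording@tEnd, " ms)")
  post <- lapply(recording@activations, function(a) a[a > tLastStim])
  reacts <- lapply(post, function(a) if (length(a) > 1L) a[-1L] else
    numeric(0))
  allRe <- unlist(reacts, use.names = FALSE)
  nEvoked <- sum(lengths(post) > 0L)
  nRe <- sum(lengths(reacts) > 0L)
  if (!length(allRe) || nRe < minReactivationFraction * nEvoked)
    return(list(classification = "NONINDUCIBLE",
                vtCycleLength = NA_real_))
  Tlast <- max(allRe)
  Trel <- Tlast - tLastStim
  if (Trel <= 1000)
    return(list(classification = "SINGLE_BEAT", vtCycleLength = NA_real_))
  cls <- if (Trel >= window - sustainedGap) "SUSTAINED" else "UNSUSTAINED"
  # cycle length at the 10 most re-activated nodes, final 1 s of activity
  counts <- lengths(reacts)
  topN <- order(counts, decreasing = TRUE)[seq_len(min(10L, sum(counts > 0)))]
  ivals <- unlist(lapply(topN, function(i) {
    a <- post[[i]]
    a <- a[a >= Tlast - 1000 & a <= Tlast]
    if (length(a) > 1L) diff(a) else numeric(0)
  }), use.names = FALSE)
  cl <- if (length(ivals)) stats::median(ivals) else NA_real_
  list(classification = cls, vtCycleLength = cl)
}

#' First-activation (isochrone) map for a time interval
#'
#' @param recording a \code{\link{Recording}}.
#' @param from,to interval bounds, ms.
#' @return numeric per-node local activation time (ms); nodes that do not
#'   activate in the interval (including scar) are NA.
#' @export
computeActivationMap <- function(recording, from = recording@tStart,
                                 to = recording@tEnd) {
  stopifnot(is(recording, "Recording"), from < to)
  lat <- vapply(recording@activations, function(a) {
    a <- a[a >= from & a <= to]
    if (length(a)) a[1] else NA_real_
  }, numeric(1))
  if (all(is.na(lat)))
    stop("no activations in the requested interval")
  lat
}

# merge two consecutive recordings of the same mesh (r2 continues r1)
.mergeRecordings <- function(r1, r2, lockout = 50) {
  act <- mapply(function(a, b) {
    if (length(a)) b <- b[b >= a[length(a)] + lockout]
    c(a, b)
  }, r1@activations, r2@activations, SIMPLIFY = FALSE)
  frames <- cbind(r1@frames, r2@frames)
  ft <- c(r1@frameTimes, r2@frameTimes)
  new("Recording", frames = frames, frameTimes = ft, activations = act,
      stimLog = rbind(r1@stimLog, r2@stimLog), finalState = r2@finalState,
      nodeLabels = r1@nodeLabels, tStart = r1@tStart, tEnd = r2@tEnd,
      dt = r1@dt)
}

#' Run the programmed-stimulation protocol at one pacing site
#'
#' Conditions the tissue with the S1 drive train (computed once and
#' checkpointed at the onset of the last S1 beat, so the decremental scan
#' restarts from the identical conditioned state), then scans the S2
#' coupling interval downward from 300 ms in 10 ms steps until re-entrant
#' arrhythmia is induced or S2 fails to capture; if no arrhythmia was
#' induced, S2 is frozen at its shortest capturing interval and S3 (then
#' S4) is scanned in the same manner.
#'
#' @param mesh,fibers,cond,cells,config as in \code{\link{runMonodomain}}.
#' @param center pacing electrode centre, mm.
#' @param train a \code{\link{pulseTrain}}.
#' @param amplitude stimulus amplitude, uA/uF (NA: 1.5 x strand threshold,
#'   computed once).
#' @param stimDuration stimulus pulse duration, ms.
#' @param window post-pacing observation window, ms.
#' @param recordFinal if TRUE, the recording of the inducing (or last)
#'   trial is returned with Vm frames sampled every
#'   \code{finalFrameInterval} ms.
#' @param finalFrameInterval frame sampling of the returned recording, ms.
#' @param verbose print scan progress.
#' @return list with \code{classification}, \code{vtCycleLength},
#'   \code{couplings} (the extrastimulus couplings of the inducing trial,
#'   or the deepest tested), \code{tested} (data.frame of all trials),
#'   \code{recording} (the final trial's \code{\link{Recording}} or NULL)
#'   and \code{tLastStim}.
#' @export
runSiteProtocol <- function(mesh, fibers, cond, cells, center,
                            train = pulseTrain(), config = simConfig(),
                            amplitude = NA_real_, stimDuration = 2,
                            window = 2000, recordFinal = FALSE,
                            finalFrameInterval = 10, verbose = FALSE) {
  if (is.null(cells$gz)) cells$gz <- makeGzParams(cells$normal)
  if (is.na(amplitude))
    amplitude <- 1.5 * strandDiastolicThreshold(cells$normal, cond, config,
                                                dx = mesh@resolution)
  quiet <- simConfig(dt = config@dt, outputInterval = Inf,
                     beta = config@beta, cm = config@cm,
                     actThreshold = config@actThreshold,
                     lockout = config@lockout)
  stim <- function(t) stimulusSpec(center = center, onset = t,
                                   amplitude = amplitude,
                                   duration = stimDuration)
  # S1 conditioning up to the onset of the last S1 beat
  s1on <- (seq_len(train@nS1) - 1L) * train@s1CL
  tCheck <- s1on[train@nS1]
  s1rec <- runMonodomain(mesh, fibers, cond, cells,
    stimuli = lapply(s1on[-train@nS1], stim),
    duration = tCheck, config = quiet)
  s1state <- s1rec@finalState

  tested <- data.frame(level = integer(0), coupling = numeric(0),
                       captured = logical(0), classification = character(0),
                       vtCycleLength = numeric(0))
  best <- list(classification = "NONINDUCIBLE", vtCycleLength = NA_real_,
               couplings = numeric(0))
  sev <- c(NONINDUCIBLE = 0, SINGLE_BEAT = 1, UNSUSTAINED = 2,
           SUSTAINED = 3)
  lastRec <- NULL; lastStimT <- NA_real_

  runTrial <- function(couplings, record = FALSE) {
    on <- tCheck + cumsum(c(0, couplings))   # last S1 + extrastimuli
    tLast <- on[length(on)]
    # stage 1: through last stimulus + capture probe window
    r1 <- runMonodomain(mesh, fibers, cond, cells,
      stimuli = lapply(on, stim), duration = tLast - tCheck + 160,
      config = quiet, state = s1state, tStart = tCheck)
    cap <- detectCapture(r1, mesh, center, tLast)
    if (!cap)
      return(list(captured = FALSE, classification = "NO_CAPTURE",
                  vtCycleLength = NA_real_, recording = NULL,
                  tLast = tLast))
    cfg2 <- if (record)
      simConfig(dt = config@dt, outputInterval = finalFrameInterval,
                beta = config@beta, cm = config@cm,
                actThreshold = config@actThreshold,
                lockout = config@lockout)
    else quiet
    # observe in chunks; once the tissue is quiescent (no activation in
    # the last chunk and every node repolarized) the remaining window
    # cannot contain activity, so it is skipped without changing any
    # activation time
    rec <- r1
    remaining <- window + 100 - 160
    chunk <- 500
    while (remaining > 1e-9) {
      d <- min(chunk, remaining)
      r2 <- runMonodomain(mesh, fibers, cond, cells, stimuli = list(),
        duration = d, config = cfg2, state = rec@finalState,
        tStart = rec@tEnd)
      quiescent <- sum(lengths(r2@activations)) == 0L &&
        max(r2@finalState[1, ]) < -70
      rec <- .mergeRecordings(rec, r2, lockout = config@lockout)
      remaining <- remaining - d
      if (quiescent) break
    }
    if (remaining > 0) rec@tEnd <- rec@tEnd + remaining
    out <- detectReentry(rec, tLast, window = window)
    c(out, list(captured = TRUE, recording = rec, tLast = tLast))
  }

  frozen <- numeric(0)
  for (level in seq_len(train@maxExtrastimuli)) {
    coupling <- train@prematureInitial
    shortestCapturing <- NA_real_
    while (coupling >= train@minCoupling) {
      tr <- runTrial(c(frozen, coupling), record = recordFinal)
      tested <- rbind(tested, data.frame(level = level + 1L,
        coupling = coupling, captured = tr$captured,
        classification = tr$classification,
        vtCycleLength = if (is.null(tr$vtCycleLength)) NA_real_ else
          tr$vtCycleLength))
      if (verbose)
        message("S", level + 1L, " = ", coupling, " ms: ",
                tr$classification)
      if (!tr$captured) break
      shortestCapturing <- coupling
      if (sev[tr$classification] > sev[best$classification]) {
        best <- list(classification = tr$classification,
                     vtCycleLength = tr$vtCycleLength,
                     couplings = c(frozen, coupling))
        lastRec <- tr$recording; lastStimT <- tr$tLast
      }
      if (tr$classification %in% c("UNSUSTAINED", "SUSTAINED")) {
        return(list(classification = tr$classification,
                    vtCycleLength = tr$vtCycleLength,
                    couplings = c(frozen, coupling), tested = tested,
                    recording = tr$recording, tLastStim = tr$tLast))
      }
      coupling <- coupling - train@decrement
    }
    if (is.na(shortestCapturing)) break   # nothing captures at this level
    frozen <- c(frozen, shortestCapturing)
  }
  list(classification = best$classification,
       vtCycleLength = best$vtCycleLength, couplings = best$couplings,
       tested = tested, recording = lastRec, tLastStim = lastStimT)
}

#' Run the full multi-site arrhythmia-induction test
#'
#' Applies \code{\link{runSiteProtocol}} at every pacing site and
#' aggregates the per-site outcomes into the overall inducibility call:
#' positive if re-entrant arrhythmia persisting more than 1 s (an
#' UNSUSTAINED or SUSTAINED episode) is elicited from at least one site.
#' A solver failure at a site is reported as FAILED, distinct from
#' NONINDUCIBLE.
#'
#' @param mesh,fibers,cond,cells,config as in \code{\link{runMonodomain}}.
#' @param sites data.frame as from \code{\link{placePacingSites}}, or a
#'   list of electrode-centre coordinate vectors.
#' @param train a \code{\link{pulseTrain}}.
#' @param amplitude stimulus amplitude (NA: 1.5 x strand threshold,
#'   computed once and shared by all sites).
#' @param window post-pacing observation window, ms.
#' @param seed provenance seed recorded in the result.
#' @param verbose print progress.
#' @return a \code{\link{VarpResult}}.
#' @export
runVarp <- function(mesh, fibers, cond = conductivities(),
                    cells = list(normal = cellParams()), sites,
                    train = pulseTrain(), config = simConfig(),
                    amplitude = NA_real_, window = 2000, seed = NA,
                    verbose = FALSE) {
  if (is.null(cells$gz)) cells$gz <- makeGzParams(cells$normal)
  if (is.data.frame(sites)) {
    centers <- lapply(seq_len(nrow(sites)), function(i)
      unlist(sites[i, intersect(c("x", "y", "z"), names(sites))]))
    labels <- as.character(sites$site)
  } else {
    centers <- sites
    labels <- if (!is.null(names(sites))) names(sites) else
      as.character(seq_along(sites))
  }
  if (is.na(amplitude))
    amplitude <- 1.5 * strandDiastolicThreshold(cells$normal, cond, config,
                                                dx = mesh@resolution)
  rows <- lapply(seq_along(centers), function(i) {
    if (verbose) message("site ", labels[i])
    out <- tryCatch(
      runSiteProtocol(mesh, fibers, cond, cells, centers[[i]],
                      train = train, config = config,
                      amplitude = amplitude, window = window,
                      verbose = verbose),
      error = function(e) {
        warning("site ", labels[i], " failed: ", conditionMessage(e))
        list(classification = "FAILED", vtCycleLength = NA_real_,
             couplings = numeric(0))
      })
    data.frame(site = labels[i], classification = out$classification,
               vtCycleLength = out$vtCycleLength,
               couplings = paste(out$couplings, collapse = "/"))
  })
  sitesDf <- do.call(rbind, rows)
  pos <- any(sitesDf$classification %in% c("UNSUSTAINED", "SUSTAINED"))
  new("VarpResult", sites = sitesDf,
      overall = if (pos) "positive" else "negative",
      provenance = list(seed = seed, nSites = nrow(sitesDf),
                        train = c(nS1 = train@nS1, s1CL = train@s1CL,
                                  premature = train@prematureInitial,
                                  decrement = train@decrement)))
}

#' Schedule of a multi-model induction study
#'
#' Enumerates the per-site simulations of a cohort study: one programmed
#' stimulation run per model and pacing site.
#'
#' @param nModels number of tissue models in the cohort.
#' @param siteLabels pacing-site labels (default: the 19-site
#'   biventricular panel: AHA segments 1-17 plus RV apex and RV
#'   outflow-region sites).
#' @return data.frame with one row per scheduled simulation.
#' @export
#' @examples
#' nrow(planVarpStudy(41))   # 779
planVarpStudy <- function(nModels,
                          siteLabels = c(as.character(1:17),
                                         "RV_APEX", "RV_OT")) {
  stopifnot(nModels >= 1)
  expand.grid(model = seq_len(nModels), site = siteLabels,
              stringsAsFactors = FALSE)
}

#' Serialize / summarize an induction-test result
#'
#' @param result a \code{\link{VarpResult}}.
#' @param path optional path: the machine-readable JSON summary is written
#'   there.
#' @return invisibly, the JSON string of the stable-schema summary.
#' @export
varpReport <- function(result, path = NULL) {
  stopifnot(is(result, "VarpResult"))
  df <- result@sites
  cat(sprintf("Inducibility test: %s\n", toupper(result@overall)))
  for (i in seq_len(nrow(df)))
    cat(sprintf("  site %-8s %-13s%s%s\n", df$site[i],
                df$classification[i],
                ifelse(is.na(df$vtCycleLength[i]), "",
                       sprintf(" CL = %.0f ms", df$vtCycleLength[i])),
                ifelse(nzchar(df$couplings[i]),
                       paste0("  [", df$couplings[i], "]"), "")))
  js <- jsonlite::toJSON(list(
    overall = result@overall,
    sites = df,
    provenance = result@provenance), dataframe = "rows", auto_unbox = TRUE,
    na = "null", digits = NA)
  if (!is.null(path)) writeLines(js, path)
  invisible(as.character(js))
}

#' Parse a serialized induction-test summary
#'
#' Round-trip counterpart of \code{\link{varpReport}}.
#'
#' @param json JSON string or file path.
#' @return a \code{\link{VarpResult}}.
#' @export
parseVarpReport <- function(json) {
  x <- jsonlite::fromJSON(json)
  df <- x$sites
  df$vtCycleLength <- as.numeric(ifelse(is.na(df$vtCycleLength) |
    vapply(df$vtCycleLength, is.null, logical(1)), NA, df$vtCycleLength))
  new("VarpResult", sites = df, overall = x$overall,
      provenance = as.list(x$provenance))
}
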