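# shared fixtures, built in code

smallSheet <- function(n = 20, dx = 0.35) generateSheet(n, n, dx)

sheetFibersX <- function(mesh) assignFibers(mesh, constantDirection = c(1, 0))

# a sheet with a central circular scar and GZ rim
infarctedSheet <- function(n = 40, dx = 0.5, rScar = 5, rim = 2) {
  mesh <- generateSheet(n, n, dx)
  ctr <- rep(n * dx / 2, 2)
  addInfarct(mesh, infarctSpec(center = ctr, radii = c(rScar, rScar),
                               gzRimWidth = rim))
}

# synthetic Recording carrying prescribed activation lists
syntheticRecording <- function(activations, tStart = 0, tEnd = 3000,
                               labels = NULL) {
  n <- length(activations)
  if (is.null(labels)) labels <- rep(0L, n)
  new("Recording", frames = matrix(numeric(0), n, 0),
      frameTimes = numeric(0), activations = activations,
      stimLog = data.frame(onset = numeric(0), duration = numeric(0),
                           amplitude = numeric(0), nNodes = integer(0)),
      finalState = matrix(-85, 19, n), nodeLabels = labels,
      tStart = tStart, tEnd = tEnd, dt = 0.025)
}

# element-adjacency connectivity check on a label subset (flood fill)
labelsConnected <- function(mesh, which_lab) {
  el <- meshElements(mesh)
  keep <- which(as.integer(tissueLabels(mesh)) - 1L == which_lab)
  if (length(keep) < 2) return(TRUE)
  byNode <- split(rep(seq_along(keep), ncol(el)),
                  as.vector(el[keep, , drop = FALSE]))
  seen <- logical(length(keep))
  queue <- 1L; seen[1L] <- TRUE
  elNodes <- el[keep, , drop = FALSE]
  while (length(queue)) {
    e <- queue[1]; queue <- queue[-1]
    nb <- unique(unlist(byNode[as.character(elNodes[e, ])],
                        use.names = FALSE))
    new <- nb[!seen[nb]]
    seen[new] <- TRUE
    queue <- c(queue, new)
  }
  all(seen)
}
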