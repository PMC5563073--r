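## Run-and-pause motion engine.
##
## Granule motion is modeled as a discrete-time Markov chain on the frame
## grid: during a run the granule advances by v * dt each frame, during a
## pause it holds position. Run dwell times are geometric with mean runMeanS;
## natural pauses last a single frame, and runs are kept long enough that
## consecutive pauses are separated by more than one granule diameter.
## Together these guarantee that no natural dwell window can satisfy the
## >= 10 s docking criterion: docking events in simulated data are exactly
## the docks the generator inserts. Bi-directional granules flip run
## direction after every run, guaranteeing >= 1 reversal per 60 s window.

## Per-frame step velocities (um/s), length nSteps.
motionSteps <- function(class, nSteps, dtS, kin) {
  if (class == "stationary" || nSteps < 1L) return(numeric(nSteps))
  vA <- kin@vAntero / 60
  vR <- kin@vRetro / 60
  runMeanFrames <- max(kin@runMeanS / dtS, 1)
  ## shortest run separating two pauses by > granuleDiameter
  minRunFrames <- floor(kin@granuleDiameter / (min(vA, vR) * dtS)) + 1L
  dir <- switch(class,
    anterograde = 1, retrograde = -1,
    bidirectional = sample(c(-1, 1), 1L))
  steps <- numeric(0)
  while (length(steps) < nSteps) {
    run <- minRunFrames + rgeom(1L, 1 / max(runMeanFrames - minRunFrames, 1))
    v <- if (dir > 0) vA else -vR
    steps <- c(steps, rep(v, run), 0)
    if (class == "bidirectional") dir <- -dir
  }
  steps[seq_len(nSteps)]
}

sampleClasses <- function(n, kin) {
  sample(c("anterograde", "retrograde", "bidirectional", "stationary"),
         n, replace = TRUE,
         prob = c(kin@fracAntero, kin@fracRetro, kin@fracBidir,
                  kin@fracStationary))
}

#' Simulate granule tracks with known motility classes
#'
#' Generates `n` granule tracks on an unbounded shaft axis with the
#' run-and-pause kinetics of a [GranuleKinetics-class] preset and no
#' protrusion/dock coupling. This is the population used for
#' parameter-recovery of the motility classifier, the speed estimators and
#' their Monte-Carlo tests. Tracks start at s = 0 (positions are relative);
#' identical seeds give identical output.
#'
#' @param n number of granules.
#' @param kinetics a [GranuleKinetics-class] preset.
#' @param durationS track duration, s.
#' @param frameIntervalS frame interval, s.
#' @param seed integer seed.
#' @return list with elements `tracks` (data.frame: granule_id, frame, t_s,
#'   s_um, x_px, y_px, on_shaft) and `classes` (data.frame: granule_id,
#'   class) holding the ground-truth class labels.
#' @examples
#' sim <- simulateTracks(5, granuleKinetics(), durationS = 60, seed = 1)
#' table(sim$classes$class)
#' @export
simulateTracks <- function(n, kinetics = granuleKinetics(), durationS = 120,
                           frameIntervalS = 3, seed = 1) {
  stopifnot(is(kinetics, "GranuleKinetics"))
  validObject(kinetics)
  withSeed(seed, {
    nFrames <- floor(durationS / frameIntervalS) + 1L
    tS <- (seq_len(nFrames) - 1L) * frameIntervalS
    classes <- sampleClasses(n, kinetics)
    res <- vector("list", n)
    for (i in seq_len(n)) {
      steps <- motionSteps(classes[i], nFrames - 1L, frameIntervalS, kinetics)
      s <- cumsum(c(0, steps * frameIntervalS)) +
        rnorm(nFrames, 0, kinetics@jitterSd)
      res[[i]] <- data.frame(
        granule_id = sprintf("g%04d", i), frame = seq_len(nFrames),
        t_s = tS, s_um = s, x_px = s / 0.118, y_px = 0, on_shaft = TRUE)
    }
    list(tracks = do.call(rbind, res),
         classes = data.frame(granule_id = sprintf("g%04d", seq_len(n)),
                              class = classes))
  })
}
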