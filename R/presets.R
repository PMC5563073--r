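#' Construct an axon terminal geometry
#'
#' By default a straight 100 um terminal shaft sampled at 118 nm pixels and a
#' 3 s frame interval, matching fast time-lapse imaging of retinal ganglion
#' cell (RGC) axon terminals. The arc-length coordinate `s` is 0 at the
#' proximal end and increases distally (anterograde = increasing `s`).
#'
#' @param terminalLength length of the analyzed terminal segment, um.
#' @param pixelSize um per pixel.
#' @param frameInterval seconds per frame.
#' @param shaft optional n x 2 matrix of centerline points (um); defaults to a
#'   straight horizontal line of length `terminalLength`.
#' @param shaftOffset y position (um) of the default straight shaft.
#' @return an [AxonGeometry-class] object.
#' @examples
#' axonGeometry()
#' @export
axonGeometry <- function(terminalLength = 100, pixelSize = 0.118,
                         frameInterval = 3, shaft = NULL, shaftOffset = 5) {
  if (is.null(shaft))
    shaft <- cbind(c(0, terminalLength), c(shaftOffset, shaftOffset))
  new("AxonGeometry", shaft = shaft, terminalLength = terminalLength,
      pixelSize = pixelSize, frameInterval = frameInterval)
}

#' Construct a granule kinetics preset
#'
#' Defaults are the trafficking statistics of endogenously labeled RNA
#' granules in RGC axon terminals in vivo: 2.6 granules/10 um, anterograde
#' runs at 10.0 um/min, retrograde at 11.4 um/min, and per-minute motility
#' fractions 25.6% anterograde / 27.7% retrograde / 5.9% bi-directional /
#' 40.8% stationary.
#'
#' The remaining arguments parameterize the run-and-pause motion model of the
#' simulator. Pauses are kept shorter than the 10 s docking threshold so that
#' docking events are exactly the docks the generator inserts; stationary
#' granules are placed in small clusters (shared sites), reflecting the
#' accumulation of immobile granules at a few hotspots per terminal.
#'
#' @param densityPer10um granules per 10 um.
#' @param vAntero,vRetro run speed, um/min.
#' @param fracAntero,fracRetro,fracBidir,fracStationary motility fractions
#'   (must sum to 1 within 1e-9).
#' @param granuleDiameter granule diameter, um.
#' @param runMeanS mean run duration, s.
#' @param pauseMeanS mean pause duration, s (capped below the docking
#'   threshold by the simulator).
#' @param jitterSd positional jitter SD, um.
#' @param stationaryClusterSize stationary granules per shared site.
#' @return a [GranuleKinetics-class] object.
#' @examples
#' granuleKinetics()
#' @export
granuleKinetics <- function(densityPer10um = 2.6, vAntero = 10.0,
                            vRetro = 11.4, fracAntero = 0.256,
                            fracRetro = 0.277, fracBidir = 0.059,
                            fracStationary = 0.408, granuleDiameter = 1.0,
                            runMeanS = 12, pauseMeanS = 4, jitterSd = 0.03,
                            stationaryClusterSize = 3) {
  new("GranuleKinetics", densityPer10um = densityPer10um, vAntero = vAntero,
      vRetro = vRetro, fracAntero = fracAntero, fracRetro = fracRetro,
      fracBidir = fracBidir, fracStationary = fracStationary,
      granuleDiameter = granuleDiameter, runMeanS = runMeanS,
      pauseMeanS = pauseMeanS, jitterSd = jitterSd,
      stationaryClusterSize = stationaryClusterSize)
}

#' Construct a branch-event / docking-coupling preset
#'
#' Defaults reproduce the published protrusion and docking statistics: 50
#' filopodia and 8 branches added (and removed) per 10 min on the terminal
#' 50 um; 84% of protrusions preceded by a docked granule in the 10 s before
#' emergence; 22.0% of docking events followed by protrusion emergence; docks
#' found at 16% of random (position, time) sites; docking threshold 10 s.
#'
#' @param pDockGivenProtrusion probability a protrusion has a coupled dock.
#' @param pProtrusionGivenDock probability a docking event is followed by a
#'   protrusion.
#' @param backgroundSiteDockCoverage dock coverage of random sites.
#' @param dockMinDurationS docking duration threshold, s (use 60 for
#'   mitochondria).
#' @param filopodiaAddRate,branchAddRate additions per 10 min on the terminal
#'   50 um.
#' @param filopodiaLifetimeS,branchLifetimeS mean lifetimes, s.
#' @param dockDurationRangeS (min, max) duration of inserted docks, s.
#' @param birthDelayRangeS (min, max) delay from coupled-dock onset to
#'   protrusion birth, s; kept well below the 10 s association window.
#' @return a [BranchKinetics-class] object.
#' @examples
#' branchKinetics()
#' @export
branchKinetics <- function(pDockGivenProtrusion = 0.84,
                           pProtrusionGivenDock = 0.22,
                           backgroundSiteDockCoverage = 0.16,
                           dockMinDurationS = 10,
                           filopodiaAddRate = 50, branchAddRate = 8,
                           filopodiaLifetimeS = 120, branchLifetimeS = 300,
                           dockDurationRangeS = c(12, 18),
                           birthDelayRangeS = c(1, 2.5)) {
  new("BranchKinetics", pDockGivenProtrusion = pDockGivenProtrusion,
      pProtrusionGivenDock = pProtrusionGivenDock,
      backgroundSiteDockCoverage = backgroundSiteDockCoverage,
      dockMinDurationS = dockMinDurationS,
      filopodiaAddRate = filopodiaAddRate, branchAddRate = branchAddRate,
      filopodiaLifetimeS = filopodiaLifetimeS,
      branchLifetimeS = branchLifetimeS,
      dockDurationRangeS = dockDurationRangeS,
      birthDelayRangeS = birthDelayRangeS)
}

#' FRAP presets
#'
#' Named presets for the simulated FRAP experiments:
#' \describe{
#'   \item{venus_bactin}{fast recovery of a translated Venus-beta-actin
#'     reporter, anchored at 18.6% recovery 5 min post-bleach (tau = 100 s),
#'     1 Hz acquisition for 300 s.}
#'   \item{venus_control}{slow recovery of the Venus-only control, anchored at
#'     4.8% recovery 10 min post-bleach (tau = 200 s), 30 s interval for
#'     600 s.}
#'   \item{venus_bactin_chx}{translation-inhibited (cycloheximide) variant:
#'     plateau suppressed to 0.03.}
#' }
#'
#' @param name preset name, or an arbitrary label when the other parameters
#'   are supplied explicitly.
#' @param tauS recovery time constant, s.
#' @param anchorTimeS,anchorFraction recovery anchor pinning the plateau
#'   amplitude A = fraction / (1 - exp(-time/tau)).
#' @param frameIntervalS,durationS post-bleach acquisition protocol.
#' @param hotspotMode "uniform" or "focal_at_docks".
#' @param hotspotSigmaPx Gaussian hotspot width, px.
#' @param noiseSd relative intensity noise SD.
#' @param bleachRate per-frame multiplicative acquisition bleaching
#'   (default 0: the anchors are as-measured recoveries).
#' @return a [FrapModel-class] object.
#' @examples
#' frapModel("venus_bactin")
#' frapModel("venus_control")
#' @export
frapModel <- function(name = c("venus_bactin", "venus_control",
                               "venus_bactin_chx"),
                      tauS = NULL, anchorTimeS = NULL, anchorFraction = NULL,
                      frameIntervalS = NULL, durationS = NULL,
                      hotspotMode = "uniform", hotspotSigmaPx = 8,
                      noiseSd = 0.02, bleachRate = 0) {
  if (is.null(tauS)) {
    name <- match.arg(name)
    def <- switch(name,
      venus_bactin = list(tau = 100, at = 300, af = 0.186, dt = 1, dur = 300),
      venus_control = list(tau = 200, at = 600, af = 0.048, dt = 30, dur = 600),
      venus_bactin_chx = list(tau = 100, at = 300,
                              af = 0.03 * (1 - exp(-3)), dt = 1, dur = 300))
    tauS <- def$tau; anchorTimeS <- def$at; anchorFraction <- def$af
    if (is.null(frameIntervalS)) frameIntervalS <- def$dt
    if (is.null(durationS)) durationS <- def$dur
  }
  new("FrapModel", name = name, tauS = tauS, anchorTimeS = anchorTimeS,
      anchorFraction = anchorFraction, frameIntervalS = frameIntervalS,
      durationS = durationS, hotspotMode = hotspotMode,
      hotspotSigmaPx = hotspotSigmaPx, noiseSd = noiseSd,
      bleachRate = bleachRate)
}

#' Plateau amplitude implied by a FRAP preset's recovery anchor
#'
#' The noiseless recovery curve is R(t) = A (1 - exp(-t/tau)) with
#' A = anchorFraction / (1 - exp(-anchorTimeS/tauS)), so that R at the anchor
#' time equals the anchor fraction exactly.
#'
#' @param model a [FrapModel-class].
#' @return plateau amplitude A (fraction of pre-bleach fluorescence).
#' @examples
#' recoveryPlateau(frapModel("venus_bactin"))  # 0.186/(1 - exp(-3)) = 0.1958
#' @export
recoveryPlateau <- function(model) {
  stopifnot(is(model, "FrapModel"))
  model@anchorFraction / (1 - exp(-model@anchorTimeS / model@tauS))
}
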