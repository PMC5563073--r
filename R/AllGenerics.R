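#' @rdname AxonRecording-class
#' @param x an object with a geometry/track/protrusion component.
#' @export
setGeneric("geometry", function(x) standardGeneric("geometry"))

#' @rdname AxonRecording-class
#' @export
setGeneric("tracks", function(x) standardGeneric("tracks"))

#' @rdname AxonRecording-class
#' @export
setGeneric("protrusions", function(x) standardGeneric("protrusions"))

#' @rdname AxonRecording-class
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' @rdname ArborTrace-class
#' @param x an [ArborTrace-class].
#' @export
setGeneric("branches", function(x) standardGeneric("branches"))

#' @rdname aci
#' @export
setGeneric("aci", function(x) standardGeneric("aci"))

#' @rdname branchStats
#' @export
setGeneric("branchStats", function(x) standardGeneric("branchStats"))

#' @rdname normalizeRecovery
#' @export
setGeneric("normalizeRecovery", function(x, ...) standardGeneric("normalizeRecovery"))

#' @rdname fviSeries
#' @export
setGeneric("fviSeries", function(x, ...) standardGeneric("fviSeries"))

setMethod("geometry", "AxonRecording", function(x) x@geometry)
setMethod("tracks", "AxonRecording", function(x) x@tracks)
setMethod("protrusions", "AxonRecording", function(x) x@protrusions)
setMethod("groundTruth", "AxonRecording", function(x) x@truth)
setMethod("branches", "ArborTrace", function(x) x@branches)

setMethod("show", "AxonGeometry", function(object) {
  cat(sprintf("AxonGeometry: terminal %.1f um, pixel %.3f um, frame %.1f s\n",
              object@terminalLength, object@pixelSize, object@frameInterval))
})

setMethod("show", "GranuleKinetics", function(object) {
  cat(sprintf(paste0(
    "GranuleKinetics: %.2f granules/10 um\n",
    "  speeds (um/min): antero %.1f, retro %.1f\n",
    "  fractions: antero %.3f, retro %.3f, bidir %.3f, stationary %.3f\n"),
    object@densityPer10um, object@vAntero, object@vRetro, object@fracAntero,
    object@fracRetro, object@fracBidir, object@fracStationary))
})

setMethod("show", "BranchKinetics", function(object) {
  cat(sprintf(paste0(
    "BranchKinetics: %.0f filopodia + %.0f branches per 10 min\n",
    "  P(dock | protrusion) = %.2f, P(protrusion | dock) = %.2f,",
    " background coverage = %.2f\n  dock >= %.0f s\n"),
    object@filopodiaAddRate, object@branchAddRate, object@pDockGivenProtrusion,
    object@pProtrusionGivenDock, object@backgroundSiteDockCoverage,
    object@dockMinDurationS))
})

setMethod("show", "FrapModel", function(object) {
  A <- object@anchorFraction / (1 - exp(-object@anchorTimeS / object@tauS))
  cat(sprintf(paste0(
    "FrapModel '%s': tau = %.0f s, anchor R(%.0f s) = %.3f (plateau A = %.4f)\n",
    "  mode %s, noise %.3f, %d s at %.0f s/frame\n"),
    object@name, object@tauS, object@anchorTimeS, object@anchorFraction, A,
    object@hotspotMode, object@noiseSd, as.integer(object@durationS),
    object@frameIntervalS))
})

setMethod("show", "AxonRecording", function(object) {
  cat(sprintf(paste0(
    "AxonRecording: %d granules (%d track rows), %d protrusions, %d true docks\n",
    "  %.0f s at %.1f s/frame on %.0f um\n"),
    length(unique(object@tracks$granule_id)), nrow(object@tracks),
    nrow(object@protrusions),
    if (is.null(object@truth$docks)) 0L else nrow(object@truth$docks),
    max(object@tracks$t_s, 0), object@geometry@frameInterval,
    object@geometry@terminalLength))
})

setMethod("show", "FrapSeries", function(object) {
  cat(sprintf(paste0(
    "FrapSeries: %d x %d px, %d pre- + %d post-bleach frames (%.0f s)\n",
    "  roi %d px, shaft %d px, branch %d px, background %d px\n"),
    nrow(object@roiMask), ncol(object@roiMask), dim(object@preBleach)[3],
    dim(object@postBleach)[3], max(object@tS), sum(object@roiMask),
    sum(object@shaftMask), sum(object@branchMask), sum(object@backgroundMask)))
})

setMethod("show", "ArborTrace", function(object) {
  b <- object@branches
  cat(sprintf("ArborTrace: %d nodes, %d branches (max order %s), total length %.1f um\n",
              nrow(object@nodes), nrow(b),
              if (nrow(b)) max(b$order) else "-",
              sum(b$length_um)))
})
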