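#' @import methods
NULL

#' Axon terminal geometry
#'
#' Describes the analyzed terminal segment of an axon: the shaft centerline as
#' a 2D polyline, the length of the terminal segment under analysis, and the
#' acquisition metadata (pixel size, frame interval). The arc-length coordinate
#' `s` runs from 0 at the proximal end of the analyzed segment and increases
#' distally, so anterograde transport is movement toward increasing `s`.
#'
#' @slot shaft numeric matrix (n x 2) of shaft centerline points, in um.
#' @slot terminalLength length (um) of the analyzed terminal segment.
#' @slot pixelSize um per pixel.
#' @slot frameInterval seconds per frame.
#' @exportClass AxonGeometry
setClass("AxonGeometry",
  representation(shaft = "matrix", terminalLength = "numeric",
                 pixelSize = "numeric", frameInterval = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!is.numeric(object@shaft) || ncol(object@shaft) != 2L ||
        nrow(object@shaft) < 2L)
      msg <- c(msg, "shaft must be a numeric matrix with >= 2 points")
    else if (polylineArcLength(object@shaft)[nrow(object@shaft)] <
             object@terminalLength - 1e-9)
      msg <- c(msg, "shaft arc length must be >= terminalLength")
    if (length(object@terminalLength) != 1L || object@terminalLength <= 0)
      msg <- c(msg, "terminalLength must be a positive scalar")
    if (length(object@pixelSize) != 1L || object@pixelSize <= 0)
      msg <- c(msg, "pixelSize must be > 0")
    if (length(object@frameInterval) != 1L || object@frameInterval <= 0)
      msg <- c(msg, "frameInterval must be > 0")
    if (length(msg)) msg else TRUE
  })

#' Granule transport kinetics preset
#'
#' Population statistics of RNA granule trafficking in the axon terminal:
#' linear density, mean run speeds by direction, and the per-minute motility
#' class fractions. Also carries the microscopic parameters of the
#' run-and-pause motion model used by the simulator (run/pause dwell times,
#' positional jitter, spatial clustering of stationary granules); these are
#' simulator internals whose defaults are chosen so that the window-based
#' estimators recover the preset statistics.
#'
#' @slot densityPer10um granules per 10 um of shaft.
#' @slot vAntero,vRetro mean run speed, um/min.
#' @slot fracAntero,fracRetro,fracBidir,fracStationary motility class
#'   probabilities (must sum to 1).
#' @slot granuleDiameter granule diameter, um (docking envelope).
#' @slot runMeanS,pauseMeanS mean run and pause dwell time, s.
#' @slot jitterSd positional jitter SD, um.
#' @slot stationaryClusterSize number of stationary granules sharing a site.
#' @exportClass GranuleKinetics
setClass("GranuleKinetics",
  representation(densityPer10um = "numeric", vAntero = "numeric",
                 vRetro = "numeric", fracAntero = "numeric",
                 fracRetro = "numeric", fracBidir = "numeric",
                 fracStationary = "numeric", granuleDiameter = "numeric",
                 runMeanS = "numeric", pauseMeanS = "numeric",
                 jitterSd = "numeric", stationaryClusterSize = "numeric"),
  validity = function(object) {
    msg <- character()
    fr <- c(object@fracAntero, object@fracRetro, object@fracBidir,
            object@fracStationary)
    if (any(fr < 0)) msg <- c(msg, "class fractions must be >= 0")
    if (abs(sum(fr) - 1) > 1e-9)
      msg <- c(msg, "class fractions must sum to 1 (tolerance 1e-9)")
    if (object@vAntero <= 0 || object@vRetro <= 0)
      msg <- c(msg, "speeds must be > 0")
    if (object@densityPer10um < 0) msg <- c(msg, "density must be >= 0")
    if (object@granuleDiameter <= 0) msg <- c(msg, "granuleDiameter must be > 0")
    if (object@runMeanS <= 0 || object@pauseMeanS <= 0)
      msg <- c(msg, "run/pause dwell times must be > 0")
    if (object@jitterSd < 0) msg <- c(msg, "jitterSd must be >= 0")
    if (object@stationaryClusterSize < 1)
      msg <- c(msg, "stationaryClusterSize must be >= 1")
    if (length(msg)) msg else TRUE
  })

#' Branch event / docking coupling preset
#'
#' Rates of protrusion addition and the three dock-protrusion association
#' probabilities that the generator is calibrated to reproduce: the
#' probability that a protrusion is preceded by a coupled dock, the
#' probability that a docking event is followed by protrusion emergence, and
#' the background fraction of random (position, time) sites covered by a dock.
#'
#' @slot pDockGivenProtrusion probability a protrusion has a coupled dock.
#' @slot pProtrusionGivenDock probability a dock is followed by a protrusion.
#' @slot backgroundSiteDockCoverage dock coverage of random sites.
#' @slot dockMinDurationS docking duration threshold, s (10 for RNA).
#' @slot filopodiaAddRate,branchAddRate events per 10 min on the terminal
#'   50 um.
#' @slot filopodiaLifetimeS,branchLifetimeS mean protrusion lifetime, s.
#' @slot dockDurationRangeS range (min, max) of inserted dock durations, s.
#' @slot birthDelayRangeS range of delay between coupled-dock onset and
#'   protrusion birth, s.
#' @exportClass BranchKinetics
setClass("BranchKinetics",
  representation(pDockGivenProtrusion = "numeric",
                 pProtrusionGivenDock = "numeric",
                 backgroundSiteDockCoverage = "numeric",
                 dockMinDurationS = "numeric",
                 filopodiaAddRate = "numeric", branchAddRate = "numeric",
                 filopodiaLifetimeS = "numeric", branchLifetimeS = "numeric",
                 dockDurationRangeS = "numeric",
                 birthDelayRangeS = "numeric"),
  validity = function(object) {
    msg <- character()
    pr <- c(object@pDockGivenProtrusion, object@pProtrusionGivenDock,
            object@backgroundSiteDockCoverage)
    if (any(pr < 0 | pr > 1)) msg <- c(msg, "probabilities must be in [0, 1]")
    if (object@dockMinDurationS <= 0) msg <- c(msg, "dockMinDurationS must be > 0")
    if (object@filopodiaAddRate < 0 || object@branchAddRate < 0)
      msg <- c(msg, "addition rates must be >= 0")
    if (length(object@dockDurationRangeS) != 2L ||
        diff(object@dockDurationRangeS) < 0 ||
        object@dockDurationRangeS[1] < object@dockMinDurationS)
      msg <- c(msg, "dockDurationRangeS must be (min, max) with min >= dockMinDurationS")
    if (length(object@birthDelayRangeS) != 2L || any(object@birthDelayRangeS < 0) ||
        diff(object@birthDelayRangeS) < 0)
      msg <- c(msg, "birthDelayRangeS must be a nonnegative (min, max) pair")
    if (length(msg)) msg else TRUE
  })

#' FRAP protocol / recovery preset
#'
#' Parameterizes a simulated FRAP experiment: the exponential recovery time
#' constant, the printed (time, fraction) recovery anchor that pins the
#' plateau amplitude A = fraction / (1 - exp(-time/tau)), the spatial mode of
#' recovery (uniform or focal hotspots at dock sites), and acquisition noise.
#'
#' @slot name preset label.
#' @slot tauS exponential time constant, s.
#' @slot anchorTimeS,anchorFraction recovery anchor: R(anchorTimeS) equals
#'   anchorFraction for the noiseless series.
#' @slot frameIntervalS acquisition interval of the post-bleach series, s.
#' @slot durationS post-bleach duration, s.
#' @slot hotspotMode "uniform" or "focal_at_docks".
#' @slot hotspotSigmaPx Gaussian hotspot width, px.
#' @slot noiseSd relative intensity noise SD.
#' @slot bleachRate per-frame multiplicative acquisition bleaching.
#' @exportClass FrapModel
setClass("FrapModel",
  representation(name = "character", tauS = "numeric", anchorTimeS = "numeric",
                 anchorFraction = "numeric", frameIntervalS = "numeric",
                 durationS = "numeric", hotspotMode = "character",
                 hotspotSigmaPx = "numeric", noiseSd = "numeric",
                 bleachRate = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@tauS <= 0) msg <- c(msg, "tauS must be > 0")
    if (object@anchorFraction >= 1 || object@anchorFraction <= 0)
      msg <- c(msg, "anchor fraction must be in (0, 1)")
    A <- object@anchorFraction / (1 - exp(-object@anchorTimeS / object@tauS))
    if (!(A > 0 && A < 1))
      msg <- c(msg, sprintf("derived plateau A = %.4f must lie in (0, 1)", A))
    if (!object@hotspotMode %in% c("uniform", "focal_at_docks"))
      msg <- c(msg, "hotspotMode must be 'uniform' or 'focal_at_docks'")
    if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
    if (object@bleachRate < 0 || object@bleachRate >= 1)
      msg <- c(msg, "bleachRate must be in [0, 1)")
    if (length(msg)) msg else TRUE
  })

#' A simulated axon time-lapse recording with ground truth
#'
#' Container returned by [simulateAxon()]: the granule track table, the
#' protrusion event table, the geometry and presets used, and the generator's
#' ground-truth bookkeeping (true docks with couplings, true class labels,
#' rates, seed) used by parameter-recovery tests.
#'
#' @slot geometry an [AxonGeometry-class].
#' @slot tracks data.frame with columns granule_id, frame, t_s, s_um, x_px,
#'   y_px, on_shaft.
#' @slot protrusions data.frame with one row per protrusion event.
#' @slot truth list of ground-truth annotations.
#' @exportClass AxonRecording
setClass("AxonRecording",
  representation(geometry = "AxonGeometry", tracks = "data.frame",
                 protrusions = "data.frame", truth = "list"),
  validity = function(object) {
    msg <- character()
    need <- c("granule_id", "frame", "t_s", "s_um", "x_px", "y_px")
    if (!all(need %in% names(object@tracks)))
      msg <- c(msg, paste("tracks must have columns:", paste(need, collapse = ", ")))
    needP <- c("protrusion_id", "birth_s", "death_s", "origin_s_um", "max_length_um")
    if (nrow(object@protrusions) > 0 && !all(needP %in% names(object@protrusions)))
      msg <- c(msg, paste("protrusions must have columns:", paste(needP, collapse = ", ")))
    td <- object@truth$docks
    if (!is.null(td) && nrow(td) > 0) {
      cp <- td$coupled_protrusion_id
      known <- object@protrusions$protrusion_id
      if (any(!is.na(cp) & !(cp %in% known)))
        msg <- c(msg, "every coupled_protrusion_id must exist in protrusions")
      if (any(td$flagged & (td$end_s - td$start_s) < object@truth$rates$dock_min_duration_s - 1e-9))
        msg <- c(msg, "flagged true docks must satisfy the minimum duration")
    }
    if (length(msg)) msg else TRUE
  })

#' A FRAP image time series with masks
#'
#' Pre-bleach and post-bleach image stacks together with the region masks the
#' FRAP estimators need: the analyzed terminal region (roi), the axon shaft
#' and branch masks (disjoint, inside the roi), and a background region
#' outside the bleached area.
#'
#' @slot preBleach,postBleach numeric arrays (rows x cols x frames).
#' @slot tS time (s) of each post-bleach frame, t = 0 at the first
#'   post-bleach frame.
#' @slot roiMask,shaftMask,branchMask,backgroundMask logical matrices.
#' @slot pixelSize um per pixel.
#' @slot truth list of generator ground truth (empty for real data).
#' @exportClass FrapSeries
setClass("FrapSeries",
  representation(preBleach = "array", postBleach = "array", tS = "numeric",
                 roiMask = "matrix", shaftMask = "matrix",
                 branchMask = "matrix", backgroundMask = "matrix",
                 pixelSize = "numeric", truth = "list"),
  validity = function(object) {
    msg <- character()
    dm <- dim(object@postBleach)[1:2]
    if (!identical(dim(object@preBleach)[1:2], dm))
      msg <- c(msg, "pre- and post-bleach frames must share dimensions")
    if (length(dim(object@preBleach)) != 3L || dim(object@preBleach)[3] < 1L)
      msg <- c(msg, "need >= 1 pre-bleach frame")
    if (length(object@tS) != dim(object@postBleach)[3])
      msg <- c(msg, "tS must have one entry per post-bleach frame")
    for (m in c("roiMask", "shaftMask", "branchMask", "backgroundMask"))
      if (!identical(dim(slot(object, m)), dm) || !is.logical(slot(object, m)))
        msg <- c(msg, sprintf("%s must be a logical matrix matching the frames", m))
    if (is.logical(object@shaftMask) && is.logical(object@branchMask) &&
        identical(dim(object@shaftMask), dim(object@branchMask))) {
      if (any(object@shaftMask & object@branchMask))
        msg <- c(msg, "shaft and branch masks must be disjoint")
      if (identical(dim(object@roiMask), dm) &&
          any((object@shaftMask | object@branchMask) & !object@roiMask))
        msg <- c(msg, "shaft and branch masks must lie within the roi")
    }
    if (length(msg)) msg else TRUE
  })

#' A traced axon arbor as a rooted tree of branches
#'
#' SWC-style node table plus the derived branch decomposition. The shaft is
#' the marked root path; branches emanating from the shaft are primary
#' (order 1), branches from primary branches secondary (order 2), and so on.
#'
#' @slot nodes data.frame with columns id, type, x, y, z, radius, parent.
#' @slot shaftType integer SWC type code marking shaft nodes.
#' @slot branches data.frame (one row per branch: branch_id, parent_branch,
#'   order, length_um, n_nodes) filled by the constructor.
#' @exportClass ArborTrace
setClass("ArborTrace",
  representation(nodes = "data.frame", shaftType = "integer",
                 branches = "data.frame"),
  validity = function(object) {
    msg <- character()
    nd <- object@nodes
    need <- c("id", "type", "x", "y", "z", "radius", "parent")
    if (!all(need %in% names(nd)))
      return(paste("nodes must have columns:", paste(need, collapse = ", ")))
    if (anyDuplicated(nd$id)) msg <- c(msg, "node ids must be unique")
    if (sum(nd$parent == -1L) != 1L) msg <- c(msg, "exactly one root (parent == -1)")
    known <- c(-1, nd$id)
    if (!all(nd$parent %in% known)) msg <- c(msg, "every parent must be a node id (or -1)")
    if (length(msg)) msg else TRUE
  })
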