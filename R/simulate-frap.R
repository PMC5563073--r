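## Scene layout for synthetic FRAP series: a horizontal shaft band crossing
## the image with two vertical branch bands, on the analyzed terminal window
## (the recovery analysis region is the terminal ~15 um of the axon).
frapScene <- function(widthUm = 15, pixelSize = 0.118) {
  ncol <- ceiling(widthUm / pixelSize) + 8L
  nrow <- 64L
  shaftRows <- 38:46                      # ~1.1 um thick
  br1 <- 8L + round(ncol * 0.3); br2 <- 8L + round(ncol * 0.62)
  branchCols <- list(br1 + (-3:3), br2 + (-3:3))
  branchRows <- 12:37                     # ~3 um long, above the shaft
  shaft <- matrix(FALSE, nrow, ncol); shaft[shaftRows, 5:(ncol - 4)] <- TRUE
  branch <- matrix(FALSE, nrow, ncol)
  for (bc in branchCols) branch[branchRows, bc] <- TRUE
  branch <- branch & !shaft
  bg <- matrix(FALSE, nrow, ncol); bg[54:62, ] <- TRUE
  list(nrow = nrow, ncol = ncol, shaft = shaft, branch = branch,
       roi = shaft | branch, background = bg,
       branchCentersPx = cbind(row = rep(24, 2), col = c(br1, br2)),
       shaftRowCenter = 42)
}

#' Simulate a FRAP image time series
#'
#' Generates a [FrapSeries-class] from a [FrapModel-class] preset: pre-bleach
#' frames at plateau intensity, then post-bleach frames whose roi-mean
#' normalized recovery follows R(t) = A (1 - exp(-t/tau)) exactly in the
#' noiseless case, with A pinned by the preset's recovery anchor. In
#' `uniform` mode every axon pixel recovers identically; in `focal_at_docks`
#' mode recovery is deposited as Gaussian hotspots at `dockSites`,
#' renormalized so the roi-mean recovery curve (and hence the anchor) is
#' unchanged. Relative Gaussian intensity noise and optional per-frame
#' acquisition bleaching are applied last.
#'
#' @param model a [FrapModel-class].
#' @param dockSites matrix/data.frame of hotspot centers (columns row, col,
#'   in pixels) for `focal_at_docks` mode; the scene's branch centers (see
#'   the returned truth) are a natural choice.
#' @param seed integer seed.
#' @param widthUm,pixelSize scene extent.
#' @param nPreBleach number of pre-bleach frames.
#' @param intensity,background,postBleachFraction raw plateau intensity,
#'   camera offset, and residual fluorescence fraction right after the
#'   bleach.
#' @return a [FrapSeries-class]; `@truth` records A, tau, the hotspot field
#'   and scene coordinates.
#' @examples
#' fs <- simulateFrap(frapModel("venus_control"), seed = 1)
#' fs
#' @export
simulateFrap <- function(model = frapModel("venus_bactin"), dockSites = NULL,
                         seed = 1, widthUm = 15, pixelSize = 0.118,
                         nPreBleach = 3, intensity = 1000, background = 100,
                         postBleachFraction = 0.25) {
  stopifnot(is(model, "FrapModel"))
  validObject(model)
  sc <- frapScene(widthUm, pixelSize)
  A <- recoveryPlateau(model)
  if (model@hotspotMode == "focal_at_docks") {
    if (is.null(dockSites) || NROW(dockSites) == 0)
      stop("focal_at_docks mode requires non-empty dockSites", call. = FALSE)
    dockSites <- as.matrix(dockSites)
    H <- matrix(0, sc$nrow, sc$ncol)
    rr <- row(H); cc <- col(H)
    for (k in seq_len(nrow(dockSites)))
      H <- H + exp(-((rr - dockSites[k, 1])^2 + (cc - dockSites[k, 2])^2) /
                     (2 * model@hotspotSigmaPx^2))
    w <- H / mean(H[sc$roi])            # roi-mean weight 1 preserves anchors
  } else w <- matrix(1, sc$nrow, sc$ncol)

  tS <- seq(0, model@durationS, by = model@frameIntervalS)
  withSeed(seed, {
    noisy <- function(img, k) {
      img <- img * (1 - model@bleachRate)^k
      if (model@noiseSd > 0)
        img <- img * (1 + matrix(rnorm(length(img), 0, model@noiseSd),
                                 nrow(img)))
      img
    }
    pre <- array(0, c(sc$nrow, sc$ncol, nPreBleach))
    for (k in seq_len(nPreBleach))
      pre[, , k] <- noisy(background + intensity * sc$roi, k - 1L)
    post <- array(0, c(sc$nrow, sc$ncol, length(tS)))
    for (k in seq_along(tS)) {
      rec <- A * (1 - exp(-tS[k] / model@tauS))
      img <- background +
        intensity * sc$roi * (postBleachFraction + rec * w)
      post[, , k] <- noisy(img, k - 1L)
    }
    new("FrapSeries", preBleach = pre, postBleach = post, tS = tS,
        roiMask = sc$roi, shaftMask = sc$shaft, branchMask = sc$branch,
        backgroundMask = sc$background, pixelSize = pixelSize,
        truth = list(model = model@name, A = A, tauS = model@tauS,
                     anchorTimeS = model@anchorTimeS,
                     anchorFraction = model@anchorFraction,
                     postBleachFraction = postBleachFraction,
                     intensity = intensity, background = background,
                     hotspotWeight = w,
                     branchCentersPx = sc$branchCentersPx, rng_seed = seed))
  })
}
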