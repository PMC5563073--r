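#' Render granule tracks into a synthetic image stack
#'
#' Draws each granule as a 2D Gaussian spot (full width at half maximum =
#' one granule diameter) on an axon-shaped background band following the
#' shaft polyline, one frame per track time point. Spot centers falling
#' outside the field of view are clipped to the border with a warning.
#'
#' @param tracks track table (granule_id, frame or t_s, x_px, y_px).
#' @param geometry an [AxonGeometry-class] (pixel size, shaft path).
#' @param granuleDiameterUm spot FWHM, um.
#' @param amplitude peak spot intensity above background.
#' @param background camera offset.
#' @param shaftGlow intensity of the axon-shaped background band.
#' @param noiseSd Gaussian noise SD (0 = noiseless).
#' @param seed integer seed (noise only).
#' @param heightPx image height; width follows from the geometry.
#' @return numeric array (rows x cols x frames), with attribute "t_s".
#' @export
renderStack <- function(tracks, geometry, granuleDiameterUm = 1.0,
                        amplitude = 500, background = 100, shaftGlow = 50,
                        noiseSd = 0, seed = 1, heightPx = NULL) {
  px <- geometry@pixelSize
  W <- ceiling(geometry@terminalLength / px) + 9L
  H <- if (is.null(heightPx))
    ceiling(max(geometry@shaft[, 2]) / px) + 40L else heightPx
  sigma <- granuleDiameterUm / px / 2.355
  tAll <- sort(unique(tracks$t_s))
  if (length(tAll) == 0) tAll <- 0
  ## axon-shaped background: band within ~0.8 um of the shaft polyline
  sGrid <- seq(0, geometry@terminalLength, by = px / 2)
  ctr <- polylinePoint(geometry@shaft, sGrid) / px
  bgBand <- matrix(0, H, W)
  halfW <- ceiling(0.8 / px)
  for (i in seq_len(nrow(ctr))) {
    r0 <- round(ctr[i, 2]); c0 <- round(ctr[i, 1]) + 5L
    rr <- max(1, r0 - halfW):min(H, r0 + halfW)
    if (c0 >= 1 && c0 <= W) bgBand[rr, c0] <- shaftGlow
  }
  base <- background + bgBand
  out <- array(0, c(H, W, length(tAll)))
  clipped <- FALSE
  win <- ceiling(3 * sigma)
  withSeed(seed, {
    for (k in seq_along(tAll)) {
      img <- base
      fr <- tracks[abs(tracks$t_s - tAll[k]) < 1e-9, , drop = FALSE]
      if (nrow(fr)) {
        cx <- fr$x_px + 5; cy <- fr$y_px
        if (any(cx < 1 | cx > W | cy < 1 | cy > H)) clipped <- TRUE
        cx <- pmin(pmax(cx, 1), W); cy <- pmin(pmax(cy, 1), H)
        for (j in seq_len(nrow(fr))) {
          rr <- max(1, floor(cy[j]) - win):min(H, ceiling(cy[j]) + win)
          cc <- max(1, floor(cx[j]) - win):min(W, ceiling(cx[j]) + win)
          g <- outer(rr - cy[j], cc - cx[j],
                     function(a, b) exp(-(a^2 + b^2) / (2 * sigma^2)))
          img[rr, cc] <- img[rr, cc] + amplitude * g
        }
      }
      if (noiseSd > 0)
        img <- img + matrix(rnorm(H * W, 0, noiseSd), H, W)
      out[, , k] <- img
    }
  })
  if (clipped)
    warning("some spot centers fell outside the field of view and were clipped")
  attr(out, "t_s") <- tAll
  out
}

## Trivial local-maximum spot detector used by the renderer round-trip test:
## pixels strictly greater than their 8 neighbours and above the threshold.
detectSpots <- function(frame, threshold) {
  H <- nrow(frame); W <- ncol(frame)
  hits <- list()
  for (r in 2:(H - 1)) for (cl in 2:(W - 1)) {
    v <- frame[r, cl]
    if (v <= threshold) next
    nb <- frame[(r - 1):(r + 1), (cl - 1):(cl + 1)]
    nb[2, 2] <- -Inf
    if (v > max(nb))
      hits[[length(hits) + 1L]] <- c(row = r, col = cl, value = v)
  }
  if (length(hits)) as.data.frame(do.call(rbind, hits)) else
    data.frame(row = integer(), col = integer(), value = numeric())
}
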