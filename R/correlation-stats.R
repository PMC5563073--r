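#' RNA dwell-time map
#'
#' Per-pixel temporal median of a (bleach- and drift-corrected) RNA channel
#' time series within the axon mask: pixels where granules dwell retain high
#' median intensity; pixels visited transiently fall back to background.
#' Pixels outside the mask are set to NA.
#'
#' @param stack numeric array (rows x cols x frames).
#' @param mask logical matrix.
#' @return numeric matrix (the dwell map).
#' @export
dwellMap <- function(stack, mask = NULL) {
  d <- dim(stack)
  stopifnot(length(d) == 3L)
  m <- matrix(stack, d[1] * d[2], d[3])
  med <- apply(m, 1, stats::median)
  out <- matrix(med, d[1], d[2])
  if (!is.null(mask)) out[!mask] <- NA_real_
  out
}

#' Cumulative FRAP map
#'
#' Per-pixel temporal maximum of the recovery series: any transient hotspot
#' leaves its peak value in the map. Pixels outside the mask are NA.
#'
#' @inheritParams dwellMap
#' @return numeric matrix (the cumulative recovery map).
#' @export
cumulativeFrap <- function(stack, mask = NULL) {
  d <- dim(stack)
  stopifnot(length(d) == 3L)
  out <- matrix(do.call(pmax, lapply(seq_len(d[3]), function(k)
    as.vector(stack[, , k]))), d[1], d[2])
  if (!is.null(mask)) out[!mask] <- NA_real_
  out
}

#' Masked Pearson correlation between two images
#'
#' Standard Pearson correlation computed over the pixels (or voxels) inside
#' the mask.
#'
#' @param imageA,imageB numeric matrices or arrays of identical dimensions.
#' @param mask logical matrix/array of the same dimensions; NULL uses all
#'   finite pixels.
#' @return correlation R (NA with a warning when either image has zero
#'   variance within the mask).
#' @export
maskedPearson <- function(imageA, imageB, mask = NULL) {
  stopifnot(identical(dim(imageA), dim(imageB)))
  if (is.null(mask)) mask <- array(TRUE, dim(imageA))
  a <- imageA[mask]; b <- imageB[mask]
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 2L) stop("need >= 2 mask pixels", call. = FALSE)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("zero variance within the mask; correlation undefined")
    return(NA_real_)
  }
  stats::cor(a, b)
}

#' Masked Pearson correlation of two volumes
#'
#' As [maskedPearson()] over the voxels of a 3D mask; with
#' `timeResolved = TRUE` the inputs are interpreted as (x, y, t) series and
#' a per-time-point correlation over the 2D mask is returned.
#'
#' @param stackA,stackB numeric 3D arrays.
#' @param mask3d logical 3D array (or a 2D mask when `timeResolved`).
#' @param timeResolved compute R per time point rather than over the volume.
#' @return R, or a data.frame (frame, R) when time-resolved.
#' @export
maskedPearson3D <- function(stackA, stackB, mask3d = NULL,
                            timeResolved = FALSE) {
  if (!timeResolved) return(maskedPearson(stackA, stackB, mask3d))
  d <- dim(stackA)
  m2 <- if (is.null(mask3d)) matrix(TRUE, d[1], d[2]) else mask3d
  data.frame(frame = seq_len(d[3]),
             R = vapply(seq_len(d[3]), function(k)
               maskedPearson(stackA[, , k], stackB[, , k], m2), numeric(1)))
}

#' Costes-style block-scramble null distribution
#'
#' Builds the empirical null for a masked Pearson correlation by repeatedly
#' scrambling one image in blocks of PSF scale: the image is partitioned
#' into `blockSizePx` x `blockSizePx` tiles, tiles lying fully inside the
#' mask are permuted uniformly at random (partial tiles are frozen), and R
#' against the unscrambled image is recomputed. Scrambling the second
#' channel only is sufficient because Pearson correlation is symmetric.
#'
#' @param imageA,imageB numeric matrices.
#' @param mask logical matrix.
#' @param n number of scrambles (1000 in the published procedure).
#' @param blockSizePx scramble block edge, px (PSF full width at half
#'   maximum is the natural scale).
#' @param seed integer seed.
#' @return list with `rObserved`, `rRandom` (length n), `mean`, `sd`,
#'   `percentileOfObserved` (percentage of null values below the observed R),
#'   `nBlocks`, `blockSizePx`, `seed`.
#' @export
costesScrambleNull <- function(imageA, imageB, mask = NULL, n = 1000,
                               blockSizePx = 8, seed = 1) {
  stopifnot(blockSizePx >= 1, n >= 1)
  d <- dim(imageA)
  if (is.null(mask)) mask <- matrix(TRUE, d[1], d[2])
  rObs <- maskedPearson(imageA, imageB, mask)
  ## index blocks fully inside the mask
  rStarts <- seq(1L, d[1] - blockSizePx + 1L, by = blockSizePx)
  cStarts <- seq(1L, d[2] - blockSizePx + 1L, by = blockSizePx)
  blocks <- list()
  for (r0 in rStarts) for (c0 in cStarts) {
    rr <- r0:(r0 + blockSizePx - 1L); cc <- c0:(c0 + blockSizePx - 1L)
    if (all(mask[rr, cc])) blocks[[length(blocks) + 1L]] <- list(r = rr, c = cc)
  }
  if (length(blocks) < 2L)
    stop("fewer than 2 scramble blocks lie fully inside the mask; ",
         "reduce blockSizePx", call. = FALSE)
  withSeed(seed, {
    rRand <- numeric(n)
    for (i in seq_len(n)) {
      perm <- sample(length(blocks))
      scr <- imageB
      for (b in seq_along(blocks)) {
        src <- blocks[[perm[b]]]; dst <- blocks[[b]]
        scr[dst$r, dst$c] <- imageB[src$r, src$c]
      }
      rRand[i] <- suppressWarnings(maskedPearson(imageA, scr, mask))
    }
    list(rObserved = rObs, rRandom = rRand, mean = mean(rRand),
         sd = stats::sd(rRand),
         percentileOfObserved = 100 * mean(rRand < rObs),
         nBlocks = length(blocks), blockSizePx = blockSizePx, seed = seed)
  })
}

#' Observed-versus-null paired comparison across axons
#'
#' Per axon, the difference between the observed correlation and the mean of
#' its scramble null; a paired t test across axons on these differences, and
#' each axon's empirical percentile within its own null.
#'
#' @param rObserved numeric vector of observed correlations (one per axon).
#' @param nulls list of null samples (numeric vectors), parallel to
#'   `rObserved`.
#' @return list with `perAxon` (data.frame r_obs, null_mean, null_sd, diff,
#'   percentile), `t`, `df`, `p`.
#' @export
obsVsNull <- function(rObserved, nulls) {
  stopifnot(length(rObserved) == length(nulls))
  nullMean <- vapply(nulls, mean, numeric(1))
  nullSd <- vapply(nulls, stats::sd, numeric(1))
  pct <- vapply(seq_along(nulls), function(i)
    100 * mean(nulls[[i]] < rObserved[i]), numeric(1))
  diffs <- rObserved - nullMean
  if (stats::sd(diffs) == 0) {
    tt <- list(statistic = c(t = 0), parameter = c(df = length(diffs) - 1L),
               p.value = if (mean(diffs) == 0) 1 else 0)
  } else tt <- stats::t.test(diffs)
  list(perAxon = data.frame(r_obs = rObserved, null_mean = nullMean,
                            null_sd = nullSd, diff = diffs,
                            percentile = pct),
       t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}
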