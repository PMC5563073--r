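## Count direction reversals with a displacement threshold (turning-point
## detection): a reversal is scored when the position retreats >= minRun from
## the running extremum after advancing >= minRun in the previous direction.
countReversals <- function(s, minRun) {
  dir <- 0; rev <- 0L; ext <- s[1]
  for (v in s[-1]) {
    if (dir == 0) {
      if (abs(v - ext) >= minRun) { dir <- sign(v - ext); ext <- v }
    } else {
      ext <- if (dir > 0) max(ext, v) else min(ext, v)
      if ((ext - v) * dir >= minRun) { rev <- rev + 1L; dir <- -dir; ext <- v }
    }
  }
  rev
}

#' Classify the motility of one granule track
#'
#' Over the first `windowS` seconds of the track: a granule that moves less
#' than `stationaryThreshUm` (maximum excursion from its starting position)
#' is stationary; a granule that reverses direction at least once (runs of at
#' least `runMinUm` on both sides of the turn) is bi-directional; otherwise
#' the net displacement sign gives anterograde (increasing s) or retrograde.
#'
#' @param track data.frame with columns t_s and s_um for a single granule.
#' @param windowS classification window, s.
#' @param stationaryThreshUm displacement threshold, um.
#' @param runMinUm minimum run length for a reversal, um.
#' @return one of "stationary", "anterograde", "retrograde", "bidirectional",
#'   or NA_character_ when the track is shorter than the window.
#' @examples
#' tr <- data.frame(t_s = seq(0, 60, 3), s_um = seq(0, 10, length.out = 21))
#' classifyMotility(tr)  # anterograde
#' @export
classifyMotility <- function(track, windowS = 60, stationaryThreshUm = 1.0,
                             runMinUm = 1.0) {
  stopifnot(all(c("t_s", "s_um") %in% names(track)))
  o <- order(track$t_s)
  t <- track$t_s[o]; s <- track$s_um[o]
  if (length(t) < 2L || (t[length(t)] - t[1]) < windowS) return(NA_character_)
  keep <- t <= t[1] + windowS
  s <- s[keep]
  if (max(abs(s - s[1])) < stationaryThreshUm) return("stationary")
  if (countReversals(s, runMinUm) >= 1L) return("bidirectional")
  if (s[length(s)] - s[1] >= 0) "anterograde" else "retrograde"
}

#' Summarize motility classes over a track table
#'
#' Applies [classifyMotility()] per granule and tabulates the class
#' fractions among classifiable tracks.
#'
#' @param tracks track table (granule_id, t_s, s_um).
#' @inheritParams classifyMotility
#' @return list with `classes` (per-granule data.frame), `fractions` (named
#'   vector over the four classes), `nClassified`, `nUnclassifiable`.
#' @export
motilitySummary <- function(tracks, windowS = 60, stationaryThreshUm = 1.0,
                            runMinUm = 1.0) {
  cls <- vapply(split(tracks, tracks$granule_id), classifyMotility,
                character(1), windowS = windowS,
                stationaryThreshUm = stationaryThreshUm, runMinUm = runMinUm)
  ok <- !is.na(cls)
  lev <- c("anterograde", "retrograde", "bidirectional", "stationary")
  frac <- prop.table(table(factor(cls[ok], levels = lev)))
  list(classes = data.frame(granule_id = names(cls), class = unname(cls)),
       fractions = c(frac), nClassified = sum(ok), nUnclassifiable = sum(!ok))
}

#' Estimate anterograde and retrograde run speeds
#'
#' Runs are maximal stretches of consecutive frame steps whose speed exceeds
#' `runSpeedMinUmMin` with a consistent direction and whose total
#' displacement reaches `runMinUm`. Each run contributes displacement /
#' duration; run speeds are averaged per granule and then across granules,
#' separately by direction.
#'
#' @param tracks track table (granule_id, t_s, s_um, optionally on_shaft).
#' @param shaftOnly drop samples with on_shaft == FALSE before analysis.
#' @param runSpeedMinUmMin frame-step speed threshold separating runs from
#'   pauses, um/min.
#' @param runMinUm minimum run displacement, um.
#' @return list with `anterograde` and `retrograde` mean speeds (um/min;
#'   NA if no runs in that direction), `nAntero`, `nRetro` (granules
#'   contributing), and `runs` (per-run table).
#' @export
estimateSpeeds <- function(tracks, shaftOnly = TRUE, runSpeedMinUmMin = 2,
                           runMinUm = 1.0) {
  if (shaftOnly && "on_shaft" %in% names(tracks))
    tracks <- tracks[tracks$on_shaft, , drop = FALSE]
  perGranuleA <- c(); perGranuleR <- c(); runRows <- list()
  for (tr in split(tracks, tracks$granule_id)) {
    o <- order(tr$t_s)
    t <- tr$t_s[o]; s <- tr$s_um[o]
    if (length(t) < 2L) next
    ds <- diff(s); dtt <- diff(t)
    v <- ds / dtt * 60
    state <- ifelse(abs(v) >= runSpeedMinUmMin, sign(v), 0)
    r <- rle(state)
    idx <- cumsum(c(1, r$lengths))
    sp <- list(a = c(), r = c())
    for (k in seq_along(r$values)) {
      if (r$values[k] == 0) next
      i0 <- idx[k]; i1 <- idx[k + 1] - 1
      disp <- sum(ds[i0:i1]); dur <- sum(dtt[i0:i1])
      if (abs(disp) < runMinUm) next
      speed <- abs(disp) / dur * 60
      if (r$values[k] > 0) sp$a <- c(sp$a, speed) else sp$r <- c(sp$r, speed)
      runRows[[length(runRows) + 1L]] <- data.frame(
        granule_id = tr$granule_id[1], start_s = t[i0], end_s = t[i1 + 1],
        displacement_um = disp, speed_um_min = speed,
        direction = if (r$values[k] > 0) "anterograde" else "retrograde")
    }
    if (length(sp$a)) perGranuleA <- c(perGranuleA, mean(sp$a))
    if (length(sp$r)) perGranuleR <- c(perGranuleR, mean(sp$r))
  }
  list(anterograde = if (length(perGranuleA)) mean(perGranuleA) else NA_real_,
       retrograde = if (length(perGranuleR)) mean(perGranuleR) else NA_real_,
       nAntero = length(perGranuleA), nRetro = length(perGranuleR),
       runs = if (length(runRows)) do.call(rbind, runRows) else NULL)
}

#' Granule density on the terminal segment
#'
#' Counts the distinct granules present on the terminal `terminalLengthUm`
#' of the shaft in each frame, averages over frames, and scales to granules
#' per 10 um.
#'
#' @param tracks track table (granule_id, t_s, s_um).
#' @param terminalLengthUm length of the counted terminal segment, um.
#' @param shaftLengthUm total shaft length (distal end of the s axis);
#'   defaults to the maximum observed s.
#' @return granules per 10 um (0 for an empty track table).
#' @export
granuleDensity <- function(tracks, terminalLengthUm = 70,
                           shaftLengthUm = NULL) {
  if (terminalLengthUm <= 0)
    stop("terminalLengthUm must be > 0", call. = FALSE)
  if (nrow(tracks) == 0) return(0)
  L <- if (is.null(shaftLengthUm)) max(tracks$s_um) else shaftLengthUm
  lo <- max(L - terminalLengthUm, 0)
  inSeg <- tracks$s_um >= lo & tracks$s_um <= L
  perFrame <- tapply(tracks$granule_id[inSeg], tracks$t_s[inSeg],
                     function(g) length(unique(g)))
  counts <- rep(0, length(unique(tracks$t_s)))
  counts[match(names(perFrame), as.character(sort(unique(tracks$t_s))))] <-
    as.numeric(perFrame)
  mean(counts) * 10 / terminalLengthUm
}

## Dock detection for one ordered (t, s) series: greedy left-to-right maximal
## intervals in which the position range (max s - min s) stays within one
## granule diameter; intervals shorter than minDurationS are discarded and
## their first sample released to the next interval.
dockIntervals <- function(t, s, diameterUm, minDurationS) {
  n <- length(t)
  out <- list()
  i <- 1L
  while (i < n) {
    lo <- s[i]; hi <- s[i]; j <- i
    while (j < n) {
      lo2 <- min(lo, s[j + 1]); hi2 <- max(hi, s[j + 1])
      if (hi2 - lo2 <= diameterUm) { lo <- lo2; hi <- hi2; j <- j + 1L }
      else break
    }
    if (t[j] - t[i] >= minDurationS) {
      out[[length(out) + 1L]] <- c(start = t[i], end = t[j],
                                   pos = mean(s[i:j]))
      i <- j + 1L
    } else i <- i + 1L
  }
  out
}

#' Detect docking events in granule tracks
#'
#' A dock is a maximal time interval in which the granule's position range
#' stays within one granule diameter ("stationary or oscillatory movements
#' within a distance of the diameter") for at least `minDurationS` (10 s for
#' RNA granules, 60 s for mitochondria). Intervals are found greedily left to
#' right and are non-overlapping.
#'
#' @param tracks track table (granule_id, t_s, s_um); may contain several
#'   granules.
#' @param granuleDiameterUm granule diameter, um.
#' @param minDurationS docking duration threshold, s.
#' @return data.frame with columns granule_id, position_um (mean s during the
#'   dock), start_s, end_s, duration_s; zero rows when no docks.
#' @examples
#' tr <- data.frame(granule_id = "g1", t_s = seq(0, 15, 3), s_um = rep(2, 6))
#' detectDocks(tr)  # one 15 s dock at s = 2
#' @export
detectDocks <- function(tracks, granuleDiameterUm = 1.0, minDurationS = 10) {
  stopifnot(all(c("granule_id", "t_s", "s_um") %in% names(tracks)))
  rows <- list()
  for (tr in split(tracks, tracks$granule_id)) {
    o <- order(tr$t_s)
    t <- tr$t_s[o]; s <- tr$s_um[o]
    if (length(t) < 2L) next
    if (stats::median(diff(t)) > minDurationS / 3 + 1e-9)
      stop(sprintf(paste0(
        "track %s is undersampled: the %g s docking criterion requires at ",
        "least 3 frames (sampling interval <= %g s)"),
        tr$granule_id[1], minDurationS, minDurationS / 3), call. = FALSE)
    for (d in dockIntervals(t, s, granuleDiameterUm, minDurationS))
      rows[[length(rows) + 1L]] <- data.frame(
        granule_id = tr$granule_id[1], position_um = unname(d["pos"]),
        start_s = unname(d["start"]), end_s = unname(d["end"]))
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(granule_id = character(), position_um = numeric(),
               start_s = numeric(), end_s = numeric())
  out$duration_s <- out$end_s - out$start_s
  rownames(out) <- NULL
  out
}

#' Dock-protrusion association at protrusion bases
#'
#' Scores, for each protrusion, whether a docking event overlaps the
#' `windowS` seconds preceding its emergence within `baseRadiusUm` of its
#' base, and returns the positive fraction -- the statistic reported as "84%
#' of protrusions exhibited docked granules at their bases in the 10 s
#' window preceding emergence".
#'
#' @param docks dock table as returned by [detectDocks()].
#' @param protrusions protrusion table (protrusion_id, birth_s, origin_s_um).
#' @param windowS association window before birth, s.
#' @param baseRadiusUm spatial tolerance around the protrusion base, um
#'   (one granule diameter by default).
#' @return list with `fraction` (NA when there are no protrusions), `n`, and
#'   `flags` (per-protrusion logical data.frame).
#' @export
protrusionDockAssociation <- function(docks, protrusions, windowS = 10,
                                      baseRadiusUm = 1.0) {
  if (nrow(protrusions) == 0)
    return(list(fraction = NA_real_, n = 0L, flags = NULL))
  hit <- vapply(seq_len(nrow(protrusions)), function(i) {
    b <- protrusions$birth_s[i]; x <- protrusions$origin_s_um[i]
    any(docks$start_s <= b & docks$end_s >= b - windowS &
          abs(docks$position_um - x) <= baseRadiusUm)
  }, logical(1))
  list(fraction = mean(hit), n = nrow(protrusions),
       flags = data.frame(protrusion_id = protrusions$protrusion_id,
                          docked = hit))
}

#' Dock occupancy of random (position, time) sites
#'
#' The randomized-site control: sites are drawn uniformly over the terminal
#' segment and the observed time span; a site is positive when a detected
#' dock (>= `minDurationS`) covers its time point within `baseRadiusUm` of
#' its position. Deterministic given the seed.
#'
#' @param tracks track table; docks are detected internally with
#'   [detectDocks()].
#' @param geometry an [AxonGeometry-class] giving the segment length.
#' @param nSites number of random sites.
#' @param seed integer seed.
#' @param granuleDiameterUm,minDurationS dock detection parameters.
#' @param baseRadiusUm spatial tolerance, um.
#' @return list with `fraction`, `nSites`, and the `sites` table
#'   (s_um, t_s, docked).
#' @export
randomSiteDockFraction <- function(tracks, geometry, nSites = 500, seed = 1,
                                   granuleDiameterUm = 1.0, minDurationS = 10,
                                   baseRadiusUm = granuleDiameterUm) {
  stopifnot(nSites >= 1)
  docks <- detectDocks(tracks, granuleDiameterUm, minDurationS)
  tMax <- if (nrow(tracks)) max(tracks$t_s) else 0
  withSeed(seed, {
    sUm <- runif(nSites, 0, geometry@terminalLength)
    tQ <- runif(nSites, 0, tMax)
    hit <- vapply(seq_len(nSites), function(i) {
      any(docks$start_s <= tQ[i] & docks$end_s >= tQ[i] &
            abs(docks$position_um - sUm[i]) <= baseRadiusUm)
    }, logical(1))
    list(fraction = mean(hit), nSites = nSites,
         sites = data.frame(s_um = sUm, t_s = tQ, docked = hit))
  })
}

#' Randomized-follow control: does a followed dock lead to a protrusion?
#'
#' For each random (time, position) query the nearest granule at that time is
#' followed forward to its first docking event of at least `minDurationS`
#' (an ongoing dock counts as found); the query is positive when a
#' protrusion is born within `windowS` after the dock onset within
#' `baseRadiusUm` of the dock position. Queries whose granule never docks,
#' or with no granule present, are skipped. The returned fraction is over
#' resolved queries.
#'
#' @param tracks track table.
#' @param protrusions protrusion table.
#' @param nSets number of random queries per axon.
#' @param seed integer seed.
#' @param windowS time window after dock onset, s.
#' @param granuleDiameterUm,minDurationS dock detection parameters.
#' @param baseRadiusUm spatial tolerance, um.
#' @param geometry optional [AxonGeometry-class]; defaults to the observed s
#'   range.
#' @return list with `fraction` (NA when nothing resolved), `nResolved`,
#'   `nQueries`, and the per-query table.
#' @export
randomFollowControl <- function(tracks, protrusions, nSets = 20, seed = 1,
                                windowS = 10, granuleDiameterUm = 1.0,
                                minDurationS = 10,
                                baseRadiusUm = granuleDiameterUm,
                                geometry = NULL) {
  docks <- detectDocks(tracks, granuleDiameterUm, minDurationS)
  L <- if (is.null(geometry)) max(tracks$s_um) else geometry@terminalLength
  tMax <- if (nrow(tracks)) max(tracks$t_s) else 0
  withSeed(seed, {
    sQ <- runif(nSets, 0, L)
    tQ <- runif(nSets, 0, tMax)
    res <- data.frame(s_um = sQ, t_s = tQ, granule_id = NA_character_,
                      resolved = FALSE, positive = FALSE)
    for (i in seq_len(nSets)) {
      ## granule positions at (nearest frame to) the query time
      dt <- abs(tracks$t_s - tQ[i])
      atT <- tracks[dt <= min(dt) + 1e-9, , drop = FALSE]
      if (nrow(atT) == 0) next
      g <- atT$granule_id[which.min(abs(atT$s_um - sQ[i]))]
      res$granule_id[i] <- g
      dg <- docks[docks$granule_id == g & docks$end_s >= tQ[i], , drop = FALSE]
      if (nrow(dg) == 0) next
      d <- dg[which.min(dg$start_s), ]
      res$resolved[i] <- TRUE
      if (nrow(protrusions))
        res$positive[i] <- any(
          protrusions$birth_s >= d$start_s &
            protrusions$birth_s <= d$start_s + windowS &
            abs(protrusions$origin_s_um - d$position_um) <= baseRadiusUm)
    }
    nRes <- sum(res$resolved)
    list(fraction = if (nRes) mean(res$positive[res$resolved]) else NA_real_,
         nResolved = nRes, nQueries = nSets, queries = res)
  })
}
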