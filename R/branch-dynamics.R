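#' Classify a protrusion as filopodium or branch
#'
#' Protrusions shorter than 5 um (maximal length) are filopodia; protrusions
#' of 5 um or more are branches. The published definition leaves exactly
#' 5 um unassigned ("< 5 um" vs "> 5 um"); the boundary is assigned to
#' branch here.
#'
#' @param maxLengthUm maximal protrusion length, um (vectorized).
#' @param boundaryUm class boundary, um.
#' @return character vector, "filopodium" or "branch".
#' @examples
#' classifyProtrusion(c(3, 5, 12))
#' @export
classifyProtrusion <- function(maxLengthUm, boundaryUm = 5) {
  if (any(maxLengthUm < 0, na.rm = TRUE))
    stop("protrusion length must be >= 0", call. = FALSE)
  ifelse(maxLengthUm < boundaryUm, "filopodium", "branch")
}

#' Classify protrusion lifetime as short-lived or persistent
#'
#' Within the 60 min analysis window, lifetimes of 30 min or less are
#' short-lived and lifetimes above 30 min are persistent (the published
#' ranges are 0-30 and 31-60 min; the continuous boundary at exactly 30 min
#' is assigned to short-lived).
#'
#' @param lifetimeS protrusion lifetime, s (vectorized).
#' @param boundaryS class boundary, s.
#' @return character vector, "short_lived" or "persistent".
#' @export
lifetimeClass <- function(lifetimeS, boundaryS = 30 * 60) {
  if (any(lifetimeS < 0, na.rm = TRUE))
    stop("lifetime must be >= 0", call. = FALSE)
  ifelse(lifetimeS <= boundaryS, "short_lived", "persistent")
}

#' Classify branch length as short or long
#'
#' Branches of 5-15 um are short; branches above 15 um are long (boundary
#' 15 um assigned to short, per the printed ranges "5-15" and ">15").
#'
#' @param maxLengthUm maximal branch length, um (vectorized).
#' @return character vector, "short" or "long".
#' @export
lengthClass <- function(maxLengthUm) {
  ifelse(maxLengthUm <= 15, "short", "long")
}

#' Count protrusion additions and removals
#'
#' Counts protrusions added (born) and removed (died) on the terminal
#' `terminalUm` of the shaft within an analysis window, split by type via
#' [classifyProtrusion()] -- the "protrusions added and removed in 10 min"
#' scoring. Censored protrusions (alive at the end of the recording) count
#' as added but not removed; a protrusion visible in a single frame counts
#' as both.
#'
#' @param protrusions protrusion table (birth_s, death_s, origin_s_um,
#'   max_length_um, optionally censored).
#' @param windowS analysis window length, s.
#' @param startS window start, s.
#' @param terminalUm terminal segment length, um.
#' @param shaftLengthUm total shaft length; defaults to the maximum origin.
#' @return data.frame with rows filopodium/branch and columns added, removed.
#' @export
countDynamics <- function(protrusions, windowS = 600, startS = 0,
                          terminalUm = 50, shaftLengthUm = NULL) {
  L <- if (is.null(shaftLengthUm)) {
    if (nrow(protrusions)) max(protrusions$origin_s_um) else terminalUm
  } else shaftLengthUm
  obsEnd <- if (nrow(protrusions)) max(protrusions$death_s, na.rm = TRUE) else 0
  if (startS + windowS > obsEnd + 1e-9 && nrow(protrusions) > 0)
    stop("analysis window exceeds the observation span", call. = FALSE)
  lo <- max(L - terminalUm, 0)
  p <- protrusions[protrusions$origin_s_um >= lo, , drop = FALSE]
  type <- classifyProtrusion(p$max_length_um)
  cens <- if ("censored" %in% names(p)) p$censored else rep(FALSE, nrow(p))
  inWin <- function(x) x >= startS & x <= startS + windowS
  out <- data.frame(type = c("filopodium", "branch"), added = 0L, removed = 0L)
  for (k in 1:2) {
    sel <- type == out$type[k]
    out$added[k] <- sum(sel & inWin(p$birth_s))
    out$removed[k] <- sum(sel & !cens & inWin(p$death_s))
  }
  out
}

#' Time of RNA granule presence at branch base, mid-region and tip
#'
#' For one protrusion, scores each frame of the recording in which an RNA
#' granule occupies the branch base (within `baseRadiusUm` of the origin),
#' the tip region (distal `tipFraction` of the current branch length, at
#' least `tipMinUm`), or the intervening mid-region, and accumulates frame
#' intervals into per-region dwell times.
#'
#' Granules inside the branch are identified by the optional track columns
#' `branch_id` (matching the protrusion id) and `d_um` (distance from the
#' branch origin along the branch); granules without branch annotation count
#' only toward the base via their shaft coordinate.
#'
#' @param protrusion single-row protrusion data.frame (protrusion_id,
#'   birth_s, death_s, origin_s_um).
#' @param tracks track table.
#' @param lengths per-frame branch length table (protrusion_id, t_s,
#'   length_um); when NULL the branch is assumed at max_length_um throughout.
#' @param baseRadiusUm base region radius, um.
#' @param tipFraction distal fraction of the branch forming the tip region.
#' @param tipMinUm minimum tip region size, um.
#' @param frameIntervalS frame interval, s; inferred from the tracks when
#'   NULL.
#' @return data.frame with protrusion_id, base_s, mid_s, tip_s.
#' @export
rnaPresence <- function(protrusion, tracks, lengths = NULL,
                        baseRadiusUm = 1.0, tipFraction = 0.2, tipMinUm = 1.0,
                        frameIntervalS = NULL) {
  stopifnot(nrow(protrusion) == 1L)
  tAll <- sort(unique(tracks$t_s))
  if (is.null(frameIntervalS))
    frameIntervalS <- if (length(tAll) > 1) stats::median(diff(tAll)) else 1
  tt <- tAll[tAll >= protrusion$birth_s & tAll <= protrusion$death_s]
  base <- mid <- tip <- 0
  for (tf in tt) {
    fr <- tracks[abs(tracks$t_s - tf) < 1e-9, , drop = FALSE]
    if (nrow(fr) == 0) next
    len <- if (is.null(lengths)) protrusion$max_length_um else {
      lsub <- lengths[lengths$protrusion_id == protrusion$protrusion_id, ]
      if (nrow(lsub)) stats::approx(lsub$t_s, lsub$length_um, xout = tf,
                                    rule = 2)$y else 0
    }
    tipSpan <- max(tipFraction * len, tipMinUm)
    inBranch <- "branch_id" %in% names(fr) &&
      any(!is.na(fr$branch_id) & fr$branch_id == protrusion$protrusion_id)
    if (inBranch) {
      d <- fr$d_um[!is.na(fr$branch_id) &
                     fr$branch_id == protrusion$protrusion_id]
      if (any(d <= baseRadiusUm)) base <- base + frameIntervalS
      else if (any(d >= len - tipSpan)) tip <- tip + frameIntervalS
      else mid <- mid + frameIntervalS
    } else {
      onShaft <- if ("branch_id" %in% names(fr))
        fr[is.na(fr$branch_id), , drop = FALSE] else fr
      if (any(abs(onShaft$s_um - protrusion$origin_s_um) <= baseRadiusUm))
        base <- base + frameIntervalS
    }
  }
  data.frame(protrusion_id = protrusion$protrusion_id, base_s = base,
             mid_s = mid, tip_s = tip)
}

#' Pearson correlation between RNA presence time and branch fate
#'
#' Plain Pearson correlations between per-branch RNA presence durations and
#' branch lifetime / maximal length.
#'
#' @param durations numeric vector of RNA presence times, s.
#' @param lifetimes branch lifetimes, s.
#' @param maxLengths maximal branch lengths, um.
#' @return data.frame with one row per comparison: variable, r, n.
#' @export
presenceCorrelations <- function(durations, lifetimes = NULL,
                                 maxLengths = NULL) {
  rows <- list()
  if (!is.null(lifetimes))
    rows$lifetime <- data.frame(variable = "lifetime",
                                r = stats::cor(durations, lifetimes),
                                n = length(durations))
  if (!is.null(maxLengths))
    rows$max_length <- data.frame(variable = "max_length",
                                  r = stats::cor(durations, maxLengths),
                                  n = length(durations))
  do.call(rbind, unname(rows))
}

#' Axon navigation metrics: outgrowth velocity and stalling
#'
#' Net displacement of the axon tip over the observation period, expressed
#' per hour; an axon moving less than 5 um over 1 hr is stalled (strict
#' inequality: exactly 5 um/hr is not stalled).
#'
#' @param tipPositions data.frame with t_s and either (x_um, y_um) or s_um.
#' @param stallThreshUmPerHr stalling threshold, um/hr.
#' @return list with velocity_um_per_hr and stalled.
#' @examples
#' tp <- data.frame(t_s = c(0, 3600), s_um = c(0, 3))
#' navigationMetrics(tp)$stalled  # TRUE
#' @export
navigationMetrics <- function(tipPositions, stallThreshUmPerHr = 5) {
  o <- order(tipPositions$t_s)
  tp <- tipPositions[o, , drop = FALSE]
  span <- tp$t_s[nrow(tp)] - tp$t_s[1]
  if (span <= 0) stop("tip positions must span a positive time", call. = FALSE)
  disp <- if (all(c("x_um", "y_um") %in% names(tp)))
    sqrt((tp$x_um[nrow(tp)] - tp$x_um[1])^2 +
           (tp$y_um[nrow(tp)] - tp$y_um[1])^2)
  else abs(tp$s_um[nrow(tp)] - tp$s_um[1])
  v <- disp / span * 3600
  list(velocity_um_per_hr = v, stalled = v < stallThreshUmPerHr)
}
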