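## Dock insertion calibration.
##
## Docking events in the simulator are explicit: mobile (anterograde or
## retrograde) granules receive inserted docks as a Poisson process, and a
## subset of docks ("coupled") spawn a protrusion at the dock position
## shortly after dock onset. Two insertion rates are derived from the presets:
##
##   rhoC -- coupled-dock candidate rate per mobile granule while it is in the
##     protrusion zone (terminal 50 um), set so that the realized coupled
##     protrusion rate equals pDockGivenProtrusion * total protrusion rate.
##   rhoU -- uncoupled-dock rate per mobile granule anywhere on the shaft, set
##     so that the randomized-follow procedure (random site -> nearest granule
##     -> first dock >= threshold -> protrusion within 10 s of onset) scores
##     positive with probability pProtrusionGivenDock. The solved balance
##     accounts for queries that resolve to permanently docked stationary
##     granules (always negative) and for mobile-granule queries that never
##     encounter a dock (skipped).
##
## Stationary granules sit in clusters of `stationaryClusterSize` at shared
## sites and are docked throughout; together with the inserted docks this
## yields the preset background random-site coverage (default 0.16) at the
## default presets -- see the methods vignette for the spacetime algebra.
dockInsertionPlan <- function(geometry, kinetics, branching, durationS) {
  L <- geometry@terminalLength
  zoneLen <- min(50, L)
  zoneFrac <- zoneLen / L
  dtS <- geometry@frameInterval
  Nexp <- kinetics@densityPer10um * L / 10
  Nm <- Nexp * (kinetics@fracAntero + kinetics@fracRetro)
  nStatSites <- Nexp * kinetics@fracStationary / kinetics@stationaryClusterSize
  lambdaP <- (branching@filopodiaAddRate + branching@branchAddRate) / 600
  r <- kinetics@granuleDiameter        # association radius = granule diameter
  dEff <- mean(branching@dockDurationRangeS) + 3 * dtS  # detection extension
  ## composition constants of the randomized-follow procedure at the default
  ## presets, matched by Monte Carlo during development: share of resolved
  ## queries landing on directed mobile granules, probability a coupled first
  ## dock scores positive (detection onset fuzz), false-positive rate of
  ## uncoupled first docks
  mobRes <- 0.68; fComp <- 0.83; fPos <- 0.92; pFalse <- 0.02
  fCpl <- 0.957  # realized / planned coupled-dock yield (end effects)
  lamExtra <- 0.025  # window coverage from bi-directional dwell docks
  p12 <- branching@pProtrusionGivenDock
  cFrac <- branching@pDockGivenProtrusion
  rhoC <- 0; rhoU <- 0
  if (Nm > 0 && zoneFrac > 0 && lambdaP > 0 && cFrac > 0) {
    pc <- min(max((p12 - pFalse) / (mobRes * fComp * (fPos - pFalse)), 1e-6), 1)
    for (it in 1:40) {
      rhoC <- cFrac * lambdaP / (Nm * zoneFrac)
      rcEff <- rhoC * zoneFrac
      rhoU <- if (p12 > 0) rcEff * (1 - pc) / pc else 0
      ## coincidence discount: an uncoupled protrusion can meet a background
      ## dock in its 10 s window; lower the coupled fraction so the measured
      ## association equals the preset
      C <- cFrac * lambdaP * durationS
      U <- rhoU * Nm * durationS
      lamW <- lamExtra + nStatSites * 2 * r / L +
        C * (dEff + 10) * 2 * r / (zoneLen * durationS) +
        U * (dEff + 10) * 2 * r / (L * durationS)
      pCoinc <- 1 - exp(-lamW)
      cNew <- min(max((branching@pDockGivenProtrusion - pCoinc) /
                        max(1 - pCoinc, 1e-6), 0), 1)
      if (abs(cNew - cFrac) < 1e-10) { cFrac <- cNew; break }
      cFrac <- cNew
    }
    rhoC <- rhoC / fCpl  # compensate coupled-dock realization losses
  }
  ## dead-time compensation: a dock blocks the granule for about
  ## meanDock + 2 frames; inflate the candidate rate so the realized
  ## insertion rate matches rhoC * zoneFrac + rhoU (type-II counter)
  rhoIns <- rhoC * zoneFrac + rhoU
  busyS <- mean(branching@dockDurationRangeS) + 3 * dtS
  pIns <- if (rhoC + rhoU > 0)
    (rhoU + rhoC * zoneFrac) / (rhoC + rhoU) else 1
  denom <- max(pIns * (1 - min(rhoIns * busyS, 0.9)), 1e-9)
  rateCand <- if (rhoIns > 0) rhoIns / denom else 0
  list(rhoC = rhoC, rhoU = rhoU, rateCand = rateCand, zoneLen = zoneLen,
       lambdaP = lambdaP, coupledFraction = cFrac)
}

## Inserted-dock duration in frames (position frozen for m steps -> observed
## duration m * dt, which must clear the docking threshold).
dockFrames <- function(branching, dtS) {
  mMin <- ceiling(branching@dockMinDurationS / dtS + 0.5)
  dur <- runif(1, branching@dockDurationRangeS[1], branching@dockDurationRangeS[2])
  max(round(dur / dtS), mMin)
}

#' Simulate a full axon time-lapse dataset with ground truth
#'
#' Generates one synthetic axon terminal recording: granule tracks
#' (run-and-pause transport with the preset speed/direction statistics),
#' docking events, and protrusion events coupled to docks so that the three
#' association statistics of the presets hold in expectation --
#' P(dock precedes protrusion), P(protrusion follows dock), and the
#' random-site dock coverage. All events are recorded in the ground truth.
#' Identical seed and configuration give bit-identical output.
#'
#' Granules that leave the terminal segment wrap to the opposite end and
#' continue under a new track id, keeping density stationary over time.
#'
#' @param geometry an [AxonGeometry-class].
#' @param kinetics a [GranuleKinetics-class] preset.
#' @param branching a [BranchKinetics-class] preset.
#' @param durationS recording duration, s.
#' @param seed integer seed.
#' @return an [AxonRecording-class] with ground truth in [groundTruth()].
#' @examples
#' rec <- simulateAxon(durationS = 300, seed = 2)
#' rec
#' @export
simulateAxon <- function(geometry = axonGeometry(),
                         kinetics = granuleKinetics(),
                         branching = branchKinetics(),
                         durationS = 600, seed = 1) {
  stopifnot(is(geometry, "AxonGeometry"), is(kinetics, "GranuleKinetics"),
            is(branching, "BranchKinetics"))
  validObject(geometry); validObject(kinetics); validObject(branching)
  withSeed(seed, {
    dt <- geometry@frameInterval
    L <- geometry@terminalLength
    nFrames <- floor(durationS / dt) + 1L
    nSteps <- nFrames - 1L
    tS <- (seq_len(nFrames) - 1L) * dt
    plan <- dockInsertionPlan(geometry, kinetics, branching, durationS)
    zoneMin <- L - plan$zoneLen

    N <- rpois(1L, kinetics@densityPer10um * L / 10)
    classes <- sampleClasses(N, kinetics)
    iStat <- which(classes == "stationary")
    ## stationary granules cluster at shared sites
    nSites <- if (length(iStat)) ceiling(length(iStat) / kinetics@stationaryClusterSize) else 0L
    sitePos <- runif(nSites, 0, L)
    siteOf <- if (length(iStat)) rep(seq_len(nSites), each = kinetics@stationaryClusterSize)[seq_along(iStat)] else integer(0)

    trackList <- vector("list", N)
    dockList <- list()
    protList <- list()
    protId <- 0L

    for (i in seq_len(N)) {
      id <- sprintf("g%04d", i)
      cl <- classes[i]
      if (cl == "stationary") {
        s0 <- sitePos[siteOf[match(i, iStat)]] + runif(1, -0.15, 0.15)
        s <- rep(s0, nFrames) + rnorm(nFrames, 0, kinetics@jitterSd)
        seg <- rep(id, nFrames)
        dockList[[length(dockList) + 1L]] <- data.frame(
          granule_id = id, position_um = s0, start_s = 0,
          end_s = tS[nFrames], coupled_protrusion_id = NA_character_)
      } else {
        steps <- motionSteps(cl, nSteps, dt, kinetics)
        s0 <- runif(1, 0, L)
        if (cl %in% c("anterograde", "retrograde") &&
            (plan$rhoC + plan$rhoU) > 0) {
          ## inserted docks: Poisson candidate arrivals; a dock occupies the
          ## granule (plus a 3-frame gap, so consecutive docks sit more than
          ## one diameter apart and cannot merge in detection), and the
          ## candidate rate is
          ## compensated for that dead time so the realized insertion rates
          ## match the plan
          onsets <- cumsum(rexp(ceiling(4 * plan$rateCand * durationS) + 10L,
                                plan$rateCand))
          onsets <- onsets[onsets < durationS]
          nextFree <- 1L
          for (tOn in onsets) {
            k <- max(1L, round(tOn / dt))
            if (k < nextFree || k > nSteps - 3L) next
            m <- dockFrames(branching, dt)
            m <- min(m, nSteps - k + 1L)
            if (m * dt < branching@dockMinDurationS) next
            pos <- (s0 + sum(steps[seq_len(k - 1L)]) * dt) %% L
            coupled <- runif(1) < plan$rhoC / (plan$rhoC + plan$rhoU)
            protHere <- NA_character_
            if (coupled) {
              if (pos < zoneMin) next  # coupled candidates live in the zone
              birth <- tS[k] + runif(1, branching@birthDelayRangeS[1],
                                     branching@birthDelayRangeS[2])
              if (birth < durationS - 3 * dt) {
                protId <- protId + 1L
                protHere <- sprintf("p%04d", protId)
                protList[[protId]] <- data.frame(
                  protrusion_id = protHere, birth_s = birth,
                  origin_s_um = pos, coupled = TRUE)
              }
            }
            steps[k:(k + m - 1L)] <- 0
            dockList[[length(dockList) + 1L]] <- data.frame(
              granule_id = id, position_um = pos, start_s = tS[k],
              end_s = tS[k + m], coupled_protrusion_id = protHere)
            nextFree <- k + m + 3L
          }
        }
        s <- s0 + cumsum(c(0, steps)) * dt
        if (cl == "bidirectional") {
          ## reflect at the segment ends (adds a reversal, which the class
          ## exhibits anyway); directed granules wrap with a new track id
          s <- L - abs(L - (s %% (2 * L)))
          segIdx <- rep(0L, nFrames)
        } else segIdx <- floor(s / L)
        s <- s %% L
        s <- s + rnorm(nFrames, 0, kinetics@jitterSd)
        seg <- if (all(segIdx == segIdx[1])) rep(id, nFrames) else
          paste0(id, letters[1L + segIdx - min(segIdx)])
      }
      xy <- polylinePoint(geometry@shaft, pmin(pmax(s, 0), L))
      trackList[[i]] <- data.frame(
        granule_id = seg, frame = seq_len(nFrames), t_s = tS, s_um = s,
        x_px = xy[, 1] / geometry@pixelSize,
        y_px = xy[, 2] / geometry@pixelSize, on_shaft = TRUE)
    }

    ## docks on wrapped tracks: re-key to the segment id active at dock onset
    docks <- if (length(dockList)) do.call(rbind, dockList) else
      data.frame(granule_id = character(), position_um = numeric(),
                 start_s = numeric(), end_s = numeric(),
                 coupled_protrusion_id = character())
    if (nrow(docks)) {
      allTracks <- do.call(rbind, trackList)
      base <- substr(docks$granule_id, 1, 5)
      for (j in seq_len(nrow(docks))) {
        sub <- allTracks[substr(allTracks$granule_id, 1, 5) == base[j] &
                           allTracks$t_s == docks$start_s[j], , drop = FALSE]
        if (nrow(sub)) docks$granule_id[j] <- sub$granule_id[1]
      }
    }

    ## uncoupled protrusions, uniform over the protrusion zone
    nUnc <- rpois(1L, (1 - plan$coupledFraction) * plan$lambdaP * durationS)
    if (nUnc > 0) {
      for (u in seq_len(nUnc)) {
        protId <- protId + 1L
        protList[[protId]] <- data.frame(
          protrusion_id = sprintf("p%04d", protId),
          birth_s = runif(1, 0, durationS - 3 * dt),
          origin_s_um = runif(1, zoneMin, L), coupled = FALSE)
      }
    }
    prot <- if (length(protList)) do.call(rbind, protList) else
      data.frame(protrusion_id = character(), birth_s = numeric(),
                 origin_s_um = numeric(), coupled = logical())

    ## protrusion types, lifetimes and length profiles (30 s sampling)
    if (nrow(prot)) {
      pFilo <- branching@filopodiaAddRate /
        max(branching@filopodiaAddRate + branching@branchAddRate, 1e-12)
      isFilo <- runif(nrow(prot)) < pFilo
      nominal <- ifelse(isFilo, runif(nrow(prot), 1.0, 4.5),
                        runif(nrow(prot), 5.5, 18))
      life <- pmax(rexp(nrow(prot), 1 / ifelse(isFilo,
        branching@filopodiaLifetimeS, branching@branchLifetimeS)), 30)
      death <- prot$birth_s + life
      prot$censored <- death > durationS
      prot$death_s <- pmin(death, durationS)
      prot$lifetime_s <- prot$death_s - prot$birth_s
      lenTab <- vector("list", nrow(prot))
      maxObs <- numeric(nrow(prot))
      for (j in seq_len(nrow(prot))) {
        tt <- seq(prot$birth_s[j], prot$death_s[j], by = 30)
        u <- (tt - prot$birth_s[j]) / life[j]
        len <- nominal[j] * pmax(1 - abs(2 * u - 1), 0)
        maxObs[j] <- if (length(len)) max(len) else 0
        lenTab[[j]] <- data.frame(protrusion_id = prot$protrusion_id[j],
                                  t_s = tt, length_um = len)
      }
      prot$max_length_um <- maxObs
      lengths <- do.call(rbind, lenTab)
    } else {
      prot$censored <- logical(0); prot$death_s <- numeric(0)
      prot$lifetime_s <- numeric(0); prot$max_length_um <- numeric(0)
      lengths <- data.frame(protrusion_id = character(), t_s = numeric(),
                            length_um = numeric())
    }

    docks$duration_s <- docks$end_s - docks$start_s
    docks$flagged <- docks$duration_s >= branching@dockMinDurationS
    truth <- list(
      docks = docks,
      classes = data.frame(granule_id = sprintf("g%04d", seq_len(N)),
                           class = classes),
      protrusion_lengths = lengths,
      rates = list(
        dock_min_duration_s = branching@dockMinDurationS,
        p_dock_given_protrusion = branching@pDockGivenProtrusion,
        p_protrusion_given_dock = branching@pProtrusionGivenDock,
        background_site_dock_coverage = branching@backgroundSiteDockCoverage,
        density_per_10um = kinetics@densityPer10um,
        v_antero = kinetics@vAntero, v_retro = kinetics@vRetro,
        rho_coupled = plan$rhoC, rho_uncoupled = plan$rhoU),
      rng_seed = seed)
    new("AxonRecording", geometry = geometry,
        tracks = do.call(rbind, trackList), protrusions = prot, truth = truth)
  })
}
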