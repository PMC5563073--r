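test_that("motility classification follows the window definitions", {
  t <- seq(0, 60, 3)
  expect_identical(classifyMotility(makeTrack(t, rep(2, length(t)))),
                   "stationary")
  expect_identical(classifyMotility(makeTrack(t, seq(0, 12, length.out = length(t)))),
                   "anterograde")
  expect_identical(classifyMotility(makeTrack(t, seq(5, 0, length.out = length(t)))),
                   "retrograde")
  ## +3 um then back -3 um: reversal with runs >= 1 um on both sides
  s <- c(seq(0, 3, length.out = 11), seq(2.7, 0, length.out = 10))
  expect_identical(classifyMotility(makeTrack(t, s)), "bidirectional")
  ## shorter than the window: not classifiable
  expect_true(is.na(classifyMotility(makeTrack(t[t < 50], rep(0, sum(t < 50))))))
})

test_that("run speeds equal displacement over duration", {
  ## one run of 5 um in 30 s -> 10 um/min
  tr <- makeTrack(seq(0, 30, 3), seq(0, 5, length.out = 11))
  sp <- estimateSpeeds(tr)
  expect_equal(sp$anterograde, 10, tolerance = 1e-9)
  expect_true(is.na(sp$retrograde))
  ## all-stationary input -> empty result marker
  sp0 <- estimateSpeeds(makeTrack(seq(0, 30, 3), rep(1, 11)))
  expect_true(is.na(sp0$anterograde) && is.na(sp0$retrograde))
  expect_identical(sp0$nAntero, 0L)
})

test_that("granule density counts distinct granules per frame", {
  t <- rep(seq(0, 30, 3), each = 7)
  tr <- data.frame(granule_id = rep(sprintf("g%d", 1:7), times = 11),
                   t_s = t, s_um = rep(seq(5, 65, 10), times = 11))
  expect_equal(granuleDensity(tr, 70, shaftLengthUm = 70), 1.0)
  expect_equal(granuleDensity(tr[0, ], 70), 0)
  expect_error(granuleDensity(tr, 0), "terminalLengthUm")
})

test_that("dock detection finds dwell intervals and rejects runs", {
  t <- seq(0, 15, 3)
  d <- detectDocks(makeTrack(t, rep(4, 6)))
  expect_equal(nrow(d), 1L)
  expect_equal(d$duration_s, 15)
  expect_equal(d$position_um, 4)
  ## +-0.3 um oscillation for 12 s within a 1 um diameter
  d2 <- detectDocks(makeTrack(seq(0, 12, 3), c(0, .3, -.3, .3, 0) + 2))
  expect_equal(nrow(d2), 1L)
  ## a steady 10 um/min run never docks
  d3 <- detectDocks(makeTrack(seq(0, 60, 3), seq(0, 10, length.out = 21)))
  expect_equal(nrow(d3), 0L)
  ## undersampled track names the 3-frame rule
  expect_error(detectDocks(makeTrack(seq(0, 60, 6), rep(0, 11))),
               "3 frames")
})

test_that("dock detection agrees with the exhaustive window oracle", {
  set.seed(41)
  for (rep in 1:100) {
    tr <- randomWanderTrack(sample(20:80, 1))
    got <- detectDocks(makeTrack(tr$t_s, tr$s_um))
    want <- oracleDocks(tr$t_s, tr$s_um, 1.0, 10)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want)) {
      expect_equal(got$start_s, want$start_s)
      expect_equal(got$end_s, want$end_s)
      expect_equal(got$position_um, want$position_um, tolerance = 1e-12)
    }
  }
})

test_that("dock-protrusion association counts docks in the preceding window", {
  docks <- data.frame(granule_id = "g1", position_um = c(10, 40),
                      start_s = c(100, 300), end_s = c(115, 320))
  docks$duration_s <- docks$end_s - docks$start_s
  pr <- data.frame(protrusion_id = c("p1", "p2"),
                   birth_s = c(118, 500), origin_s_um = c(10.4, 40))
  a <- protrusionDockAssociation(docks, pr)
  expect_equal(a$fraction, 0.5)   # p1 within 10 s window and radius; p2 late
  expect_true(a$flags$docked[1] && !a$flags$docked[2])
  ## every / none
  expect_equal(protrusionDockAssociation(docks,
    data.frame(protrusion_id = "q", birth_s = 116, origin_s_um = 10))$fraction, 1)
  expect_equal(protrusionDockAssociation(docks[0, ], pr)$fraction, 0)
  expect_true(is.na(protrusionDockAssociation(docks, pr[0, ])$fraction))
})

test_that("association is monotone in window and radius", {
  rec <- simulateAxon(durationS = 300, seed = 21)
  d <- detectDocks(tracks(rec))
  pr <- protrusions(rec)
  fr <- sapply(c(5, 10, 20, 40), function(w)
    protrusionDockAssociation(d, pr, windowS = w)$fraction)
  expect_true(all(diff(fr) >= 0))
  fr2 <- sapply(c(0.5, 1, 2, 5), function(r)
    protrusionDockAssociation(d, pr, baseRadiusUm = r)$fraction)
  expect_true(all(diff(fr2) >= 0))
})

test_that("random-site control is deterministic and bounded", {
  g <- axonGeometry()
  ## no docks anywhere -> 0
  tr <- simulateTracks(5, granuleKinetics(fracAntero = 1, fracRetro = 0,
                                          fracBidir = 0, fracStationary = 0),
                       durationS = 120, seed = 3)$tracks
  r0 <- randomSiteDockFraction(tr, g, nSites = 50, seed = 1)
  expect_equal(r0$fraction, 0)
  ## docks covering the whole segment at all times -> 1
  big <- do.call(rbind, lapply(1:100, function(i)
    makeTrack(seq(0, 120, 3), rep(i - 0.5, 41), sprintf("g%03d", i))))
  r1 <- randomSiteDockFraction(big, g, nSites = 50, seed = 1)
  expect_equal(r1$fraction, 1)
  r1b <- randomSiteDockFraction(big, g, nSites = 50, seed = 1)
  expect_identical(r1$sites, r1b$sites)
})

test_that("random-follow control scores protrusions after dock onset", {
  ## a single granule running 0 -> 20 um, then docked from ~60 s onward,
  ## with a protrusion born 5 s after dock onset at the dock position
  t <- seq(0, 120, 3)
  s <- pmin(seq(0, by = 1, length.out = length(t)), 20)
  tr <- makeTrack(t, s)
  pr <- data.frame(protrusion_id = "p1", birth_s = 65, origin_s_um = 20)
  fc <- randomFollowControl(tr, pr, nSets = 10, seed = 4)
  expect_true(fc$nResolved > 0)
  expect_equal(fc$fraction, 1)
  ## no protrusions at all -> 0
  fc0 <- randomFollowControl(tr, pr[0, ], nSets = 10, seed = 4)
  expect_equal(fc0$fraction, 0)
})

test_that("mitochondrial docking reuses the pipeline with a 60 s threshold", {
  t <- seq(0, 120, 3)
  tr <- makeTrack(t, c(rep(0, 15), seq(0.5, 13, length.out = length(t) - 15)))
  dRna <- detectDocks(tr, minDurationS = 10)
  dMito <- detectDocks(tr, minDurationS = 60)
  expect_equal(nrow(dRna), 1L)
  expect_equal(nrow(dMito), 0L)
})
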