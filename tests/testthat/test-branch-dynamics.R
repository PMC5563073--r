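test_that("protrusion, lifetime and length classes use the printed boundaries", {
  expect_identical(classifyProtrusion(c(3, 12, 5)),
                   c("filopodium", "branch", "branch"))
  expect_error(classifyProtrusion(-1), ">= 0")
  expect_identical(lifetimeClass(c(10, 45, 30) * 60),
                   c("short_lived", "persistent", "short_lived"))
  expect_identical(lengthClass(c(8, 20, 15)), c("short", "long", "short"))
  ## classes are exhaustive and mutually exclusive over [0, Inf)
  x <- c(0, 4.999, 5, 5.001, 15, 15.001, 1e6)
  expect_false(any(is.na(classifyProtrusion(x))))
})

test_that("count_dynamics tallies additions and removals by type", {
  pr <- data.frame(protrusion_id = c("p1", "p2", "p3"),
                   birth_s = c(90, 60, 200), death_s = c(600, 150, 480),
                   origin_s_um = c(80, 90, 95),
                   max_length_um = c(3, 4, 12),
                   censored = c(TRUE, FALSE, FALSE))
  cd <- countDynamics(pr, windowS = 600, shaftLengthUm = 100)
  expect_equal(cd$added[cd$type == "filopodium"], 2L)
  expect_equal(cd$removed[cd$type == "filopodium"], 1L)  # p1 censored
  expect_equal(cd$added[cd$type == "branch"], 1L)
  expect_equal(cd$removed[cd$type == "branch"], 1L)
  ## single-frame protrusion counts as added and removed
  one <- data.frame(protrusion_id = "q", birth_s = 60, death_s = 60,
                    origin_s_um = 90, max_length_um = 2, censored = FALSE)
  cd1 <- countDynamics(one, windowS = 60, shaftLengthUm = 100)
  expect_equal(cd1$added[1], 1L); expect_equal(cd1$removed[1], 1L)
  expect_error(countDynamics(pr, windowS = 1200, startS = 0,
                             shaftLengthUm = 100), "window")
})

test_that("addition/removal recovers the generator rates (conservation)", {
  added <- c(); removed <- c(); alive <- c()
  for (i in 1:30) {
    rec <- simulateAxon(durationS = 600, seed = 600 + i)
    pr <- protrusions(rec)
    cd <- countDynamics(pr, windowS = 600, shaftLengthUm = 100)
    added <- c(added, sum(cd$added)); removed <- c(removed, sum(cd$removed))
    alive <- c(alive, sum(pr$censored))
  }
  ## conservation: added - removed = protrusions alive at the end
  expect_equal(mean(added) - mean(removed), mean(alive), tolerance = 1e-9)
  ## filopodia + branch addition rate 58 per 10 min, 3 MC SE
  se <- sd(added) / sqrt(length(added))
  expect_lt(abs(mean(added) - 58), 3 * se + 1e-9)
})

test_that("RNA presence accumulates frame intervals per region", {
  pr <- data.frame(protrusion_id = "p1", birth_s = 0, death_s = 120,
                   origin_s_um = 50, max_length_um = 9)
  ## granule parked at the origin for the whole 120 s
  tr <- makeTrack(seq(0, 120, 3), rep(50, 41))
  pres <- rnaPresence(pr, tr, frameIntervalS = 3)
  expect_equal(pres$base_s, 123)  # 41 frames x 3 s
  expect_equal(pres$mid_s + pres$tip_s, 0)
  ## no granules -> zeros
  pres0 <- rnaPresence(pr, tr[0, ], frameIntervalS = 3)
  expect_equal(pres0$base_s + pres0$mid_s + pres0$tip_s, 0)
})

test_that("a granule traversing the branch splits time across regions", {
  ## branch of 9 um: base region 0-1, tip region 7.2-9 (distal 20 %),
  ## mid 1-7.2; uniform traversal 0 -> 9 um over 90 s
  pr <- data.frame(protrusion_id = "p1", birth_s = 0, death_s = 90,
                   origin_s_um = 50, max_length_um = 9)
  t <- seq(0, 90, 3)
  d <- seq(0, 9, length.out = length(t))
  tr <- data.frame(granule_id = "g1", t_s = t, s_um = 50,
                   branch_id = "p1", d_um = d)
  pres <- rnaPresence(pr, tr, frameIntervalS = 3)
  ## frame-bookkeeping oracle
  want <- c(base = sum(d <= 1), tip = sum(d > 1 & d >= 9 - 1.8),
            mid = sum(d > 1 & d < 9 - 1.8)) * 3
  expect_equal(pres$base_s, unname(want["base"]))
  expect_equal(pres$tip_s, unname(want["tip"]))
  expect_equal(pres$mid_s, unname(want["mid"]))
})

test_that("presence correlations report plain Pearson r", {
  dur <- c(10, 20, 30, 40)
  pc <- presenceCorrelations(dur, lifetimes = dur * 7, maxLengths = -dur)
  expect_equal(pc$r[pc$variable == "lifetime"], 1)
  expect_equal(pc$r[pc$variable == "max_length"], -1)
  ## coupled simulation: presence proportional to lifetime plus noise
  set.seed(8)
  life <- runif(60, 100, 3000)
  pres <- 0.2 * life + rnorm(60, 0, 50)
  expect_gt(presenceCorrelations(pres, lifetimes = life)$r, 0.9)
})

test_that("navigation metrics flag stalling below 5 um/hr (strict)", {
  tp <- function(d) data.frame(t_s = c(0, 3600), s_um = c(0, d))
  expect_true(navigationMetrics(tp(3))$stalled)
  expect_false(navigationMetrics(tp(40))$stalled)
  expect_false(navigationMetrics(tp(5))$stalled)
  expect_equal(navigationMetrics(tp(40))$velocity_um_per_hr, 40)
})
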