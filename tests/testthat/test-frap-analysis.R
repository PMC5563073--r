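test_that("drift correction recovers known shifts", {
  set.seed(12)
  base <- matrix(0, 48, 64)
  base[20:28, 30:38] <- 100
  base <- base + matrix(runif(48 * 64, 0, 5), 48)
  shift <- function(m, dy, dx)
    m[((seq_len(nrow(m)) - 1 - dy) %% nrow(m)) + 1,
      ((seq_len(ncol(m)) - 1 - dx) %% ncol(m)) + 1]
  ## apply-then-invert round trip over a random shift sequence
  dys <- sample(-5:5, 6); dxs <- sample(-5:5, 6)
  stack <- array(0, c(48, 64, 6))
  for (k in 1:6) stack[, , k] <- shift(base, dys[k], dxs[k])
  dc <- driftCorrect(stack, reference = 1)
  ## reported shifts register each frame back onto the reference
  expect_equal(dc$shifts$dy[-1], dys[1] - dys[-1])
  expect_equal(dc$shifts$dx[-1], dxs[1] - dxs[1] * 0 - dxs[-1])
  for (k in 2:6) expect_equal(dc$stack[, , k], stack[, , 1])
  ## identical frames: zero shifts
  flat <- array(rep(base, 3), c(48, 64, 3))
  expect_true(all(driftCorrect(flat)$shifts$dy == 0))
  ## featureless frames warn and pass through
  z <- array(0, c(8, 8, 2)); z[, , 1] <- base[1:8, 1:8]
  expect_warning(driftCorrect(z), "featureless")
})

test_that("histogram matching equalizes frame means", {
  set.seed(5)
  base <- matrix(rgamma(60 * 60, 2, 0.1), 60)
  stack <- array(0, c(60, 60, 5))
  for (k in 1:5) stack[, , k] <- base * 0.8^(k - 1)  # exponential decay
  bc <- bleachCorrect(stack)
  for (k in 1:5)
    expect_equal(mean(bc[, , k]), mean(stack[, , 1]), tolerance = 1e-9)
  ## reference frame unchanged
  expect_equal(bc[, , 1], stack[, , 1])
  ## constant stack unchanged (identity mapping)
  const <- array(7, c(10, 10, 3))
  expect_identical(bleachCorrect(const), const)
})

test_that("normalization yields (F - F0) / Fp with affine invariance", {
  fs <- simulateFrap(frapModel("venus_bactin", noiseSd = 0), seed = 1)
  rc <- normalizeRecovery(fs)
  ## flat series: R identically 0
  flat <- fs
  for (k in seq_len(dim(flat@postBleach)[3]))
    flat@postBleach[, , k] <- flat@postBleach[, , 1]
  expect_true(all(abs(normalizeRecovery(flat)$R) < 1e-12))
  ## full recovery from F0 = background to Fp gives R -> 1
  full <- fs
  pre <- full@preBleach[, , 1]
  nPost <- dim(full@postBleach)[3]
  bgVal <- mean(pre[full@backgroundMask])
  full@postBleach[, , 1][] <- bgVal
  for (k in 2:nPost) full@postBleach[, , k] <- pre
  rcF <- normalizeRecovery(full)
  expect_equal(rcF$R[nPost], 1, tolerance = 1e-9)
  ## affine rescaling of all raw intensities leaves R unchanged
  sc <- fs
  sc@preBleach <- 3.7 * sc@preBleach + 40
  sc@postBleach <- 3.7 * sc@postBleach + 40
  expect_equal(normalizeRecovery(sc)$R, rc$R, tolerance = 1e-9)
  ## invalid bleach reference
  dark <- fs
  dark@preBleach[] <- mean(fs@preBleach[, , 1][fs@backgroundMask])
  expect_error(normalizeRecovery(dark), "background")
})

test_that("single-exponential fit recovers noiseless truth to 1e-6", {
  t <- seq(0, 300, 1)
  y <- 0.1958 * (1 - exp(-t / 100))
  f <- fitRecoveryExponential(data.frame(t_s = t, R = y))
  expect_equal(f$A, 0.1958, tolerance = 1e-6)
  expect_equal(f$tau, 100, tolerance = 1e-4)
  expect_equal(f$df, length(t) - 2L)
  ## R == 0 collapses to the A ~ 0 boundary and is flagged
  f0 <- fitRecoveryExponential(data.frame(t_s = t, R = rep(0, length(t))))
  expect_true(f0$boundary)
})

test_that("noisy exponential fits are unbiased within 3 SE", {
  A <- recoveryPlateau(frapModel("venus_bactin"))
  t <- seq(0, 300, 1)
  set.seed(77)
  As <- replicate(100, {
    y <- A * (1 - exp(-t / 100)) + rnorm(length(t), 0, 0.01)
    fitRecoveryExponential(data.frame(t_s = t, R = y))$A
  })
  expect_lt(abs(mean(As) - A), 3 * sd(As) / sqrt(length(As)))
})

test_that("quadratic fit is exact on quadratic input", {
  t <- seq(0, 300, 10)
  y <- 1.02 + 0.003 * t + 2e-6 * t^2
  f <- fitFviQuadratic(data.frame(t_s = t, fvi = y))
  expect_equal(c(f$c0, f$c1, f$c2), c(1.02, 0.003, 2e-6), tolerance = 1e-9)
  fc <- fitFviQuadratic(data.frame(t_s = t, fvi = rep(2, length(t))))
  expect_equal(c(fc$c1, fc$c2), c(0, 0), tolerance = 1e-12)
  ## noisy quadratic: coefficients recovered within 3 SE over replicates
  set.seed(3)
  c2s <- replicate(60, {
    y2 <- 1 + 0.002 * t + 3e-6 * t^2 + rnorm(length(t), 0, 0.05)
    fitFviQuadratic(data.frame(t_s = t, fvi = y2))$c2
  })
  expect_lt(abs(mean(c2s) - 3e-6), 3 * sd(c2s) / sqrt(60))
})

test_that("extra sum-of-squares F statistic matches the formula", {
  ## hand-computed: F = ((10 - 6)/(20 - 16)) / (6/16) = 2.6667
  fS <- list(sse = 10, df = 20)
  fsep <- list(list(sse = 4, df = 10), list(sse = 2, df = 6))
  ft <- extraSSFTest(fS, fsep)
  expect_equal(ft$F, ((10 - 6) / 4) / (6 / 16), tolerance = 1e-12)
  expect_equal(ft$p, pf(ft$F, 4, 16, lower.tail = FALSE))
  ## identical data fitted jointly and separately: F ~ 0, p ~ 1
  set.seed(13)
  t <- seq(0, 300, 5); y <- 0.19 * (1 - exp(-t / 90)) + rnorm(length(t), 0, 0.005)
  one <- fitRecoveryExponential(data.frame(t_s = t, R = y))
  both <- fitRecoveryExponential(data.frame(t_s = c(t, t), R = c(y, y)))
  ft2 <- extraSSFTest(list(sse = both$sse, df = both$df), list(one, one))
  expect_lt(ft2$F, 1e-4)
  expect_gt(ft2$p, 0.999)
  expect_error(extraSSFTest(list(sse = 1, df = 20),
                            list(list(sse = 2, df = 8))), "nested")
})

test_that("the F test separates different recovery amplitudes", {
  t <- seq(0, 300, 2)
  set.seed(21)
  y1 <- 0.1958 * (1 - exp(-t / 100)) + rnorm(length(t), 0, 0.01)
  y2 <- 0.0505 * (1 - exp(-t / 200)) + rnorm(length(t), 0, 0.01)
  f1 <- fitRecoveryExponential(data.frame(t_s = t, R = y1))
  f2 <- fitRecoveryExponential(data.frame(t_s = t, R = y2))
  fsh <- fitRecoveryExponential(data.frame(t_s = c(t, t), R = c(y1, y2)))
  ft <- extraSSFTest(list(sse = fsh$sse, df = fsh$df), list(f1, f2))
  expect_lt(ft$p, 0.001)
})

test_that("F-test type-I error is ~5% under a shared-truth null", {
  ## 1000 simulated pairs from one quadratic truth, shared vs separate OLS
  set.seed(42)
  t <- seq(0, 300, 10)
  rejections <- replicate(1000, {
    y1 <- 1 + 0.002 * t + 1e-6 * t^2 + rnorm(length(t), 0, 0.05)
    y2 <- 1 + 0.002 * t + 1e-6 * t^2 + rnorm(length(t), 0, 0.05)
    f1 <- fitFviQuadratic(data.frame(t_s = t, fvi = y1))
    f2 <- fitFviQuadratic(data.frame(t_s = t, fvi = y2))
    fsh <- fitFviQuadratic(data.frame(t_s = c(t, t), fvi = c(y1, y2)))
    extraSSFTest(list(sse = fsh$sse, df = fsh$df), list(f1, f2))$p < 0.05
  })
  se <- sqrt(0.05 * 0.95 / 1000)
  expect_lt(abs(mean(rejections) - 0.05), 2 * se + 1e-12)
})

test_that("FVI is the branch/shaft SD ratio with population SDs", {
  f <- rbind(c(0, 10), c(0, 5))
  branch <- rbind(c(TRUE, TRUE), c(FALSE, FALSE))
  expect_equal(computeFvi(f, branch, !branch), 2.0)   # SD 5 / SD 2.5
  expect_warning(v <- computeFvi(matrix(1, 2, 2), branch, !branch),
                 "undefined")
  expect_true(is.na(v))
})

test_that("FVI of identically distributed noise approaches 1 as masks grow", {
  set.seed(9)
  for (n in c(100, 1000, 10000)) {
    fvis <- replicate(40, {
      f <- matrix(rnorm(2 * n), ncol = 2)
      m1 <- matrix(c(rep(TRUE, n), rep(FALSE, n)), ncol = 2)
      computeFvi(f, m1, !m1)
    })
    expect_lt(abs(mean(fvis) - 1), 3 * sd(fvis) / sqrt(40) + 5 / n)
  }
})

test_that("branch hotspots raise FVI monotonically with amplitude", {
  sc <- axodyn:::frapScene()
  set.seed(4)
  noise <- matrix(rnorm(sc$nrow * sc$ncol, 0, 2), sc$nrow)
  rr <- row(noise); cc <- col(noise)
  spot <- exp(-((rr - sc$branchCentersPx[1, 1])^2 +
                  (cc - sc$branchCentersPx[1, 2])^2) / (2 * 16))
  fvis <- sapply(c(0, 5, 20, 80), function(a)
    computeFvi(100 + noise + a * spot, sc$branch, sc$shaft))
  expect_true(all(diff(fvis) > 0))
  expect_gt(fvis[4], 1)
})

test_that("the FVI time course of focal recovery rises above 1", {
  m <- frapModel("venus_bactin", hotspotMode = "focal_at_docks",
                 durationS = 120)
  fs <- simulateFrap(m, dockSites = axodyn:::frapScene()$branchCentersPx,
                     seed = 6)
  fv <- fviSeries(fs)
  expect_gt(fv$fvi[nrow(fv)], 1.5)
  expect_gt(fv$fvi[nrow(fv)], fv$fvi[2])
  ## quadratic summary of the time course exists
  qf <- fitFviQuadratic(fv)
  expect_true(is.finite(qf$c2))
})
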