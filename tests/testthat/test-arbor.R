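test_that("branch orders follow the shaft-outward recursion", {
  ## shaft with 3 direct branches -> all primary
  tr <- simulateArbor(nPrimary = 3, childProb = 0, seed = 1)
  expect_true(all(assignOrders(tr)$order == 1L))
  expect_equal(aci(tr), 1)
  ## one branch bearing one child -> orders 1 and 2
  nd <- data.frame(id = 1:6, type = c(2, 2, 3, 3, 3, 3),
                   x = c(0, 10, 10, 10, 12, 14), y = c(0, 0, 2, 4, 2, 3),
                   z = 0, radius = .4, parent = c(-1, 1, 2, 3, 3, 5))
  tr2 <- arborTrace(nd)
  expect_equal(sort(assignOrders(tr2)$order), c(1L, 2L))
})

test_that("orders equal the depth-from-shaft oracle on random arbors", {
  for (seed in 1:20) {
    tr <- simulateArbor(nPrimary = sample(2:6, 1), childProb = 0.6,
                        maxOrder = 5, seed = 100 + seed)
    b <- branches(tr)
    expect_identical(b$order, oracleOrders(b))
  }
})

test_that("branch stats enumerate counts and lengths", {
  ## 4 primary branches of 10 um each, rising vertically off 4 shaft nodes
  nd <- data.frame(id = 1:4, type = 2L, x = c(0, 10, 20, 30), y = 0, z = 0,
                   radius = .5, parent = c(-1L, 1L, 2L, 3L))
  for (j in 1:4)
    nd <- rbind(nd, data.frame(id = 4 + 2 * j - 1:0, type = 3L,
                               x = nd$x[j], y = c(5, 10), z = 0, radius = .3,
                               parent = c(j, 4 + 2 * j - 1L)))
  bs <- branchStats(arborTrace(nd))
  expect_equal(bs$nBranches, 4L)
  expect_equal(bs$totalLengthUm, 4 * 10)
  ## empty arbor -> zeros
  sh <- data.frame(id = 1:2, type = 2L, x = c(0, 10), y = 0, z = 0,
                   radius = .5, parent = c(-1L, 1L))
  bs0 <- branchStats(arborTrace(sh))
  expect_equal(bs0$nBranches, 0L)
  expect_equal(bs0$totalLengthUm, 0)
  expect_true(is.na(aci(arborTrace(sh))))
  ## random arbors: totals match direct enumeration over the branch table
  for (seed in 1:5) {
    tr <- simulateArbor(5, 0.5, seed = 200 + seed)
    b <- branches(tr)
    bs <- branchStats(tr)
    expect_equal(bs$totalLengthUm, sum(b$length_um))
    expect_equal(sum(bs$perOrder$n), nrow(b))
  }
})

test_that("ACI is the mean branch order with the 1.4 simple/complex cut", {
  mk <- function(orders) {
    nodes <- data.frame(id = 1:2, type = 2L, x = c(0, 10), y = 0, z = 0,
                        radius = .5, parent = c(-1L, 1L))
    nid <- 2L; prevMids <- integer(0)
    for (lev in seq_along(orders)) {
      newMids <- integer(0)
      for (j in seq_len(orders[lev])) {
        att <- if (lev == 1) 2L else prevMids[1 + (j - 1) %% length(prevMids)]
        mid <- nid + 1L; tip <- nid + 2L; nid <- nid + 2L
        nodes <- rbind(nodes, data.frame(id = c(mid, tip), type = 3L,
                                         x = c(1, 2) + nid, y = c(1, 2),
                                         z = 0, radius = .3,
                                         parent = c(att, mid)))
        newMids <- c(newMids, mid)
      }
      prevMids <- newMids
    }
    arborTrace(nodes)
  }
  expect_equal(aci(mk(c(4, 2))), (4 * 1 + 2 * 2) / 6, tolerance = 1e-12)
  expect_identical(classifyArbor(aci(mk(c(4, 2)))), "simple")
  expect_equal(aci(mk(c(2, 2, 2))), 2.0)
  expect_identical(classifyArbor(2.0), "complex")
  expect_identical(classifyArbor(1.4), "complex")  # boundary: >= 1.4
  ## ACI >= 1 always; adding a higher-order branch never decreases it
  for (seed in 1:10) {
    tr <- simulateArbor(sample(2:5, 1), 0.5, seed = 300 + seed)
    a0 <- aci(tr)
    expect_gte(a0, 1)
    b <- branches(tr)
    ## append a child to the deepest branch
    deep <- b[which.max(b$order), ]
    nd <- tr@nodes
    newId <- max(nd$id) + 1:2
    nd <- rbind(nd, data.frame(id = newId, type = 3L, x = 99, y = c(1, 2),
                               z = 0, radius = .3,
                               parent = c(deep$start_node, newId[1])))
    expect_gte(aci(arborTrace(nd)), a0)
  }
})

test_that("SWC text round-trips and malformed trees error", {
  tr <- simulateArbor(4, 0.5, seed = 7)
  f <- tempfile(fileext = ".swc")
  writeArbor(tr, f)
  tr2 <- readArbor(f)
  expect_equal(branches(tr2)$order, branches(tr)$order)
  expect_equal(branches(tr2)$length_um, branches(tr)$length_um,
               tolerance = 1e-6)
  ## cycle detection
  bad <- data.frame(id = 1:3, type = c(2, 3, 3), x = 0, y = 0, z = 0,
                    radius = .3, parent = c(-1, 3, 2))
  expect_error(arborTrace(bad), "cycle")
  ## two roots
  bad2 <- data.frame(id = 1:2, type = 2L, x = 0, y = 0, z = 0,
                     radius = .3, parent = c(-1, -1))
  expect_error(arborTrace(bad2), "one root")
})
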