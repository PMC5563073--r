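# Independent brute-force oracles used by the property tests.

# Exhaustive-window dock oracle: for every start index, find the largest end
# index whose position range stays within the diameter (recomputed from
# scratch per window), then select non-overlapping maximal windows greedily
# left to right, keeping those meeting the duration threshold.
oracleDocks <- function(t, s, diameterUm, minDurationS) {
  n <- length(t)
  out <- list()
  i <- 1L
  while (i < n) {
    jMax <- i
    for (j in (i + 1):n) {
      if (max(s[i:j]) - min(s[i:j]) <= diameterUm) jMax <- j else break
    }
    if (t[jMax] - t[i] >= minDurationS) {
      out[[length(out) + 1L]] <- data.frame(start_s = t[i], end_s = t[jMax],
                                            position_um = mean(s[i:jMax]))
      i <- jMax + 1L
    } else i <- i + 1L
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(start_s = numeric(), end_s = numeric(),
               position_um = numeric())
}

# Depth-from-shaft order oracle: walk each branch's parent chain to the
# shaft, counting hops.
oracleOrders <- function(branchTable) {
  vapply(seq_len(nrow(branchTable)), function(k) {
    depth <- 1L
    p <- branchTable$parent_branch[k]
    while (!is.na(p)) {
      depth <- depth + 1L
      p <- branchTable$parent_branch[branchTable$branch_id == p]
    }
    depth
  }, integer(1))
}

# Random wandering track for dock-oracle comparisons: mixture of dwells and
# drifts on a time grid.
randomWanderTrack <- function(nSamples = 60, dtS = 3) {
  steps <- sample(c(0, 0, 0.1, -0.1, 0.5, -0.5, 1.5), nSamples - 1,
                  replace = TRUE)
  data.frame(t_s = (seq_len(nSamples) - 1) * dtS,
             s_um = cumsum(c(0, steps)))
}

makeTrack <- function(t, s, id = "g1") {
  data.frame(granule_id = id, t_s = t, s_um = s)
}
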