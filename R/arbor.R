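## Decompose a node tree into branches. Non-shaft nodes are grouped into
## maximal unbranched paths; a branch starts where a neurite leaves the shaft
## or where a parent branch bifurcates, and ends at a leaf or the next
## bifurcation. Branch order is centrifugal: 1 off the shaft, incrementing
## at every parent-child branch relation.
decomposeBranches <- function(nodes, shaftType) {
  id2row <- match(nodes$id, nodes$id)  # identity; use named lookup below
  rowOf <- seq_len(nrow(nodes)); names(rowOf) <- as.character(nodes$id)
  isShaft <- nodes$type == shaftType
  childrenOf <- split(nodes$id, factor(as.character(nodes$parent),
                                       levels = as.character(nodes$id)))
  nKids <- lengths(childrenOf)

  ## cycle / reachability check: every node must reach the root
  root <- nodes$id[nodes$parent == -1L]
  for (i in seq_len(nrow(nodes))) {
    cur <- nodes$id[i]; nstep <- 0L
    while (cur != root) {
      cur <- nodes$parent[rowOf[as.character(cur)]]
      nstep <- nstep + 1L
      if (nstep > nrow(nodes))
        stop("node table contains a cycle or unreachable nodes", call. = FALSE)
    }
  }

  ## a traced branch keeps its identity through bifurcations: the lowest-id
  ## non-shaft child continues the path, any other children start daughter
  ## branches (the traced-path convention of neurite tracing tools)
  nsKids <- function(nid) {
    kids <- childrenOf[[as.character(nid)]]
    kids[!isShaft[rowOf[as.character(kids)]]]
  }
  parentShaft <- isShaft[rowOf[as.character(nodes$parent)]]
  parentShaft[is.na(parentShaft)] <- TRUE  # root counts as shaft attachment
  isCont <- vapply(seq_len(nrow(nodes)), function(i) {
    if (isShaft[i] || parentShaft[i]) return(FALSE)
    k <- nsKids(nodes$parent[i])
    length(k) > 0L && nodes$id[i] == min(k)
  }, logical(1))
  starts <- nodes$id[!isShaft & (parentShaft | !isCont)]
  branchRows <- list(); nodeBranch <- rep(NA_integer_, nrow(nodes))
  bid <- 0L
  for (st in starts) {
    bid <- bid + 1L
    path <- integer(0); cur <- st
    repeat {
      path <- c(path, rowOf[as.character(cur)])
      kids <- nsKids(cur)
      if (length(kids) == 0L) break
      cur <- min(kids)
    }
    nodeBranch[path] <- bid
    pRow <- rowOf[as.character(nodes$parent[path[1]])]
    xyz <- as.matrix(nodes[c(pRow, path), c("x", "y", "z")])
    len <- sum(sqrt(rowSums(diff(xyz)^2)))
    branchRows[[bid]] <- data.frame(
      branch_id = bid, start_node = nodes$id[path[1]],
      attach_node = nodes$id[pRow], length_um = len, n_nodes = length(path))
  }
  br <- if (length(branchRows)) do.call(rbind, branchRows) else
    data.frame(branch_id = integer(), start_node = integer(),
               attach_node = integer(), length_um = numeric(),
               n_nodes = integer())
  ## parent branch and order
  br$parent_branch <- rep(NA_integer_, nrow(br))
  br$order <- rep(NA_integer_, nrow(br))
  if (nrow(br)) {
    for (k in seq_len(nrow(br)))
      br$parent_branch[k] <- nodeBranch[rowOf[as.character(br$attach_node[k])]]
    remaining <- seq_len(nrow(br))
    ord <- 1L
    while (length(remaining)) {
      now <- remaining[is.na(br$parent_branch[remaining]) |
                         !is.na(br$order[br$parent_branch[remaining]])]
      if (!length(now))
        stop("branch order assignment failed (malformed tree)", call. = FALSE)
      br$order[now] <- ifelse(is.na(br$parent_branch[now]), 1L,
                              br$order[br$parent_branch[now]] + 1L)
      remaining <- setdiff(remaining, now)
      ord <- ord + 1L
    }
  }
  br[, c("branch_id", "parent_branch", "order", "length_um", "n_nodes",
         "start_node", "attach_node")]
}

#' Construct an arbor trace from an SWC-style node table
#'
#' @param nodes data.frame with columns id, type, x, y, z, radius, parent
#'   (parent -1 for the root). Shaft nodes carry the SWC type code
#'   `shaftType` (2 = axon by convention); all other nodes belong to
#'   branches.
#' @param shaftType integer type code marking the axon shaft.
#' @return an [ArborTrace-class] with the branch decomposition filled in.
#' @examples
#' nd <- data.frame(id = 1:4, type = c(2, 2, 3, 3),
#'                  x = c(0, 10, 10, 10), y = c(0, 0, 3, 6), z = 0,
#'                  radius = 0.5, parent = c(-1, 1, 2, 3))
#' branches(arborTrace(nd))  # one primary branch, 6 um
#' @export
arborTrace <- function(nodes, shaftType = 2L) {
  obj <- new("ArborTrace", nodes = nodes, shaftType = as.integer(shaftType),
             branches = data.frame())
  obj@branches <- decomposeBranches(nodes, shaftType)
  obj
}

#' Read an SWC-format arbor trace
#'
#' Plain-text SWC: one node per line, columns id type x y z radius parent,
#' '#' comments. Shaft nodes are identified by their SWC type code
#' (default 2, axon).
#'
#' @param file path to an SWC file.
#' @param shaftType integer type code marking the axon shaft.
#' @return an [ArborTrace-class].
#' @export
readArbor <- function(file, shaftType = 2L) {
  nd <- utils::read.table(file, comment.char = "#",
                          col.names = c("id", "type", "x", "y", "z",
                                        "radius", "parent"))
  arborTrace(nd, shaftType)
}

#' Write an arbor trace in SWC format
#'
#' @param trace an [ArborTrace-class].
#' @param file output path.
#' @return invisibly, the file path.
#' @export
writeArbor <- function(trace, file) {
  nd <- trace@nodes[, c("id", "type", "x", "y", "z", "radius", "parent")]
  writeLines(c("# id type x y z radius parent",
               apply(nd, 1, function(r) paste(format(r, trim = TRUE),
                                              collapse = " "))), file)
  invisible(file)
}

#' Per-branch orders of an arbor
#'
#' Branches emanating from the shaft are primary (order 1); a branch's
#' children are one order higher.
#'
#' @param trace an [ArborTrace-class].
#' @return data.frame with branch_id, parent_branch, order.
#' @export
assignOrders <- function(trace) {
  stopifnot(is(trace, "ArborTrace"))
  trace@branches[, c("branch_id", "parent_branch", "order")]
}

#' Branch counts and lengths of an arbor
#'
#' @param x an [ArborTrace-class].
#' @return list with `perOrder` (data.frame order, n, length_um), `nBranches`
#'   and `totalLengthUm` (branch polylines only; the shaft is not counted).
#' @rdname branchStats
#' @export
setMethod("branchStats", "ArborTrace", function(x) {
  b <- x@branches
  if (nrow(b) == 0)
    return(list(perOrder = data.frame(order = integer(), n = integer(),
                                      length_um = numeric()),
                nBranches = 0L, totalLengthUm = 0))
  per <- data.frame(order = sort(unique(b$order)))
  per$n <- vapply(per$order, function(o) sum(b$order == o), integer(1))
  per$length_um <- vapply(per$order, function(o)
    sum(b$length_um[b$order == o]), numeric(1))
  list(perOrder = per, nBranches = nrow(b), totalLengthUm = sum(b$length_um))
})

#' Axon complexity index
#'
#' The axon complexity index (ACI) summarizes arbor branching as the mean
#' branch order: the sum of branch orders divided by the number of branches.
#' A purely primary arbor has ACI = 1; higher-order branching raises it.
#' Arbors with ACI below 1.4 are classed simple, at or above 1.4 complex.
#'
#' @param x an [ArborTrace-class].
#' @return `aci()`: the index (NA for an arbor without branches).
#' @examples
#' tr <- simulateArbor(nPrimary = 4, childProb = 0, seed = 1)
#' aci(tr)  # 1: all branches primary
#' @rdname aci
#' @export
setMethod("aci", "ArborTrace", function(x) {
  b <- x@branches
  if (nrow(b) == 0) return(NA_real_)
  sum(b$order) / nrow(b)
})

#' @param aciValue an ACI value as returned by [aci()] (vectorized).
#' @param boundary simple/complex boundary.
#' @return `classifyArbor()`: "simple" or "complex" (NA passes through).
#' @rdname aci
#' @export
classifyArbor <- function(aciValue, boundary = 1.4) {
  ifelse(is.na(aciValue), NA_character_,
         ifelse(aciValue < boundary, "simple", "complex"))
}

#' Simulate a random arbor trace
#'
#' Builds a rooted arbor: a straight shaft with `nPrimary` primary branches
#' at random positions, each branch independently sprouting children with
#' probability `childProb` per branch up to `maxOrder`. Branch geometry is a
#' short 2-node polyline of random length. Useful as a ground-truth fixture:
#' the construction order of every branch is its true centrifugal order.
#'
#' @param nPrimary number of primary branches.
#' @param childProb probability that a branch bears a child branch.
#' @param maxOrder maximum branch order generated.
#' @param shaftLength shaft length, um.
#' @param seed integer seed.
#' @return an [ArborTrace-class].
#' @export
simulateArbor <- function(nPrimary = 4, childProb = 0.4, maxOrder = 4,
                          shaftLength = 100, seed = 1) {
  withSeed(seed, {
    nShaft <- 11L
    nodes <- data.frame(id = 1:nShaft, type = 2L,
                        x = seq(0, shaftLength, length.out = nShaft),
                        y = 0, z = 0, radius = 0.5,
                        parent = c(-1L, 1:(nShaft - 1L)))
    nextId <- nShaft
    extra <- list()
    ## each branch is a 2-node polyline (mid + tip); children attach at the
    ## mid node so that the attachment is a true bifurcation
    grow <- function(parentId, px, py, order) {
      ang <- runif(1, pi / 6, 5 * pi / 6) * sample(c(-1, 1), 1)
      len <- runif(1, 3, 15)
      mx <- px + len / 2 * cos(ang); my <- py + len / 2 * sin(ang)
      tx <- px + len * cos(ang); ty <- py + len * sin(ang)
      midId <- nextId + 1L; tipId <- nextId + 2L; nextId <<- nextId + 2L
      extra[[length(extra) + 1L]] <<- data.frame(
        id = c(midId, tipId), type = 3L, x = c(mx, tx), y = c(my, ty),
        z = 0, radius = 0.3, parent = c(parentId, midId))
      if (order < maxOrder && runif(1) < childProb)
        grow(midId, mx, my, order + 1L)
    }
    attach <- sample(2:nShaft, nPrimary, replace = TRUE)
    for (a in attach)
      grow(nodes$id[a], nodes$x[a], nodes$y[a], 1L)
    arborTrace(rbind(nodes, do.call(rbind, extra)))
  })
}
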