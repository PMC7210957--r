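# Sankoff minimum-cost ancestral reconstruction for an ordered multistate
# character on a rooted tree with polytomies: subtree cost vectors by the
# standard dynamic program, MPR state sets from an up/down pass, and the
# min-max range of independent origins (edges 0 -> {1,2}) over all
# minimum-cost reconstructions from a second dynamic program.

#' Ordered (linear) step matrix
#'
#' Cost `|i - j|` between states, the standard cost for an ordered
#' multistate character (conical = 0, rounded = 1, flat = 2 for the
#' tooth-crown character).
#'
#' @param states integer state alphabet (default `0:2`).
#' @return numeric cost matrix with dimnames = states.
#' @export
orderedStepMatrix <- function(states = 0:2) {
  k <- length(states)
  m <- abs(outer(states, states, "-"))
  dimnames(m) <- list(states, states)
  m
}

#' Unordered (Fitch) step matrix
#'
#' Unit cost between distinct states.
#'
#' @param states integer state alphabet (default `0:2`).
#' @return numeric cost matrix.
#' @export
unorderedStepMatrix <- function(states = 0:2) {
  k <- length(states)
  m <- 1 - diag(k)
  dimnames(m) <- list(states, states)
  m
}

# children of each node as a list indexed by node id
.children_list <- function(tree) {
  nNode <- length(tree$tip.label) + tree$Nnode
  ch <- vector("list", nNode)
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]; c_ <- tree$edge[e, 2]
    ch[[p]] <- c(ch[[p]], c_)
  }
  ch
}

# nodes in postorder (children before parents) and the root id
.postorder_nodes <- function(tree) {
  nTip <- length(tree$tip.label)
  po <- ape::reorder.phylo(tree, "postorder")
  parents <- unique(po$edge[, 1])          # already children-first
  root <- nTip + 1L
  list(internal = parents, root = root, nTip = nTip)
}

# is an edge p -> c an "origin" of the molariform condition? (vectorized)
.is_origin <- function(sParent, sChild)
  sParent == 0L & (sChild == 1L | sChild == 2L)

#' Sankoff parsimony with MPR sets and origin-count range
#'
#' Computes the minimum total step cost of the character on the tree, the
#' per-node MPR sets (states occurring in at least one minimum-cost
#' reconstruction, from the up/down cost decomposition), and the minimum and
#' maximum number of independent origins of the molariform condition (edges
#' whose parent state is 0 and child state is 1 or 2) over all minimum-cost
#' reconstructions.  Polytomies are handled as hard multifurcations by
#' summing child contributions.
#'
#' @param tree rooted ape `phylo` (polytomies permitted).
#' @param charMatrix named list taxon -> non-empty integer state subset;
#'   every tip must have an entry (ambiguous / missing = the full alphabet).
#' @param stepMatrix cost matrix (default [orderedStepMatrix()]).
#' @param states integer state alphabet.
#' @return a [ParsimonyResult-class].
#' @examples
#' tr <- ape::read.tree(text = "((A,B),(C,D));")
#' cm <- list(A = 0L, B = 0L, C = 1L, D = 2L)
#' sankoffParsimony(tr, cm)
#' @export
sankoffParsimony <- function(tree, charMatrix,
                             stepMatrix = orderedStepMatrix(states),
                             states = 0:2) {
  cm <- .match_tips(tree, charMatrix, states)
  k <- length(states)
  stopifnot(all(dim(stepMatrix) == k))
  if (any(diag(stepMatrix) != 0)) stop("step matrix diagonal must be 0")
  if (any(stepMatrix != t(stepMatrix))) stop("step matrix must be symmetric")
  po <- .postorder_nodes(tree)
  nTip <- po$nTip
  nNode <- nTip + tree$Nnode
  ch <- .children_list(tree)
  INF <- .Machine$double.xmax / 4

  S <- matrix(INF, k, nNode)               # subtree cost vectors
  Omin <- matrix(INF, k, nNode)            # subtree origin-count bounds
  Omax <- matrix(-INF, k, nNode)
  for (t in seq_len(nTip)) {
    ok <- states %in% cm[[tree$tip.label[t]]]
    S[ok, t] <- 0
    Omin[ok, t] <- 0
    Omax[ok, t] <- 0
  }
  # m[c][s] = min over child states of step(s, s') + S_c(s'); cached per node
  m <- matrix(NA_real_, k, nNode)
  for (v in po$internal) {
    for (si in seq_len(k)) {
      tot <- 0; omin <- 0; omax <- 0
      for (c_ in ch[[v]]) {
        cand <- stepMatrix[si, ] + S[, c_]
        mc <- min(cand)
        tot <- tot + mc
        arg <- which(cand <= mc + 1e-9)
        org <- as.numeric(.is_origin(states[si], states[arg]))
        omin <- omin + min(org + Omin[arg, c_])
        omax <- omax + max(org + Omax[arg, c_])
      }
      S[si, v] <- tot
      Omin[si, v] <- omin
      Omax[si, v] <- omax
    }
    for (c_ in ch[[v]])
      m[, c_] <- apply(stepMatrix + matrix(S[, c_], k, k, byrow = TRUE),
                       1, min)
  }
  root <- po$root
  minCost <- min(S[, root])

  # downward pass: D[s, v] = min cost of the rest of the tree given v = s
  D <- matrix(INF, k, nNode)
  D[, root] <- 0
  # preorder = reverse postorder of internal nodes
  for (v in rev(po$internal)) {
    kids <- ch[[v]]
    msum <- rowSums(m[, kids, drop = FALSE])
    for (c_ in kids) {
      other <- msum - m[, c_]              # siblings' contribution per s
      base <- D[, v] + other               # cost outside c's subtree, at v=s
      # D_c(s') = min_s base(s) + step(s, s')
      D[, c_] <- apply(matrix(base, k, k) + stepMatrix, 2, min)
    }
  }
  total <- S + D
  mpr <- lapply(seq_len(nNode), function(v)
    states[total[, v] <= minCost + 1e-9])

  rootArg <- which(S[, root] <= minCost + 1e-9)
  originRange <- c(min(Omin[rootArg, root]), max(Omax[rootArg, root]))

  new("ParsimonyResult", minCost = minCost, mprSets = mpr,
      originRange = as.integer(round(originRange)),
      costVectors = S, states = as.integer(states))
}

#' Count independent origins on a single reconstruction
#'
#' Number of edges whose parent state is 0 (conical) and child state is 1 or
#' 2 (rounded or flat, the molariform condition).
#'
#' @param tree rooted ape `phylo`.
#' @param nodeStates integer vector of one state per node (ape numbering:
#'   tips first, then internal nodes).
#' @return integer origin count.
#' @examples
#' tr <- ape::read.tree(text = "((A,B),(C,D));")
#' countOrigins(tr, c(1L, 0L, 1L, 2L, 0L, 0L, 0L))
#' @export
countOrigins <- function(tree, nodeStates) {
  nNode <- length(tree$tip.label) + tree$Nnode
  stopifnot(length(nodeStates) == nNode)
  sum(.is_origin_vec(nodeStates[tree$edge[, 1]], nodeStates[tree$edge[, 2]]))
}

.is_origin_vec <- function(sParent, sChild)
  sParent == 0L & (sChild == 1L | sChild == 2L)

#' Brute-force parsimony by exhaustive enumeration
#'
#' Independent oracle for small trees: enumerates every assignment of states
#' to internal nodes (and every resolution of ambiguous tips), scores total
#' step cost, and collects the minimum cost, per-node MPR sets and the
#' origin-count range over all minimum-cost reconstructions.  Exponential in
#' the node count; intended for trees of about 8 tips or fewer.
#'
#' @inheritParams sankoffParsimony
#' @return list with `minCost`, `mprSets`, `originRange`.
#' @export
enumerateParsimony <- function(tree, charMatrix,
                               stepMatrix = orderedStepMatrix(states),
                               states = 0:2) {
  cm <- .match_tips(tree, charMatrix, states)
  nTip <- length(tree$tip.label)
  nNode <- nTip + tree$Nnode
  allowed <- c(lapply(tree$tip.label, function(t) cm[[t]]),
               rep(list(states), tree$Nnode))
  counts <- lengths(allowed)
  if (prod(counts) > 5e6) stop("enumeration too large")
  idx <- do.call(expand.grid, lapply(allowed, seq_along))
  assign_ <- matrix(0L, nrow(idx), nNode)
  for (v in seq_len(nNode)) assign_[, v] <- allowed[[v]][idx[[v]]]
  si <- match(assign_[, tree$edge[, 1]], states)
  sj <- match(assign_[, tree$edge[, 2]], states)
  costs <- matrix(stepMatrix[cbind(si, sj)], nrow(idx))
  total <- rowSums(costs)
  minCost <- min(total)
  best <- which(total <= minCost + 1e-9)
  mpr <- lapply(seq_len(nNode), function(v)
    sort(unique(assign_[best, v])))
  orig <- vapply(best, function(b)
    sum(.is_origin_vec(assign_[b, tree$edge[, 1]],
                       assign_[b, tree$edge[, 2]])), numeric(1))
  list(minCost = minCost, mprSets = mpr,
       originRange = as.integer(range(orig)))
}
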