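# Equal-rates Mk likelihood machinery for the 3-state tooth-crown character:
# closed-form transition probabilities, Felsenstein pruning with a uniform
# root prior, 1-D maximum-likelihood rate estimation, two-pass marginal
# ancestral reconstructions, simulation, and enumeration oracles for
# validation on small trees.

#' Mk transition probability matrix
#'
#' Equal-rates k-state Markov model: `P(i -> i) = 1/k + (k-1)/k exp(-k r t)`
#' and `P(i -> j) = 1/k - 1/k exp(-k r t)` for `i != j`; rows sum to 1.  With
#' k = 3 this is `1/3 + 2/3 exp(-3 r t)` and `1/3 - 1/3 exp(-3 r t)`.
#'
#' @param rate substitution rate per unit branch length, >= 0.
#' @param branchLength branch length, >= 0.
#' @param k number of states (default 3).
#' @return k x k stochastic matrix.
#' @examples
#' mkTransitionProb(0.5, 0)        # identity
#' mkTransitionProb(10, 100)       # ~ 1/3 everywhere
#' @export
mkTransitionProb <- function(rate, branchLength, k = 3L) {
  if (rate < 0 || branchLength < 0)
    stop("rate and branchLength must be >= 0")
  e <- exp(-k * rate * branchLength)
  off <- (1 - e) / k
  m <- matrix(off, k, k)
  diag(m) <- 1 / k + (k - 1) / k * e
  m
}

# per-tip indicator matrix (k x nTip) from the state subsets
.tip_indicators <- function(tree, cm, states) {
  k <- length(states)
  L <- matrix(0, k, length(tree$tip.label))
  for (t in seq_along(tree$tip.label))
    L[states %in% cm[[tree$tip.label[t]]], t] <- 1
  L
}

# pruning pass: list(L = partial likelihood matrix (k x nNode, scaled),
# logScale = per-node accumulated log scale, loglik)
.mk_prune <- function(tree, cm, rate, states) {
  k <- length(states)
  nTip <- length(tree$tip.label)
  nNode <- nTip + tree$Nnode
  bl <- if (is.null(tree$edge.length)) rep(1, nrow(tree$edge))
        else tree$edge.length
  ch <- .children_list(tree)
  po <- .postorder_nodes(tree)
  edgeOfChild <- integer(nNode)
  edgeOfChild[tree$edge[, 2]] <- seq_len(nrow(tree$edge))
  L <- matrix(0, k, nNode)
  L[, seq_len(nTip)] <- .tip_indicators(tree, cm, states)
  logScale <- numeric(nNode)
  P <- vector("list", nrow(tree$edge))
  for (e in seq_len(nrow(tree$edge)))
    P[[e]] <- mkTransitionProb(rate, bl[e], k)
  for (v in po$internal) {
    lv <- rep(1, k)
    sc <- 0
    for (c_ in ch[[v]]) {
      lv <- lv * as.numeric(P[[edgeOfChild[c_]]] %*% L[, c_])
      sc <- sc + logScale[c_]
    }
    mx <- max(lv)
    if (mx <= 0) return(list(L = L, logScale = logScale, loglik = -Inf))
    L[, v] <- lv / mx
    logScale[v] <- sc + log(mx)
  }
  root <- po$root
  loglik <- log(sum(L[, root] / k)) + logScale[root]
  list(L = L, logScale = logScale, loglik = loglik, P = P,
       edgeOfChild = edgeOfChild, ch = ch, po = po)
}

#' Mk log-likelihood of a character on a tree
#'
#' Felsenstein pruning with a uniform root prior (1/k per state); ambiguity
#' sets enter as partial-likelihood indicators.  Missing branch lengths
#' default to uniform length 1 (the unit is absorbed by the rate).
#'
#' @param tree rooted ape `phylo` (polytomies permitted).
#' @param charMatrix named list taxon -> integer state subset.
#' @param rate substitution rate, > 0 (0 allowed for limiting checks).
#' @param states integer state alphabet (default `0:2`).
#' @return log-likelihood (numeric scalar).
#' @export
mkLoglik <- function(tree, charMatrix, rate, states = 0:2) {
  cm <- .match_tips(tree, charMatrix, states)
  .mk_prune(tree, cm, rate, states)$loglik
}

#' Maximum-likelihood rate estimate for the Mk model
#'
#' 1-D bounded optimization of [mkLoglik()] over the rate.  When the data
#' cannot identify a rate (all tips effectively in the same single state)
#' the result is flagged and the rate sits at the lower search bound.
#'
#' @inheritParams mkLoglik
#' @param interval search interval for the rate.
#' @param tol convergence tolerance passed to [stats::optimize()].
#' @param computeMarginals also fill in marginal reconstructions and the
#'   ML origin count (default TRUE).
#' @return an [MkResult-class].
#' @export
fitRate <- function(tree, charMatrix, states = 0:2,
                    interval = c(1e-8, 100), tol = 1e-8,
                    computeMarginals = TRUE) {
  cm <- .match_tips(tree, charMatrix, states)
  observed <- cm[vapply(cm, length, 1L) < length(states)]
  identifiable <- length(unique(observed)) > 1L
  if (!identifiable) {
    warning("rate is unidentifiable (no state variation among tips); ",
            "rate fixed at the lower bound")
    rateHat <- interval[1]
  } else {
    f <- function(r) .mk_prune(tree, cm, r, states)$loglik
    # the surface has a saturation plateau at high rates; bracket the peak on
    # a log-spaced grid first, then golden-section inside the bracket
    grid <- exp(seq(log(interval[1]), log(interval[2]), length.out = 40L))
    lls <- vapply(grid, f, numeric(1))
    iBest <- which.max(lls)
    lo <- grid[max(1L, iBest - 1L)]
    hi <- grid[min(length(grid), iBest + 1L)]
    opt <- optimize(f, interval = c(lo, hi), maximum = TRUE, tol = tol)
    rateHat <- if (opt$objective >= lls[iBest]) opt$maximum else grid[iBest]
  }
  ll <- .mk_prune(tree, cm, rateHat, states)$loglik
  marg <- matrix(numeric(), 0, length(states))
  orange <- c(NA_integer_, NA_integer_)
  if (computeMarginals) {
    marg <- marginalASR(tree, cm, rateHat, states)
    orange <- .ml_origin_range(tree, marg, states)
  }
  new("MkResult", rateHat = rateHat, logLik = ll, marginals = marg,
      mlOriginRange = orange, identifiable = identifiable,
      states = as.integer(states))
}

#' Marginal ancestral state probabilities under the Mk model
#'
#' Standard two-pass (up/down) algorithm: for each node, the marginal
#' posterior over states combines the node's subtree partial likelihood with
#' the likelihood of the rest of the tree, under a uniform root prior.  Each
#' returned row sums to 1.  Tip rows are posteriors over the tip's allowed
#' set (a point mass for unambiguous tips).
#'
#' @inheritParams mkLoglik
#' @return numeric matrix (nodes x states), rows summing to 1.
#' @export
marginalASR <- function(tree, charMatrix, rate, states = 0:2) {
  cm <- .match_tips(tree, charMatrix, states)
  k <- length(states)
  pr <- .mk_prune(tree, cm, rate, states)
  if (!is.finite(pr$loglik)) stop("zero likelihood: inconsistent data")
  nTip <- length(tree$tip.label)
  nNode <- nTip + tree$Nnode
  root <- pr$po$root
  # G[s, v]: (scaled) likelihood of everything outside v's subtree given
  # v = s, seeded with the root prior
  G <- matrix(0, k, nNode)
  G[, root] <- 1 / k
  for (v in rev(pr$po$internal)) {
    kids <- pr$ch[[v]]
    # down-messages to each child: G_v(s) times siblings' up-messages
    up <- vapply(kids, function(c_)
      as.numeric(pr$P[[pr$edgeOfChild[c_]]] %*% pr$L[, c_]), numeric(k))
    tot <- apply(up, 1, prod)
    for (i in seq_along(kids)) {
      c_ <- kids[i]
      sib <- tot / up[, i]
      sib[!is.finite(sib)] <- apply(up[, -i, drop = FALSE], 1, prod)[!is.finite(sib)]
      base <- G[, v] * sib
      g <- as.numeric(t(pr$P[[pr$edgeOfChild[c_]]]) %*% base)
      mx <- max(g)
      G[, c_] <- if (mx > 0) g / mx else g
    }
  }
  marg <- t(pr$L * G)
  sums <- rowSums(marg)
  bad <- sums <= 0
  if (any(bad)) stop("degenerate marginal at node(s) ",
                     paste(which(bad), collapse = ", "))
  marg / sums
}

# origin-count range from argmax marginal states (ties broaden the range)
.ml_origin_range <- function(tree, marginals, states, tieTol = 1e-9) {
  argsets <- apply(marginals, 1, function(p)
    states[p >= max(p) - tieTol], simplify = FALSE)
  pa <- tree$edge[, 1]; chl <- tree$edge[, 2]
  mn <- 0L; mx <- 0L
  for (e in seq_along(pa)) {
    ps <- argsets[[pa[e]]]; cs <- argsets[[chl[e]]]
    can <- 0L %in% ps && any(cs %in% c(1L, 2L))
    must <- identical(ps, 0L) && all(cs %in% c(1L, 2L))
    if (must) mn <- mn + 1L
    if (can) mx <- mx + 1L
  }
  c(mn, mx)
}

#' Simulate a character under the Mk model
#'
#' Draws the root state from the uniform prior and transitions along each
#' branch with [mkTransitionProb()]; used for parameter-recovery studies.
#'
#' @param tree rooted ape `phylo` with branch lengths (missing lengths
#'   default to 1).
#' @param rate substitution rate.
#' @param seed integer RNG seed.
#' @param states integer state alphabet.
#' @return list: `tipStates` (named list, singleton sets, usable as a
#'   character matrix) and `nodeStates` (integer per node).
#' @export
simulateMk <- function(tree, rate, seed = 1L, states = 0:2) {
  k <- length(states)
  bl <- if (is.null(tree$edge.length)) rep(1, nrow(tree$edge))
        else tree$edge.length
  nTip <- length(tree$tip.label)
  nNode <- nTip + tree$Nnode
  .with_seed(seed, {
    nodeStates <- integer(nNode)
    root <- nTip + 1L
    nodeStates[root] <- sample(states, 1L)
    # preorder: parents before children
    po <- ape::reorder.phylo(tree, "postorder")
    for (e in rev(seq_len(nrow(po$edge)))) {
      p <- po$edge[e, 1]; c_ <- po$edge[e, 2]
      blen <- po$edge.length[e]
      P <- mkTransitionProb(rate, blen, k)
      from <- match(nodeStates[p], states)
      nodeStates[c_] <- sample(states, 1L, prob = P[from, ])
    }
    tips <- as.list(nodeStates[seq_len(nTip)])
    names(tips) <- tree$tip.label
    list(tipStates = tips, nodeStates = nodeStates)
  })
}

#' Brute-force Mk likelihood and marginals by enumeration
#'
#' Independent oracle for small trees: sums products of transition
#' probabilities over every assignment of states to internal nodes (and
#' every resolution of ambiguous tips), with the uniform root prior.
#'
#' @inheritParams mkLoglik
#' @return list: `loglik` and `marginals` (nodes x states posterior matrix).
#' @export
enumerateMk <- function(tree, charMatrix, rate, states = 0:2) {
  cm <- .match_tips(tree, charMatrix, states)
  k <- length(states)
  nTip <- length(tree$tip.label)
  nNode <- nTip + tree$Nnode
  bl <- if (is.null(tree$edge.length)) rep(1, nrow(tree$edge))
        else tree$edge.length
  allowed <- c(lapply(tree$tip.label, function(t) cm[[t]]),
               rep(list(states), tree$Nnode))
  if (prod(lengths(allowed)) > 5e6) stop("enumeration too large")
  idx <- do.call(expand.grid, lapply(allowed, seq_along))
  assign_ <- matrix(0L, nrow(idx), nNode)
  for (v in seq_len(nNode)) assign_[, v] <- allowed[[v]][idx[[v]]]
  probs <- rep(1 / k, nrow(idx))           # root prior
  for (e in seq_len(nrow(tree$edge))) {
    P <- mkTransitionProb(rate, bl[e], k)
    si <- match(assign_[, tree$edge[e, 1]], states)
    sj <- match(assign_[, tree$edge[e, 2]], states)
    probs <- probs * P[cbind(si, sj)]
  }
  tot <- sum(probs)
  marg <- matrix(0, nNode, k)
  for (v in seq_len(nNode))
    for (si in seq_len(k))
      marg[v, si] <- sum(probs[assign_[, v] == states[si]]) / tot
  list(loglik = log(tot), marginals = marg)
}
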