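# Ordered-character Sankoff parsimony: worked examples, brute-force
# enumeration oracle, origin-range semantics, Fitch comparison and an
# independent phangorn cross-check.

test_that("forced single change and invariant-tip base cases", {
  tr2 <- ape::read.tree(text = "(A:1,B:1);")
  r <- sankoffParsimony(tr2, list(A = 0L, B = 1L))
  expect_equal(minCost(r), 1)

  tr <- randomTree(6, seed = 3)
  allZero <- setNames(as.list(rep(0L, 6)), tr$tip.label)
  r0 <- sankoffParsimony(tr, allZero)
  expect_equal(minCost(r0), 0)
  expect_true(all(vapply(mprSets(r0), identical, TRUE, 0L)))
  expect_identical(originRange(r0), c(0L, 0L))
})

test_that("six-tip example matches exhaustive enumeration exactly", {
  tr <- ape::read.tree(text = "(((A,B),(C,D)),(E,F));")
  cm <- list(A = 0L, B = 1L, C = 0L, D = 1L, E = 2L, F = 0L)
  got <- sankoffParsimony(tr, cm)
  oracle <- enumerateParsimony(tr, cm)
  expect_equal(minCost(got), oracle$minCost)
  expect_identical(mprSets(got), oracle$mprSets)
  expect_identical(originRange(got), oracle$originRange)
})

test_that("Sankoff agrees with enumeration on random trees and states", {
  for (seed in 1:25) {
    nTip <- sample(4:8, 1)
    tr <- randomTree(nTip, seed = seed)
    cm <- randomStates(tr, seed = seed + 1000, pAmbiguous = 0.2)
    got <- sankoffParsimony(tr, cm)
    oracle <- enumerateParsimony(tr, cm)
    expect_equal(minCost(got), oracle$minCost, info = paste("seed", seed))
    expect_identical(mprSets(got), oracle$mprSets,
                     info = paste("seed", seed))
    expect_identical(originRange(got), oracle$originRange,
                     info = paste("seed", seed))
  }
})

test_that("polytomies are handled as hard multifurcations", {
  tr <- ape::read.tree(text = "(A,B,C,(D,E));")
  tr$edge.length <- rep(1, nrow(tr$edge))
  cm <- list(A = 0L, B = 1L, C = 2L, D = 1L, E = 0L)
  got <- sankoffParsimony(tr, cm)
  oracle <- enumerateParsimony(tr, cm)
  expect_equal(minCost(got), oracle$minCost)
  expect_identical(mprSets(got), oracle$mprSets)
  expect_identical(originRange(got), oracle$originRange)
})

test_that("ordered min cost is never below unordered (Fitch) min cost", {
  for (seed in 26:40) {
    tr <- randomTree(sample(4:8, 1), seed = seed)
    cm <- randomStates(tr, seed = seed + 2000)
    ordered <- minCost(sankoffParsimony(tr, cm))
    fitch <- minCost(sankoffParsimony(tr, cm,
                                      stepMatrix = unorderedStepMatrix()))
    expect_gte(ordered, fitch)
  }
})

test_that("min cost matches phangorn's Sankoff on binary trees", {
  skip_if_not_installed("phangorn")
  for (seed in 41:48) {
    tr <- randomTree(sample(5:9, 1), seed = seed)
    cm <- randomStates(tr, seed = seed + 3000)
    states <- vapply(cm, `[[`, 0L, 1L)
    pd <- phangorn::phyDat(matrix(as.character(states), ncol = 1,
                                  dimnames = list(names(states), NULL)),
                           type = "USER", levels = c("0", "1", "2"))
    ph <- phangorn::sankoff(tr, pd, cost = orderedStepMatrix())
    expect_equal(minCost(sankoffParsimony(tr, cm)), as.numeric(ph))
  }
})

test_that("origin counting follows the parent-0 to child-molariform rule", {
  tr <- ape::read.tree(text = "((A,B),C);")
  # node numbering: tips A=1 B=2 C=3, root=4, (A,B)=5
  expect_equal(countOrigins(tr, c(1L, 0L, 0L, 0L, 0L)), 1)  # edge 5->A
  expect_equal(countOrigins(tr, c(1L, 2L, 0L, 0L, 0L)), 2)
  expect_equal(countOrigins(tr, c(2L, 2L, 2L, 2L, 2L)), 0)  # no 0 parents
  # chain root(0) -> X(1) -> tip(2): only the 0->1 edge is an origin
  chain <- ape::read.tree(text = "((A),B);")
  expect_equal(countOrigins(chain, c(2L, 0L, 0L, 1L)), 1)
})
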