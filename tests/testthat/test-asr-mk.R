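# Equal-rates Mk model: transition probabilities, pruning likelihood vs
# enumeration, two-pass marginals vs enumeration posteriors, state-label
# symmetry, polytomy equivalence, and rate recovery.

test_that("transition matrix limits and stochasticity", {
  expect_equal(mkTransitionProb(0.7, 0), diag(3))
  expect_equal(mkTransitionProb(50, 50), matrix(1 / 3, 3, 3),
               tolerance = 1e-12)
  for (seed in 1:5) {
    p <- SeqIsoTrim:::.with_seed(seed, c(runif(1, 0, 3), runif(1, 0, 5)))
    P <- mkTransitionProb(p[1], p[2])
    expect_equal(rowSums(P), rep(1, 3))
    expect_true(all(P >= 0))
  }
  expect_error(mkTransitionProb(-1, 1))
})

test_that("single-tip and uninformative likelihoods are exact", {
  tip <- ape::read.tree(text = "(A:1,B:1);")
  # both tips fully missing: total probability 1
  expect_equal(mkLoglik(tip, list(A = 0:2, B = 0:2), rate = 0.4), 0)
  # identical fixed tips at rate ~ 0: probability -> 1/3
  expect_equal(mkLoglik(tip, list(A = 1L, B = 1L), rate = 1e-10),
               log(1 / 3), tolerance = 1e-6)
})

test_that("pruning likelihood equals brute-force enumeration", {
  for (seed in 1:15) {
    tr <- randomTree(sample(3:7, 1), seed = seed)
    cm <- randomStates(tr, seed = seed + 500, pAmbiguous = 0.25)
    rate <- SeqIsoTrim:::.with_seed(seed, runif(1, 0.05, 1.5))
    expect_equal(mkLoglik(tr, cm, rate),
                 enumerateMk(tr, cm, rate)$loglik,
                 tolerance = 1e-10, info = paste("seed", seed))
  }
})

test_that("marginals equal enumeration posteriors to 1e-9", {
  for (seed in 16:30) {
    tr <- randomTree(sample(3:8, 1), seed = seed)
    cm <- randomStates(tr, seed = seed + 600, pAmbiguous = 0.2)
    rate <- SeqIsoTrim:::.with_seed(seed, runif(1, 0.05, 1))
    got <- marginalASR(tr, cm, rate)
    oracle <- enumerateMk(tr, cm, rate)$marginals
    expect_lt(max(abs(got - oracle)), 1e-9)
    expect_equal(rowSums(got), rep(1, nrow(got)), tolerance = 1e-12)
  }
})

test_that("unambiguous tips get point-mass marginals; symmetric root", {
  tr <- ape::read.tree(text = "(A:1,B:1);")
  m <- marginalASR(tr, list(A = 0L, B = 1L), rate = 0.3)
  expect_equal(m[1, ], c(1, 0, 0))
  expect_equal(m[2, ], c(0, 1, 0))
  # root marginal symmetric in states 0 and 1, state 2 least likely
  expect_equal(m[3, 1], m[3, 2], tolerance = 1e-12)
  expect_lt(m[3, 3], m[3, 1])
})

test_that("likelihood is invariant under joint state relabeling", {
  perm <- c(2L, 0L, 1L)                    # state s -> perm[s+1]
  for (seed in 31:38) {
    tr <- randomTree(sample(4:7, 1), seed = seed)
    cm <- randomStates(tr, seed = seed + 700)
    cmP <- lapply(cm, function(s) sort(perm[s + 1L]))
    rate <- 0.37
    expect_equal(mkLoglik(tr, cm, rate), mkLoglik(tr, cmP, rate),
                 tolerance = 1e-12)
  }
})

test_that("a polytomy equals its zero-length binary resolution", {
  tr <- ape::read.tree(text = "(A,B,C,D,(E,F));")
  tr$edge.length <- rep(1, nrow(tr$edge))
  cm <- list(A = 0L, B = 1L, C = 2L, D = 0L, E = 1L, F = 0:2)
  bin <- ape::multi2di(tr, random = FALSE)
  bin$edge.length[is.na(bin$edge.length) | bin$edge.length == 0] <- 0
  for (rate in c(0.1, 0.6)) {
    expect_equal(mkLoglik(tr, cm, rate), mkLoglik(bin, cm, rate),
                 tolerance = 1e-10)
  }
})

test_that("fitRate maximizes the likelihood and flags unidentifiable data", {
  tr <- randomTree(12, seed = 99)
  cm <- simulateMk(tr, rate = 0.4, seed = 11)$tipStates
  fit <- fitRate(tr, cm)
  grid <- c(0.01, 0.05, 0.1, 0.3, 0.5, 1, 2, 5)
  lls <- vapply(grid, function(r) mkLoglik(tr, cm, r), numeric(1))
  expect_true(all(fit@logLik >= lls - 1e-6))
  same <- setNames(as.list(rep(1L, 12)), tr$tip.label)
  expect_warning(f2 <- fitRate(tr, same), "unidentifiable")
  expect_false(f2@identifiable)
})

test_that("ML rate estimate matches ape::ace on a binary tree", {
  tr <- randomTree(20, seed = 30003)
  cm <- simulateMk(tr, rate = 0.3, seed = 40003)$tipStates
  states <- factor(vapply(cm, `[[`, 0L, 1L), levels = 0:2)
  fit <- fitRate(tr, cm, computeMarginals = FALSE)
  a <- ape::ace(states, tr, type = "discrete", model = "ER")
  expect_equal(fit@rateHat, unname(a$rates), tolerance = 1e-4)
  # ace reports the likelihood without the uniform root prior factor 1/3
  expect_equal(fit@logLik, a$loglik - log(3), tolerance = 1e-6)
})

test_that("ML origin ranges follow argmax states with ties broadening", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  cm <- list(A = 1L, B = 1L, C = 0L, D = 0L)
  fit <- fitRate(tr, cm)
  expect_true(fit@mlOriginRange[1] <= fit@mlOriginRange[2])
  expect_true(all(fit@mlOriginRange >= 0))
})
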