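# Shared fixtures: small analytic volumes, random trees with random ordered
# tip states, and a cached small phantom for the imaging tests.

# volume with a single sharp sphere (gray inside/outside), no artifacts.
# For percentile-level tests use steepSphereVolume: its blur reaches enough
# of the background that the 60th gray percentile clears the background
# constant (a constant mode makes the lowest percentile level degenerate).
sphereVolume <- function(n = 40L, radiusVox = 12, inside = 0.9,
                         outside = 0.1, spacing = 0.1, blurSigma = 0) {
  ctr <- (n + 1) / 2
  x <- slice.index(array(0, c(n, n, n)), 1)
  y <- slice.index(array(0, c(n, n, n)), 2)
  z <- slice.index(array(0, c(n, n, n)), 3)
  vals <- ifelse((x - ctr)^2 + (y - ctr)^2 + (z - ctr)^2 <= radiusVox^2,
                 inside, outside)
  if (blurSigma > 0)
    vals <- SeqIsoTrim:::.gauss_blur3(vals, blurSigma)
  VoxelVolume(array(vals, c(n, n, n)), spacing)
}

sphereCenterMm <- function(n = 40L, spacing = 0.1) rep(((n + 1) / 2 - 1) * spacing, 3)

steepSphereVolume <- function() sphereVolume(n = 32L, radiusVox = 13,
                                             spacing = 0.1, blurSigma = 1)

# random rooted tree with nTip tips, uniform unit branch lengths
randomTree <- function(nTip, seed) {
  tr <- SeqIsoTrim:::.with_seed(seed, ape::rtree(nTip, rooted = TRUE))
  tr$edge.length <- rep(1, nrow(tr$edge))
  tr
}

# random tip states over 0:2, with optional ambiguous tips
randomStates <- function(tree, seed, pAmbiguous = 0) {
  SeqIsoTrim:::.with_seed(seed, {
    out <- lapply(tree$tip.label, function(t) {
      if (runif(1) < pAmbiguous) sort(sample(0:2, sample(2:3, 1)))
      else sample(0:2, 1)
    })
    names(out) <- tree$tip.label
    out
  })
}

# small compacted-skull phantom + SIT config used across imaging tests
smallPhantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generatePhantom(compactedSkullSpec(c(72L, 56L, 72L),
                                                   seed = 7L,
                                                   streakCount = 12L))
    cache
  }
})
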