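# Marching-tetrahedra isosurface extraction.

test_that("an analytic sphere is recovered to within one voxel spacing", {
  vol <- sphereVolume(n = 48L, radiusVox = 14, spacing = 0.1,
                      blurSigma = 0.7)
  m <- extractIsosurface(vol, 0.5)
  ctr <- sphereCenterMm(48L, 0.1)
  d <- sqrt(rowSums(sweep(meshVertices(m), 2, ctr)^2))
  expect_lt(abs(mean(d) - 1.4), 0.1)        # mean radius within 1 voxel
  expect_equal(length(unique(componentIds(m))), 1L)
})

test_that("nLevels = 1 yields exactly one mesh at the mid percentile", {
  vol <- sphereVolume()
  ms <- extractIsosurfaces(vol, SITConfig(nLevels = 1L))
  expect_length(ms, 1L)
  expect_true(nFaces(ms[[1]]) > 0)
})

test_that("constant volumes are rejected; out-of-range isovalues are empty", {
  flat <- VoxelVolume(array(0.5, c(8L, 8L, 8L)))
  expect_error(extractIsosurfaces(flat), "constant")
  vol <- sphereVolume()
  empty <- extractIsosurface(vol, 0.95)
  expect_equal(nFaces(empty), 0L)
})

test_that("nested gray levels give nested surfaces", {
  # two concentric spheres: bright core inside dimmer shell
  n <- 48L
  x <- slice.index(array(0, c(n, n, n)), 1)
  y <- slice.index(array(0, c(n, n, n)), 2)
  z <- slice.index(array(0, c(n, n, n)), 3)
  r2 <- (x - 24.5)^2 + (y - 24.5)^2 + (z - 24.5)^2
  vals <- array(0.1 + 0.4 * (r2 <= 16^2) + 0.4 * (r2 <= 8^2), c(n, n, n))
  vol <- VoxelVolume(vals, 0.1)
  lo <- extractIsosurface(vol, 0.3)         # outer boundary
  hi <- extractIsosurface(vol, 0.7)         # inner boundary
  ctr <- sphereCenterMm(n, 0.1)
  rLo <- sqrt(rowSums(sweep(meshVertices(lo), 2, ctr)^2))
  rHi <- sqrt(rowSums(sweep(meshVertices(hi), 2, ctr)^2))
  expect_lt(max(rHi), min(rLo))             # lower isovalue encloses higher
})

test_that("isovalue levels span the configured percentiles evenly", {
  vol <- sphereVolume(blurSigma = 1)
  lv <- isovalueLevels(vol, SITConfig(nLevels = 5L, levelRange = c(10, 90)))
  expect_length(lv, 5L)
  expect_equal(diff(lv), rep(diff(lv)[1], 4), tolerance = 1e-9)
  q <- quantile(volValues(vol), c(0.1, 0.9), names = FALSE)
  expect_equal(lv[1], q[1])
  expect_equal(lv[5], q[2])
})
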