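# Per-slice convolution denoising.

test_that("identity kernel returns the input exactly", {
  vol <- smallPhantom()$volume
  out <- denoise(vol, matrix(1, 1, 1))
  expect_identical(volValues(out), volValues(vol))
})

test_that("normalized kernels leave constant volumes unchanged", {
  vol <- VoxelVolume(array(0.42, c(12L, 8L, 12L)))
  expect_equal(volValues(denoise(vol)), volValues(vol))
  k3 <- array(1 / 27, c(3, 3, 3))
  expect_equal(volValues(denoise(vol, k3)), volValues(vol))
})

test_that("a single bright voxel spreads to a 3x3 in-slice patch of 1/9", {
  vals <- array(0, c(11L, 5L, 11L))
  vals[6, 3, 6] <- 1
  out <- volValues(denoise(VoxelVolume(vals)))
  expect_equal(out[5:7, 3, 5:7], array(1 / 9, c(3, 3)) * matrix(1, 3, 3),
               tolerance = 1e-12)
  expect_equal(sum(out[, 3, ]), 1)          # 2D kernel conserves mass
  expect_true(all(out[, c(1, 2, 4, 5), ] == 0))  # other slices untouched
})

test_that("non-normalized kernels are rejected", {
  vol <- VoxelVolume(array(0.5, c(4L, 4L, 4L)))
  expect_error(denoise(vol, matrix(1, 3, 3)), "normalized")
})
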