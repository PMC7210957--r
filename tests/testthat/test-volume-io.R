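# Volume I/O round trips with spacing and axis convention.

test_that("NRRD float round-trips values, spacing and shape", {
  ph <- generatePhantom(PhantomSpec(gridShape = c(14L, 9L, 11L), seed = 2L,
                                    noiseSd = 0.01,
                                    primitives = list(phantomPrimitive(
                                      "sphere", "bone", gray = 0.8,
                                      center = c(7, 5, 6), radius = 3)),
                                    streakParams = list(count = 2L,
                                                        lengthRange = c(4, 8))))
  f <- tempfile(fileext = ".nrrd")
  writeVolumeNrrd(ph$volume, f)
  back <- readVolumeNrrd(f)
  expect_equal(dim(volValues(back)), dim(volValues(ph$volume)))
  expect_equal(spacingMm(back), spacingMm(ph$volume))
  expect_equal(volValues(back), volValues(ph$volume), tolerance = 1e-6)
  # double type is lossless
  f2 <- tempfile(fileext = ".nrrd")
  writeVolumeNrrd(ph$volume, f2, type = "double")
  expect_identical(volValues(readVolumeNrrd(f2)), volValues(ph$volume))
})

test_that("16-bit NRRD export path quantizes to 1/65535", {
  vol <- VoxelVolume(array(runif(4 * 5 * 6), c(4L, 5L, 6L)), 0.05)
  f <- tempfile(fileext = ".nrrd")
  writeVolumeNrrd(vol, f, type = "ushort")
  back <- readVolumeNrrd(f)
  expect_lt(max(abs(volValues(back) - volValues(vol))), 1 / 65535)
})

test_that("TIFF stack round-trips with the sidecar spacing", {
  vals <- array(seq(0, 1, length.out = 6 * 4 * 5), c(6L, 4L, 5L))
  vol <- VoxelVolume(vals, c(0.038, 0.04, 0.038))
  f <- tempfile(fileext = ".tif")
  writeVolumeTiff(vol, f)
  back <- readVolumeTiff(f)
  expect_equal(dim(volValues(back)), dim(vals))
  expect_equal(spacingMm(back), spacingMm(vol))
  expect_lt(max(abs(volValues(back) - vals)), 1 / 65535)
  # extension dispatch
  expect_equal(dim(volValues(readVolume(f))), dim(vals))
})

test_that("label maps survive NRRD as integers", {
  lbl <- array(sample(0:5, 3 * 4 * 5, replace = TRUE), c(3L, 4L, 5L))
  f <- tempfile(fileext = ".nrrd")
  writeVolumeNrrd(lbl / 5, f, type = "ushort")
  back <- round(volValues(readVolumeNrrd(f)) * 5)
  expect_identical(array(as.integer(back), dim(lbl)), lbl)
})
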