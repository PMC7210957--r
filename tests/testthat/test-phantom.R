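# Synthetic CT phantom: rasterization, determinism, truth consistency,
# streak injection, beam hardening.

test_that("a single sphere rasterizes at its gray level with matching truth", {
  spec <- PhantomSpec(gridShape = c(48L, 48L, 48L), backgroundGray = 0.1,
                      blurSigmaVox = 0, noiseSd = 0,
                      primitives = list(phantomPrimitive(
                        "sphere", "bone", gray = 0.9,
                        center = c(24, 24, 24), radius = 20)))
  ph <- generatePhantom(spec)
  v <- volValues(ph$volume)
  lbl <- ph$truth@labelMap
  x <- slice.index(v, 1); y <- slice.index(v, 2); z <- slice.index(v, 3)
  inside <- (x - 24)^2 + (y - 24)^2 + (z - 24)^2 <= 20^2
  expect_true(all(v[inside] == 0.9))
  expect_true(all(v[!inside] == 0.1))
  expect_true(all(lbl[inside] == 2L))
  s <- ph$truth@surfaces[[1]]
  expect_equal(s$radiiMm, rep(20, 3) * 0.038)
})

test_that("generation is bit-identical for a fixed spec and seed", {
  spec <- compactedSkullSpec(c(40L, 32L, 40L), seed = 5L, streakCount = 6L)
  a <- generatePhantom(spec)
  b <- generatePhantom(spec)
  expect_identical(volValues(a$volume), volValues(b$volume))
  expect_identical(a$truth@labelMap, b$truth@labelMap)
  expect_identical(a$truth@streakMask, b$truth@streakMask)
})

test_that("compacted plates span at most ~7 mm worth of voxels", {
  ph <- smallPhantom()
  lbl <- ph$truth@labelMap
  boneY <- which(apply(lbl == 2L, 2, any))
  spanVox <- diff(range(boneY)) + 1
  expect_lte(spanVox, ceiling(7 / 0.038))   # 7 mm at 38 um pitch
})

test_that("truth labels agree with analytic interiors for >= 99% of voxels", {
  ph <- smallPhantom()
  lbl <- ph$truth@labelMap
  d <- dim(lbl)
  x <- slice.index(lbl, 1); y <- slice.index(lbl, 2); z <- slice.index(lbl, 3)
  for (s in ph$truth@surfaces) {
    if (s$type == "toothShell") {
      q <- ((x - s$centerVox[1]) / s$radiiVox[1])^2 +
           ((y - s$centerVox[2]) / s$radiiVox[2])^2 +
           ((z - s$centerVox[3]) / s$radiiVox[3])^2
      inside <- q <= 1
      frac <- mean(lbl[inside] %in% c(3L, 4L))
      expect_gte(frac, 0.99)
    }
  }
})

test_that("streak injection marks exactly the modified voxels", {
  vol <- VoxelVolume(array(0.2, c(50L, 60L, 50L)), 0.038)
  r <- injectStreaks(vol, list(count = 10L, lengthRange = c(30, 60),
                               thickness = 1L, offsetRange = c(0.2, 0.3),
                               axes = "X", polarity = "bright"), seed = 3L)
  changed <- volValues(r$volume) != volValues(vol)
  expect_identical(r$mask, changed)
  comps <- SeqIsoTrim:::.mask_components(r$mask)
  n <- max(comps)
  expect_lte(n, 10L)                        # streaks may merge by chance
  expect_gte(n, 8L)
  for (k in seq_len(n)) {
    pos <- which(comps == k, arr.ind = TRUE)
    expect_gte(diff(range(pos[, 1])) + 1, 30)   # extent along X
    expect_lte(diff(range(pos[, 2])) + 1, 2)    # thickness elsewhere
    expect_lte(diff(range(pos[, 3])) + 1, 2)
  }
})

test_that("zero streaks leave the volume untouched; repeats are identical", {
  vol <- VoxelVolume(array(0.3, c(20L, 20L, 20L)))
  r0 <- injectStreaks(vol, list(count = 0L), seed = 1L)
  expect_identical(volValues(r0$volume), volValues(vol))
  expect_false(any(r0$mask))
  p <- list(count = 5L, lengthRange = c(5, 10), thickness = 1L,
            offsetRange = c(0.1, 0.2), axes = c("X", "Z"))
  a <- injectStreaks(vol, p, seed = 9L)
  b <- injectStreaks(vol, p, seed = 9L)
  expect_identical(a$mask, b$mask)
  expect_identical(volValues(a$volume), volValues(b$volume))
})

test_that("streak axes are restricted to X and Z", {
  vol <- VoxelVolume(array(0.3, c(20L, 20L, 20L)))
  expect_error(injectStreaks(vol, list(count = 2L, axes = "Y"), seed = 1L),
               "X")
})

test_that("beam hardening has the analytic radial profile and clips", {
  vol <- VoxelVolume(array(0.5, c(41L, 11L, 41L)), 0.1)
  expect_identical(volValues(applyBeamHardening(vol, 0)),
                   volValues(vol))
  out <- volValues(applyBeamHardening(vol, 0.2))
  expect_equal(out[21, 6, 21], 0.5)          # center: r = 0
  expect_equal(out[1, 6, 1], 0.5 * 1.2)      # corner: r = rmax
  # mid-edge: r^2 = rmax^2 / 2
  expect_equal(out[1, 6, 21], 0.5 * (1 + 0.2 / 2))
  big <- applyBeamHardening(VoxelVolume(array(0.9, c(21L, 5L, 21L))), 1)
  expect_true(all(volValues(big) <= 1 & volValues(big) >= 0))
})
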