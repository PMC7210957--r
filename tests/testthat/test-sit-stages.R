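# Streak classification/trimming, redundancy pruning, merging, and
# ambient-occlusion culling.

test_that("a thin axis-aligned tube is a streak; a sphere is not", {
  cfg <- SITConfig(streakThicknessMaxMm = 0.2)
  tube <- meshComponents(tubeMesh(c(0, 0, 0), c(3, 0, 0), radius = 0.05))
  cls <- classifyStreakComponents(tube, cfg)
  expect_length(cls$streak, 1L)
  expect_length(cls$kept, 0L)
  sph <- meshComponents(uvSphereMesh(radius = 1))
  cls2 <- classifyStreakComponents(sph, cfg)
  expect_length(cls2$streak, 0L)
  expect_length(cls2$kept, 1L)
  # a tube along y (the slice axis) is never a streak
  tubeY <- meshComponents(tubeMesh(c(0, 0, 0), c(0, 3, 0), radius = 0.05))
  expect_length(classifyStreakComponents(tubeY, cfg)$streak, 0L)
})

test_that("trimming removes exactly the streak components and conserves faces", {
  cfg <- SITConfig(streakThicknessMaxMm = 0.2)
  tube <- tubeMesh(c(0, 0, 0), c(3, 0, 0), radius = 0.05)
  s1 <- uvSphereMesh(center = c(0, 3, 0), radius = 0.8)
  s2 <- uvSphereMesh(center = c(0, -3, 0), radius = 0.8)
  m <- mergeMeshes(list(tube, s1, s2))
  tr <- trimStreaks(m, cfg)
  st <- trimStages(tr$report)[[1]]
  expect_equal(st$facesKept + st$facesRemoved, st$facesIn)
  expect_equal(st$facesRemoved, nFaces(tube))
  out <- meshComponents(tr$mesh)
  expect_equal(length(unique(componentIds(out))), 2L)
  # no streaks: unchanged
  tr2 <- trimStreaks(mergeMeshes(list(s1, s2)), cfg)
  expect_equal(trimStages(tr2$report)[[1]]$facesRemoved, 0L)
})

test_that("phantom streak components are classified streak, plates are not", {
  ph <- smallPhantom()
  den <- denoise(ph$volume)
  cfg <- SeqIsoTrim:::.resolve_config(SITConfig(), spacingMm(ph$volume))
  iso <- isovalueLevels(den, cfg)
  sp <- spacingMm(ph$volume)
  streakFacesIn <- 0L; streakFacesLeft <- 0L; misclassifiedSkeletal <- 0L
  for (i in c(1, 2, 3, 5, 8)) {
    m <- extractIsosurface(den, iso[i])
    if (!nFaces(m)) next
    cls <- classifyStreakComponents(m, cfg)
    tc <- componentTruthClass(m, ph$truth, sp)
    skelIds <- as.integer(names(tc)[tc == "skeletal"])
    misclassifiedSkeletal <- misclassifiedSkeletal +
      sum(skelIds %in% cls$streak)
    streakIds <- as.integer(names(tc)[tc == "streak"])
    streakFacesIn <- streakFacesIn +
      sum(componentIds(m) %in% streakIds)
    tr <- trimStreaks(m, cfg)
    m2 <- meshComponents(tr$mesh)
    if (nFaces(m2)) {
      tc2 <- componentTruthClass(m2, ph$truth, sp)
      streakFacesLeft <- streakFacesLeft +
        sum(componentIds(m2) %in% as.integer(names(tc2)[tc2 == "streak"]))
    }
  }
  expect_gt(streakFacesIn, 0L)
  expect_equal(misclassifiedSkeletal, 0L)
  # trimming (streak rule + speck filter) removes nearly all streak surface
  expect_lte(streakFacesLeft / streakFacesIn, 0.05)
})

test_that("adjacent-level sphere surfaces are pruned to the lowest isovalue", {
  vol <- steepSphereVolume()
  cfg <- SITConfig()
  lo <- extractIsosurface(vol, 0.48)
  hi <- extractIsosurface(vol, 0.52)       # same steep gradient, < 1 voxel off
  pr <- pruneRedundant(list(hi, lo), cfg, spacingMm = spacingMm(vol))
  expect_length(pr$meshes, 1L)
  expect_equal(isovalue(pr$meshes[[1]]), 0.48)
  st <- trimStages(pr$report)[[1]]
  expect_equal(st$facesKept + st$facesRemoved, st$facesIn)
})

test_that("well-separated surfaces and singletons are retained", {
  s1 <- uvSphereMesh(center = c(0, 0, 0), radius = 1)
  s1@isovalue <- 0.3
  s2 <- uvSphereMesh(center = c(10, 0, 0), radius = 1)
  s2@isovalue <- 0.5
  pr <- pruneRedundant(list(s1, s2), SITConfig(redundancyDistanceMm = 0.1))
  expect_length(pr$meshes, 2L)
  single <- pruneRedundant(list(s1), SITConfig(redundancyDistanceMm = 0.1))
  expect_length(single$meshes, 1L)
  empty <- pruneRedundant(list(), SITConfig(redundancyDistanceMm = 0.1))
  expect_length(empty$meshes, 0L)
})

test_that("pruning keeps the minimum isovalue of every constructed group", {
  # three coincident spheres (a redundancy group) + one far-away surface
  mk <- function(iso, ctr) {
    m <- uvSphereMesh(center = ctr, radius = 1)
    m@isovalue <- iso
    m
  }
  pr <- pruneRedundant(list(mk(0.7, c(0, 0, 0)), mk(0.2, c(0, 0, 0)),
                            mk(0.5, c(0, 0, 0)), mk(0.9, c(9, 9, 9))),
                       SITConfig(redundancyDistanceMm = 0.05))
  isos <- vapply(pr$meshes, isovalue, numeric(1))
  expect_setequal(isos, c(0.2, 0.9))
})

test_that("merging concatenates without welding and preserves coordinates", {
  s1 <- uvSphereMesh(radius = 1, nTheta = 10, nPhi = 6)
  s2 <- uvSphereMesh(center = c(4, 0, 0), radius = 1, nTheta = 14, nPhi = 8)
  m <- mergeMeshes(list(s1, s2))
  expect_equal(nFaces(m), nFaces(s1) + nFaces(s2))
  expect_equal(nVertices(m), nVertices(s1) + nVertices(s2))
  expect_identical(meshVertices(m)[seq_len(nVertices(s1)), ],
                   meshVertices(s1))
  one <- mergeMeshes(list(s1))
  expect_identical(meshVertices(one), meshVertices(s1))
  expect_identical(meshFaces(one), meshFaces(s1))
  none <- mergeMeshes(list())
  expect_equal(nFaces(none), 0L)
})

test_that("an isolated triangle keeps at least its open hemisphere", {
  tri <- IsoSurfaceMesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                        matrix(1:3, 1))
  acc <- faceAccessibility(tri, SITConfig(aoNDirs = 128L, aoEpsMm = 1e-5))
  expect_gte(acc, 0.5 - 0.05)
  cu <- cullOccluded(tri, SITConfig(aoNDirs = 128L, aoEpsMm = 1e-5))
  expect_equal(nFaces(cu$mesh), 1L)
})

test_that("fully enclosed faces are culled, exposed faces kept", {
  inner <- uvSphereMesh(radius = 1, nTheta = 16, nPhi = 10)
  outer <- uvSphereMesh(radius = 2.5, nTheta = 20, nPhi = 12)
  both <- mergeMeshes(list(inner, outer))
  cfg <- SITConfig(aoNDirs = 64L, seed = 3L)
  acc <- faceAccessibility(both, cfg)
  expect_true(all(acc >= 0 & acc <= 1))
  expect_true(all(acc[seq_len(nFaces(inner))] < 0.05))
  expect_true(all(acc[-seq_len(nFaces(inner))] >= 0.2))
  cu <- cullOccluded(both, cfg)
  expect_equal(nFaces(cu$mesh), nFaces(outer))
})

test_that("accessibility never increases when an occluder is added", {
  # ray casting with a fixed origin offset is exactly monotone
  m <- uvSphereMesh(radius = 1, nTheta = 12, nPhi = 8)
  cfg <- SITConfig(aoNDirs = 64L, seed = 5L, aoEpsMm = 1e-4,
                   aoMethod = "raycast")
  alone <- faceAccessibility(m, cfg)
  shell <- uvSphereMesh(radius = 3, nTheta = 16, nPhi = 10)
  both <- mergeMeshes(list(m, shell))
  together <- faceAccessibility(both, cfg)[seq_len(nFaces(m))]
  expect_true(all(together <= alone + 1e-12))
})

test_that("too few ambient-occlusion directions are rejected", {
  m <- uvSphereMesh(radius = 1)
  cfg <- SITConfig()
  cfg@aoNDirs <- 3L
  expect_error(faceAccessibility(m, cfg), "aoNDirs")
  expect_error(faceAccessibility(IsoSurfaceMesh(matrix(numeric(), 0, 3),
                                                matrix(integer(), 0, 3)),
                                 SITConfig()), "empty")
})
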