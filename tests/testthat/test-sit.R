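# Full Sequential Isosurface Trimming runs on small phantoms.

test_that("artifact-free sphere phantom collapses to one surface", {
  vol <- steepSphereVolume()
  res <- runSIT(vol, SITConfig(nLevels = 20L, kernel = matrix(1, 1, 1)))
  st <- trimStages(res$report)
  prune <- Filter(function(s) s$stage == "prune_redundant", st)[[1]]
  # the 20 level sets of one steep-gradient sphere are mutually redundant:
  # a single survivor at the lowest gray level
  expect_equal(prune$surfacesKept, 1L)
  expect_equal(prune$keptIsovalues,
               min(isovalueLevels(vol, SITConfig(nLevels = 20L))),
               tolerance = 1e-9)
  expect_equal(length(unique(componentIds(meshComponents(res$mesh)))), 1L)
})

test_that("full pipeline on a streaky phantom removes streaks and recovers truth", {
  ph <- smallPhantom()
  stats <- phantomRecoveryStats(ph, SITConfig(seed = 11L))
  expect_true(stats$conservationHolds)
  expect_gt(stats$streakComponentsTotal, 0L)
  expect_gte(stats$streakRemovalRate, 0.95)
  expect_gte(stats$truthSurfaceCoverage, 0.95)
  expect_lte(stats$meshToTruthMeanVox, 2)
  expect_equal(stats$finalStreakCriterionComponents, 0L)
})

test_that("identical volume, config and seed reproduce the run exactly", {
  ph <- smallPhantom()
  cfg <- SITConfig(nLevels = 8L, seed = 4L)
  a <- runSIT(ph$volume, cfg)
  b <- runSIT(ph$volume, cfg)
  expect_identical(meshVertices(a$mesh), meshVertices(b$mesh))
  expect_identical(meshFaces(a$mesh), meshFaces(b$mesh))
  ra <- vapply(trimStages(a$report), function(s)
    if (is.null(s$facesIn)) NA_integer_ else s$facesRemoved, integer(1))
  rb <- vapply(trimStages(b$report), function(s)
    if (is.null(s$facesIn)) NA_integer_ else s$facesRemoved, integer(1))
  expect_identical(ra, rb)
})
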