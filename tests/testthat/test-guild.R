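# Massare guild metrics: worked specimen values, boundary semantics,
# invariances.

test_that("worked specimen measurements reproduce the published metrics", {
  expect_equal(crownShapeIndex(3.13, 1.65), 1.90)
  expect_equal(relativeToothSize(3.13, 30.2), 0.104)
  expect_equal(estimateSkullWidth(15.1), 30.2)
  g <- assessGuild(3.13, 1.65, hemiWidthMm = 15.1)
  expect_identical(guildLabel(g), "crushing")
  expect_true(g@criteriaTrace$csiAbove)
  expect_true(g@criteriaTrace$rtsAtOrAbove)
})

test_that("simple ratios and error cases behave", {
  expect_equal(crownShapeIndex(1, 1), 1.00)
  expect_equal(crownShapeIndex(2, 4), 0.500)
  expect_equal(relativeToothSize(1, 10), 0.100)
  expect_equal(relativeToothSize(0.5, 30.2), 0.0166)
  expect_equal(estimateSkullWidth(1.0), 2.0)
  expect_error(estimateSkullWidth(0))
  expect_error(crownShapeIndex(3.13, 0))
  expect_error(relativeToothSize(3.13, 0))
})

test_that("guild boundaries are strict for the index, inclusive for size", {
  expect_identical(guildLabel(classifyGuild(1.0, 0.5)), "not_crushing")
  expect_identical(guildLabel(classifyGuild(2.0, 0.1)), "crushing")
  expect_identical(guildLabel(classifyGuild(1.0000001, 0.1)), "crushing")
  expect_identical(guildLabel(classifyGuild(5, 0.0999)), "not_crushing")
})

test_that("metrics are scale invariant and the classifier is monotone", {
  for (s in c(0.5, 2, 17.3)) {
    expect_equal(crownShapeIndex(3.13 * s, 1.65 * s), crownShapeIndex(3.13, 1.65))
    expect_equal(relativeToothSize(3.13 * s, 30.2 * s),
                 relativeToothSize(3.13, 30.2))
  }
  # increasing either metric never flips crushing -> not_crushing
  base <- expand.grid(csi = c(0.5, 1.0, 1.5, 3), rts = c(0.05, 0.1, 0.3))
  for (i in seq_len(nrow(base))) {
    l0 <- guildLabel(classifyGuild(base$csi[i], base$rts[i]))
    for (dcsi in c(0, 0.4)) for (drts in c(0, 0.2)) {
      l1 <- guildLabel(classifyGuild(base$csi[i] + dcsi, base$rts[i] + drts))
      if (l0 == "crushing") expect_identical(l1, "crushing")
    }
  }
})
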