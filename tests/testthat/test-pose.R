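# Jaw-pose machinery: mirroring, overlap semantics, the constrained solver,
# rigidity, and posture-width queries.

test_that("mirroring is an involution and preserves plane distances", {
  m <- toyRamusMesh()$mesh
  mm <- mirrorMesh(mirrorMesh(m))
  expect_equal(meshVertices(mm), meshVertices(m), tolerance = 1e-12)
  expect_identical(meshFaces(mm), meshFaces(m))
  # a point on the plane maps to itself
  onPlane <- IsoSurfaceMesh(rbind(c(0, 1, 2), c(0, -1, 0), c(0, 0, 5)),
                            matrix(1:3, 1))
  expect_equal(meshVertices(mirrorMesh(onPlane)), meshVertices(onPlane))
  d0 <- abs(mean(meshVertices(m)[, 1]))
  d1 <- abs(mean(meshVertices(mirrorMesh(m))[, 1]))
  expect_equal(d0, d1)
  expect_error(mirrorMesh(m, planeNormal = c(2, 0, 0)), "unit")
})

test_that("overlap detection matches analytic sphere geometry", {
  s <- function(cx) uvSphereMesh(center = c(cx, 0, 0), radius = 1,
                                 nTheta = 28, nPhi = 20)
  far <- checkOverlap(s(0), s(3))
  expect_false(far$overlap)
  expect_equal(far$minDistanceMm, 1, tolerance = 0.02)
  same <- checkOverlap(s(0), s(0))
  expect_true(same$overlap)
  pen <- checkOverlap(s(0), s(1.5))
  expect_true(pen$overlap)
  expect_equal(pen$penetrationDepthMm, 0.5, tolerance = 0.02)
  expect_error(checkOverlap(s(0), IsoSurfaceMesh(matrix(numeric(), 0, 3),
                                                 matrix(integer(), 0, 3))),
               "non-empty")
})

test_that("quarter-torus ramus reaches the closed-form optimum", {
  toy <- toyRamusMesh(jointToTipLateralMm = 15.1, tubeRadius = 1.2)
  cfg <- PoseConfig(skullWidthMm = 30.2, angleGridDeg = 1)
  sol <- solvePose(toy$mesh, toy$landmarks, cfg)
  expect_true(sol@feasible)
  expect_true(all(sol@constraintsSatisfied))
  # at zero angles the tip centerline touches the plane but the tube (radius
  # 1.2) crosses it; the optimum backs the tip off by about the amount that
  # lifts the tube clear, bounded by the tube radius plus grid slack
  expect_lte(sol@objectiveValue, 1.2 + 30.2 * (pi / 180))
  # returned pose violates no overlap: right mesh stays on x >= 0
  posed <- transformMesh(toy$mesh, sol@rightTransform)
  expect_gte(min(meshVertices(posed)[, 1]), -1e-6)
  ov <- checkOverlap(posed, mirrorMesh(posed))
  expect_false(ov$overlap)
  # the joint is pinned at half the skull width
  j <- as.numeric(sol@rightTransform %*% c(toy$landmarks@jointPoint, 1))
  expect_equal(j[1], 15.1, tolerance = 1e-6)
})

test_that("a short straight ramus cannot reach the plane: analytic residual", {
  # straight tube of length 10 from joint toward the midline; joint pinned at
  # x = 15.1, so the tip cannot get closer than 5.1 mm to the plane
  start <- c(0, 0, 0); end <- c(-10, 0, 0)
  bar <- tubeMesh(start, end, radius = 0.5, nTheta = 10, nSeg = 6)
  lm <- RamusLandmarks(jointPoint = start, anteriorTip = end)
  sol <- solvePose(bar, lm, PoseConfig(skullWidthMm = 30.2,
                                       angleGridDeg = 1))
  expect_true(sol@feasible)
  expect_equal(sol@objectiveValue, 15.1 - 10, tolerance = 0.05)
})

test_that("returned transforms are rigid and bilaterally symmetric", {
  toy <- toyRamusMesh()
  sol <- solvePose(toy$mesh, toy$landmarks, PoseConfig(angleGridDeg = 2))
  R <- sol@rightTransform[1:3, 1:3]
  expect_equal(crossprod(R), diag(3), tolerance = 1e-9)
  expect_equal(det(R), 1, tolerance = 1e-9)
  V <- meshVertices(toy$mesh)[c(1, 10, 40), ]
  dBefore <- dist(V)
  dAfter <- dist(cbind(V, 1) %*% t(sol@rightTransform))
  expect_equal(as.numeric(dAfter), as.numeric(dBefore), tolerance = 1e-9)
  # left transform is exactly the sagittal mirror of the right
  S <- diag(4); S[1, 1] <- -1
  expect_equal(sol@leftTransform, S %*% sol@rightTransform)
})

test_that("grid refinement never worsens the objective", {
  toy <- toyRamusMesh(jointToTipLateralMm = 12, tubeRadius = 1)
  coarse <- solvePose(toy$mesh, toy$landmarks,
                      PoseConfig(skullWidthMm = 24, angleGridDeg = 4,
                                 refine = FALSE))
  fine <- solvePose(toy$mesh, toy$landmarks,
                    PoseConfig(skullWidthMm = 24, angleGridDeg = 1,
                               refine = FALSE))
  expect_lte(fine@objectiveValue, coarse@objectiveValue + 1e-9)
})

test_that("widthAtPosture is consistent with a solved pose and mirrors", {
  toy <- toyRamusMesh()
  sol <- solvePose(toy$mesh, toy$landmarks, PoseConfig(angleGridDeg = 2))
  expect_equal(widthAtPosture(toy$mesh, toy$landmarks, sol), 30.2,
               tolerance = 1e-6)
  # tip pinned on the plane: the joint sits at the canonical origin, so the
  # width is 2 L sin(yaw) where L is the joint-tip chord; for the quarter
  # torus L = 15.1 * sqrt(2), hence yaw 45 deg gives exactly 2 * 15.1
  w <- widthAtPosture(toy$mesh, toy$landmarks,
                      list(anglesDeg = c(0, 45), anchor = "tip"))
  expect_equal(w, 2 * 15.1, tolerance = 1e-9)
  expect_equal(widthAtPosture(toy$mesh, toy$landmarks,
                              list(anglesDeg = c(0, 0), anchor = "tip")),
               0, tolerance = 1e-9)
})

test_that("infeasible problems return an explicit infeasibility result", {
  # giant tube so wide that any pose pierces the sagittal plane
  fat <- tubeMesh(c(0, 0, 0), c(-4, 0, 0), radius = 40, nTheta = 12,
                  nSeg = 4)
  lm <- RamusLandmarks(jointPoint = c(0, 0, 0), anteriorTip = c(-4, 0, 0))
  sol <- solvePose(fat, lm, PoseConfig(skullWidthMm = 10, angleGridDeg = 5,
                                       yawRangeDeg = c(-10, 10),
                                       inclinationRangeDeg = c(-10, 10)))
  expect_false(sol@feasible)
  expect_false(all(sol@constraintsSatisfied))
})
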