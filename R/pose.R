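# Bilateral jaw-pose reconstruction.  Coordinate convention: the sagittal
# plane is x = 0 with x lateral (right ramus at x > 0), y anterior, z dorsal.
# The pose family has two angles -- inclination (roll about the ramus long
# axis) and yaw -- with the jaw-joint point pinned at x = +skullWidth/2.  The
# left ramus is always the exact sagittal mirror of the right.

#' Construct ramus landmarks
#'
#' @param jointPoint 3D point (mm) at the jaw-joint contact.
#' @param anteriorTip 3D point (mm) at the rostral tip.
#' @param longAxis optional unit direction from tip to joint; derived from
#'   the two points when omitted.
#' @return a [RamusLandmarks-class].
#' @export
RamusLandmarks <- function(jointPoint, anteriorTip, longAxis = NULL) {
  if (is.null(longAxis)) longAxis <- .unit(jointPoint - anteriorTip)
  new("RamusLandmarks", jointPoint = as.numeric(jointPoint),
      anteriorTip = as.numeric(anteriorTip),
      longAxis = as.numeric(longAxis))
}

#' Construct a PoseConfig
#'
#' @param skullWidthMm target joint-to-joint separation (default 30.2 mm).
#' @param angleGridDeg angular grid resolution in degrees.
#' @param overlapToleranceMm minimum allowed clearance between the rami.
#' @param inclinationRangeDeg,yawRangeDeg search ranges in degrees.
#' @param refine run continuous local refinement after the grid search.
#' @return a [PoseConfig-class].
#' @export
PoseConfig <- function(skullWidthMm = 30.2, angleGridDeg = 1,
                       overlapToleranceMm = 0,
                       inclinationRangeDeg = c(-90, 90),
                       yawRangeDeg = c(-60, 60), refine = TRUE) {
  new("PoseConfig", skullWidthMm = skullWidthMm,
      angleGridDeg = angleGridDeg,
      overlapToleranceMm = overlapToleranceMm,
      inclinationRangeDeg = inclinationRangeDeg,
      yawRangeDeg = yawRangeDeg, refine = refine)
}

#' Mirror a mesh across a plane
#'
#' Reflects vertices across the plane given by a point and unit normal and
#' flips the face winding so surface orientation is preserved.  Applying the
#' same mirror twice restores the original mesh exactly.
#'
#' @param mesh an [IsoSurfaceMesh-class].
#' @param planePoint point on the mirror plane (default origin).
#' @param planeNormal unit plane normal (default the x axis: the sagittal
#'   plane x = 0).
#' @return the mirrored mesh.
#' @export
mirrorMesh <- function(mesh, planePoint = c(0, 0, 0),
                       planeNormal = c(1, 0, 0)) {
  if (abs(sqrt(sum(planeNormal^2)) - 1) > 1e-8)
    stop("planeNormal must have unit norm")
  V <- mesh@vertices
  d <- (V - matrix(planePoint, nrow(V), 3, byrow = TRUE)) %*% planeNormal
  mesh@vertices <- V - 2 * d %*% t(planeNormal)
  mesh@faces <- mesh@faces[, c(1, 3, 2), drop = FALSE]
  mesh
}

#' Test whether two mesh surfaces overlap
#'
#' Overlap means the surfaces interpenetrate or approach closer than
#' `toleranceMm`.  Penetration is assessed by a parity inside test of each
#' mesh's vertices against the other surface (meaningful for closed meshes);
#' proximity uses exact vertex-to-triangle distances both ways.
#'
#' @param meshA,meshB non-empty [IsoSurfaceMesh-class] objects.
#' @param toleranceMm minimum allowed clearance (default 0).
#' @return list: `overlap` (logical), `penetrationDepthMm` (max depth of a
#'   vertex inside the other mesh; 0 when disjoint), `minDistanceMm`
#'   (minimum inter-surface distance; 0 when interpenetrating).
#' @export
checkOverlap <- function(meshA, meshB, toleranceMm = 0) {
  if (!nrow(meshA@faces) || !nrow(meshB@faces))
    stop("checkOverlap requires non-empty meshes")
  dAB <- .point_mesh_dist(meshA@vertices, meshB@vertices, meshB@faces)
  dBA <- .point_mesh_dist(meshB@vertices, meshA@vertices, meshA@faces)
  inAB <- .points_in_mesh(meshA@vertices, meshB@vertices, meshB@faces)
  inBA <- .points_in_mesh(meshB@vertices, meshA@vertices, meshA@faces)
  pen <- 0
  if (any(inAB)) pen <- max(pen, max(dAB[inAB]))
  if (any(inBA)) pen <- max(pen, max(dBA[inBA]))
  minDist <- if (pen > 0) 0 else min(dAB, dBA)
  # surfaces coinciding over a region (not a mere touch point) overlap too
  coincident <- mean(dAB < 1e-7) > 0.1 || mean(dBA < 1e-7) > 0.1
  list(overlap = pen > 1e-6 || coincident || minDist < toleranceMm,
       penetrationDepthMm = pen, minDistanceMm = minDist)
}

# canonical frame: joint at the origin, anterior direction (tip -> away from
# joint) along +y.  Returns the 4x4 transform into the canonical frame.
.canonical_transform <- function(landmarks) {
  anterior <- -landmarks@longAxis            # longAxis runs tip -> joint
  R0 <- .rot_between(anterior, c(0, 1, 0))
  T0 <- diag(4)
  T0[1:3, 1:3] <- R0
  T0[1:3, 4] <- -R0 %*% landmarks@jointPoint
  T0
}

# pose transform for angles (radians) + joint pinned at (w2, 0, 0):
# yaw about z after inclination (roll) about the canonical long axis (y)
.pose_transform <- function(T0, incl, yaw, w2) {
  R <- .rot_axis(c(0, 0, 1), yaw) %*% .rot_axis(c(0, 1, 0), incl)
  M <- diag(4)
  M[1:3, 1:3] <- R
  M[1, 4] <- w2
  M %*% T0
}

#' Solve the bilateral jaw pose
#'
#' Grid search (then local refinement) over inclination about the ramus long
#' axis and yaw, with the jaw-joint point pinned at half the skull width from
#' the sagittal plane.  The objective is the anterior tip's distance to the
#' sagittal plane, minimized subject to (a) the two mirrored rami do not
#' overlap and (b) the tip does not cross to the far side of the plane.
#' Because the left ramus is the exact mirror of the right, the minimum
#' distance between the two rami equals twice the right ramus's minimum
#' vertex x, which is what the solver constrains.
#'
#' @param mesh right-ramus [IsoSurfaceMesh-class] (mesh coordinates).
#' @param landmarks a [RamusLandmarks-class] in mesh coordinates.
#' @param config a [PoseConfig-class].
#' @return a [PoseSolution-class]; when no pose on the grid satisfies the
#'   constraints the solution has `feasible = FALSE` and reports the least
#'   infeasible candidate (no exception is thrown).
#' @export
solvePose <- function(mesh, landmarks, config = PoseConfig()) {
  validObject(config)
  w2 <- config@skullWidthMm / 2
  tol2 <- config@overlapToleranceMm / 2
  T0 <- .canonical_transform(landmarks)
  Vc <- cbind(mesh@vertices, 1) %*% t(T0)
  Vc <- Vc[, 1:3, drop = FALSE]
  tipC <- as.numeric(T0 %*% c(landmarks@anteriorTip, 1))[1:3]

  evalPose <- function(incl, yaw) {
    R <- .rot_axis(c(0, 0, 1), yaw) %*% .rot_axis(c(0, 1, 0), incl)
    Vx <- Vc %*% R[1, ]                     # only x coordinates needed
    tip <- as.numeric(R %*% tipC)
    minx <- min(Vx) + w2
    tipx <- tip[1] + w2
    list(minx = minx, tipx = tipx)
  }

  grid_pass <- function(incls, yaws) {
    best <- NULL
    bestInfeas <- NULL
    cosY <- cos(yaws); sinY <- sin(yaws)
    for (incl in incls) {
      Ry <- .rot_axis(c(0, 1, 0), incl)
      Vr <- Vc %*% t(Ry)
      tipR <- as.numeric(Ry %*% tipC)
      # x' = cos(yaw) x - sin(yaw) y, vectorized over yaw
      X <- Vr[, 1:2, drop = FALSE] %*% rbind(cosY, -sinY)
      minx <- apply(X, 2, min) + w2
      tipx <- tipR[1] * cosY - tipR[2] * sinY + w2
      feas <- minx >= tol2 - 1e-9 & tipx >= -1e-9
      if (any(feas)) {
        k <- which(feas)[which.min(tipx[feas])]
        if (is.null(best) || tipx[k] < best$tipx)
          best <- list(incl = incl, yaw = yaws[k], tipx = tipx[k],
                       minx = minx[k])
      }
      viol <- pmax(tol2 - minx, 0) + pmax(-tipx, 0)
      k2 <- which.min(viol + 1e-6 * abs(tipx))
      if (is.null(bestInfeas) || viol[k2] < bestInfeas$viol)
        bestInfeas <- list(incl = incl, yaw = yaws[k2], tipx = tipx[k2],
                           minx = minx[k2], viol = viol[k2])
    }
    list(best = best, bestInfeas = bestInfeas)
  }

  step <- config@angleGridDeg * pi / 180
  ir <- config@inclinationRangeDeg * pi / 180
  yr <- config@yawRangeDeg * pi / 180
  # coarse pass at 5x the grid, then the configured grid around the best
  coarse <- grid_pass(seq(ir[1], ir[2], by = 5 * step),
                      seq(yr[1], yr[2], by = 5 * step))
  centre <- if (!is.null(coarse$best)) coarse$best else coarse$bestInfeas
  incls <- seq(max(ir[1], centre$incl - 6 * step),
               min(ir[2], centre$incl + 6 * step), by = step)
  yaws <- seq(max(yr[1], centre$yaw - 6 * step),
              min(yr[2], centre$yaw + 6 * step), by = step)
  fine <- grid_pass(incls, yaws)
  best <- fine$best
  if (is.null(best) && !is.null(coarse$best)) best <- coarse$best

  if (!is.null(best) && config@refine) {
    pen <- function(p) {
      e <- evalPose(p[1], p[2])
      e$tipx + 1e6 * (pmax(tol2 - e$minx, 0) + pmax(-e$tipx, 0))
    }
    opt <- optim(c(best$incl, best$yaw), pen, method = "Nelder-Mead",
                 control = list(maxit = 200, reltol = 1e-10))
    e <- evalPose(opt$par[1], opt$par[2])
    if (e$minx >= tol2 - 1e-9 && e$tipx >= -1e-9 && e$tipx <= best$tipx)
      best <- list(incl = opt$par[1], yaw = opt$par[2], tipx = e$tipx,
                   minx = e$minx)
  }

  feasible <- !is.null(best)
  sol <- if (feasible) best else fine$bestInfeas
  M <- .pose_transform(T0, sol$incl, sol$yaw, w2)
  S <- diag(4); S[1, 1] <- -1
  constraints <- c(width = TRUE,
                   noOverlap = sol$minx >= tol2 - 1e-9,
                   noDivergence = sol$tipx >= -1e-9)
  new("PoseSolution", rightTransform = M, leftTransform = S %*% M,
      tipGapMm = max(0, 2 * sol$tipx), objectiveValue = max(0, sol$tipx),
      constraintsSatisfied = constraints, feasible = feasible,
      anglesDeg = c(inclination = sol$incl * 180 / pi,
                    yaw = sol$yaw * 180 / pi))
}

#' Mandibular width under a fixed posture
#'
#' Reports the joint-to-joint separation of the mirrored pair when the right
#' ramus is posed as specified: either by a [PoseSolution-class] (returns the
#' solved skull width), or by angles with an anchoring rule -- `"joint"`
#' pins the joint at `anchorX`, `"tip"` pins the anterior tip on the sagittal
#' plane (e.g. the tooth-rows-tip-to-tip diagnostic posture).
#'
#' @param mesh right-ramus [IsoSurfaceMesh-class].
#' @param landmarks a [RamusLandmarks-class].
#' @param postureSpec a [PoseSolution-class], or a list with `anglesDeg`
#'   (inclination, yaw), `anchor` ("joint" or "tip") and optional `anchorX`
#'   (mm, default 0 for "tip").
#' @return joint-to-joint width in mm.
#' @export
widthAtPosture <- function(mesh, landmarks, postureSpec) {
  if (is(postureSpec, "PoseSolution")) {
    j <- as.numeric(postureSpec@rightTransform %*%
                      c(landmarks@jointPoint, 1))[1:3]
    return(2 * abs(j[1]))
  }
  T0 <- .canonical_transform(landmarks)
  ang <- postureSpec$anglesDeg * pi / 180
  R <- .rot_axis(c(0, 0, 1), ang[2]) %*% .rot_axis(c(0, 1, 0), ang[1])
  jC <- rep(0, 3)                            # joint at canonical origin
  tipC <- as.numeric(T0 %*% c(landmarks@anteriorTip, 1))[1:3]
  jR <- as.numeric(R %*% jC); tipR <- as.numeric(R %*% tipC)
  anchor <- if (is.null(postureSpec$anchor)) "joint" else postureSpec$anchor
  shift <- switch(anchor,
                  joint = (if (is.null(postureSpec$anchorX))
                    stop("anchorX required for joint anchoring")
                    else postureSpec$anchorX) - jR[1],
                  tip = (if (is.null(postureSpec$anchorX)) 0
                         else postureSpec$anchorX) - tipR[1],
                  stop("anchor must be 'joint' or 'tip'"))
  2 * abs(jR[1] + shift)
}
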