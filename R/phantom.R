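# Synthetic CT phantom generator.  The phantom emulates the statistical
# structure of a micro-CT scan of a severely compacted fossil: thin bone
# plates, thin-walled tooth shells with darker interiors, dense concretion
# matrix, additive gaussian image noise, axis-aligned streak artifacts and a
# radial beam-hardening gradient.  Every primitive carries a ground-truth
# label and a closed-form outer surface so downstream stages can be validated.

# truth labels
.LBL <- c(background = 0L, matrix = 1L, bone = 2L, tooth_wall = 3L,
          tooth_interior = 4L, streak = 5L)

#' Describe a phantom primitive
#'
#' Supported types: `"slab"` (an axis-aligned plate: compacted bone sheet),
#' `"sphere"`, `"ellipsoid"` (solid; used for bone nodules or concretion
#' matrix), and `"toothShell"` (an ellipsoid shell with a dense wall and a
#' darker interior, emulating thin-walled tooth crowns).
#'
#' @param type one of "slab", "sphere", "ellipsoid", "toothShell".
#' @param label truth label: "matrix", "bone" or "tooth" ("tooth" rasterizes
#'   as wall + interior).
#' @param gray gray level in `[0,1]` of the solid (or shell wall).
#' @param center voxel-index center (x, y, z), 1-based.
#' @param radius scalar radius in voxels (sphere).
#' @param radii numeric(3) semi-axes in voxels (ellipsoid/toothShell).
#' @param axis slab normal axis: "X", "Y" or "Z".
#' @param thickness slab thickness in voxels.
#' @param extent optional named list of index ranges limiting a slab, e.g.
#'   `list(x = c(20, 140), z = c(30, 130))`.
#' @param wallThickness shell wall thickness in voxels (>= 1).
#' @param interiorGray gray level of the shell interior.
#' @param grayRamp optional linear gray gradient across a slab: numeric(2)
#'   `c(from, to)` applied along the slab's normal axis (emulates graded /
#'   layered concretion matrix, so the matrix has no flat gray mode).
#' @return a list usable in the `primitives` slot of a [PhantomSpec-class].
#' @export
phantomPrimitive <- function(type, label, gray, center = NULL, radius = NULL,
                             radii = NULL, axis = "Y", thickness = NULL,
                             extent = NULL, wallThickness = 2,
                             interiorGray = NULL, grayRamp = NULL) {
  type <- match.arg(type, c("slab", "sphere", "ellipsoid", "toothShell"))
  label <- match.arg(label, c("matrix", "bone", "tooth"))
  p <- list(type = type, label = label, gray = gray, center = center,
            radius = radius, radii = radii, axis = axis,
            thickness = thickness, extent = extent,
            wallThickness = wallThickness, interiorGray = interiorGray,
            grayRamp = grayRamp)
  if (type == "toothShell" && is.null(interiorGray))
    p$interiorGray <- max(0, gray - 0.55)
  p
}

#' Construct a PhantomSpec
#'
#' @param gridShape voxel counts (X, Y slices, Z).
#' @param voxelSpacingMm voxel pitch in mm (length 1 or 3; default 0.038).
#' @param seed integer RNG seed.
#' @param backgroundGray background gray level.
#' @param primitives list of [phantomPrimitive()] descriptions.
#' @param streakParams list with `count`, `lengthRange`, `thickness`,
#'   `offsetRange`, `axes`, `polarity`.
#' @param beamHardeningStrength amplitude of the radial gray gradient.
#' @param blurSigmaVox partial-volume gaussian sigma in voxels.
#' @param noiseSd additive gaussian noise sd.
#' @return a [PhantomSpec-class] object.
#' @export
PhantomSpec <- function(gridShape = c(160L, 120L, 160L),
                        voxelSpacingMm = 0.038, seed = 1L,
                        backgroundGray = 0.1, primitives = list(),
                        streakParams = list(),
                        beamHardeningStrength = 0, blurSigmaVox = 0.7,
                        noiseSd = 0.02) {
  if (length(voxelSpacingMm) == 1L) voxelSpacingMm <- rep(voxelSpacingMm, 3L)
  proto <- new("PhantomSpec")
  sp <- proto@streakParams
  sp[names(streakParams)] <- streakParams
  new("PhantomSpec", gridShape = as.integer(gridShape),
      voxelSpacingMm = as.numeric(voxelSpacingMm), seed = as.integer(seed),
      backgroundGray = backgroundGray, primitives = primitives,
      streakParams = sp, beamHardeningStrength = beamHardeningStrength,
      blurSigmaVox = blurSigmaVox, noiseSd = noiseSd)
}

#' Default compacted-skull phantom specification
#'
#' The packaged study phantom emulates a partially prepared compacted
#' specimen: a dense, graded concretion-matrix slab occupies one side of the
#' field (inset from the volume boundary so its surface is closed), while
#' the exposed skeleton — three thin bone plates stacked along the slice
#' axis, spanning far less than 7 mm at 0.038 mm pitch, carrying two rows of
#' thin-walled tooth shells with darker interiors — sits free in air beside
#' it.  Bright and dark streak artifacts run parallel to the in-slice X and
#' Z axes on separated slices; gaussian image noise and a mild radial
#' beam-hardening gradient complete the artifact budget.  The free-standing
#' arrangement keeps every skeletal truth surface measurable after
#' occlusion culling (a surface buried in matrix is, correctly, culled as
#' concealed).
#'
#' @param gridShape voxel counts; the default (112 x 84 x 112) keeps a full
#'   pipeline run at a few minutes on one CPU.
#' @param seed RNG seed.
#' @param streakCount number of injected streaks (capped by the number of
#'   separable slice slots).
#' @return a [PhantomSpec-class].
#' @export
compactedSkullSpec <- function(gridShape = c(112L, 84L, 112L), seed = 1L,
                               streakCount = 14L) {
  nx <- gridShape[1]; ny <- gridShape[2]; nz <- gridShape[3]
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  prims <- list(
    # graded concretion slab along one side of the field, closed surface
    phantomPrimitive("slab", "matrix", gray = 0.34,
                     center = c(cx, cy, 0.25 * nz),
                     axis = "Z", thickness = 0.44 * nz,
                     extent = list(x = c(4, nx - 3), y = c(4, ny - 3)),
                     grayRamp = c(0.28, 0.40)),
    # compacted bone plates (thin sheets) at different depths along the
    # compaction (Y) axis, laterally staggered so no plate lies over
    # another: facing surfaces across a narrow gap would be concealed,
    # which is realistic but would make their truth surfaces unmeasurable
    phantomPrimitive("slab", "bone", gray = 0.58, center = c(cx, cy - 14, 0),
                     axis = "Y", thickness = 5,
                     extent = list(x = c(0.06 * nx, 0.34 * nx),
                                   z = c(0.56 * nz, 0.94 * nz))),
    phantomPrimitive("slab", "bone", gray = 0.62, center = c(cx, cy, 0),
                     axis = "Y", thickness = 4,
                     extent = list(x = c(0.38 * nx, 0.64 * nx),
                                   z = c(0.58 * nz, 0.90 * nz))),
    phantomPrimitive("slab", "bone", gray = 0.55, center = c(cx, cy + 13, 0),
                     axis = "Y", thickness = 6,
                     extent = list(x = c(0.68 * nx, 0.94 * nx),
                                   z = c(0.60 * nz, 0.92 * nz)))
  )
  # two rows of scattered thin-walled tooth shells above the plates, spaced
  # so neighbouring shells stay mutually visible
  toothY <- cy + 25
  xs <- round(seq(0.24 * nx, 0.60 * nx, length.out = 3))
  for (k in seq_along(xs)) {
    prims[[length(prims) + 1L]] <- phantomPrimitive(
      "toothShell", "tooth", gray = 0.92,
      center = c(xs[k], toothY, round(0.64 * nz)),
      radii = c(6, 5, 7), wallThickness = 2, interiorGray = 0.35)
    prims[[length(prims) + 1L]] <- phantomPrimitive(
      "toothShell", "tooth", gray = 0.9,
      center = c(xs[k], toothY, round(0.86 * nz)),
      radii = c(5, 4.5, 6), wallThickness = 2, interiorGray = 0.35)
  }
  PhantomSpec(gridShape = gridShape, seed = seed,
              primitives = prims,
              streakParams = list(count = as.integer(streakCount),
                                  lengthRange = c(60, 140), thickness = 1L,
                                  offsetRange = c(0.2, 0.45),
                                  axes = c("X", "Z"), polarity = "both"),
              beamHardeningStrength = 0.15, blurSigmaVox = 0.7,
              noiseSd = 0.015)
}

# ---------------------------------------------------------------------------
# rasterization
# ---------------------------------------------------------------------------

.axis_index <- function(axis) match(axis, c("X", "Y", "Z"))

# logical mask of a primitive's solid region (voxel centers)
.prim_masks <- function(p, d) {
  X <- slice.index(array(0, d), 1L)
  Y <- slice.index(array(0, d), 2L)
  Z <- slice.index(array(0, d), 3L)
  if (p$type == "sphere") {
    m <- (X - p$center[1])^2 + (Y - p$center[2])^2 + (Z - p$center[3])^2 <=
      p$radius^2
    return(list(solid = m))
  }
  if (p$type == "ellipsoid") {
    m <- ((X - p$center[1]) / p$radii[1])^2 +
         ((Y - p$center[2]) / p$radii[2])^2 +
         ((Z - p$center[3]) / p$radii[3])^2 <= 1
    return(list(solid = m))
  }
  if (p$type == "toothShell") {
    q <- function(r) ((X - p$center[1]) / r[1])^2 +
                     ((Y - p$center[2]) / r[2])^2 +
                     ((Z - p$center[3]) / r[3])^2
    outer_m <- q(p$radii) <= 1
    rin <- pmax(p$radii - p$wallThickness, 0.5)
    inner_m <- q(rin) <= 1
    return(list(solid = outer_m, wall = outer_m & !inner_m,
                interior = inner_m))
  }
  if (p$type == "slab") {
    ax <- .axis_index(p$axis)
    A <- list(X, Y, Z)[[ax]]
    m <- abs(A - p$center[ax]) <= p$thickness / 2
    if (!is.null(p$extent)) {
      for (nm in names(p$extent)) {
        ai <- .axis_index(toupper(nm))
        B <- list(X, Y, Z)[[ai]]
        m <- m & B >= p$extent[[nm]][1] & B <= p$extent[[nm]][2]
      }
    }
    return(list(solid = m))
  }
  stop("unknown primitive type: ", p$type)
}

# closed-form surface entry for the truth record (voxel-index parameters plus
# the mm-frame equivalents)
.prim_surface <- function(p, spacing, gridShape = NULL) {
  mm <- function(v) (v - 1) * spacing          # voxel index -> mm
  s <- list(type = p$type, label = p$label)
  if (p$type %in% c("sphere", "ellipsoid", "toothShell")) {
    s$centerVox <- p$center
    s$centerMm <- mm(p$center)
    s$radiiVox <- if (p$type == "sphere") rep(p$radius, 3) else p$radii
    s$radiiMm <- s$radiiVox * spacing
  } else {
    ax <- .axis_index(p$axis)
    s$axis <- p$axis
    s$centerVox <- p$center
    s$thicknessVox <- p$thickness
    s$planesVox <- p$center[ax] + c(-1, 1) * p$thickness / 2
    s$planesMm <- (s$planesVox - 1) * spacing[ax]
    s$extent <- p$extent
    if (is.null(s$extent) && !is.null(gridShape)) {
      other <- setdiff(1:3, ax)
      s$extent <- setNames(lapply(other, function(a) c(1, gridShape[a])),
                           c("x", "y", "z")[other])
    }
    # full box bounds (voxel indices): slabs are boxes, and all six faces
    # are real surfaces
    lim <- vector("list", 3L)
    lim[[ax]] <- s$planesVox
    for (nm in names(s$extent))
      lim[[.axis_index(toupper(nm))]] <- s$extent[[nm]]
    s$boxVox <- lim
  }
  s
}

# separable gaussian blur with edge-renormalized truncated kernels
.gauss_blur3 <- function(a, sigma) {
  if (sigma <= 0) return(a)
  r <- max(1L, ceiling(3 * sigma))
  w <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  w <- w / sum(w)
  d <- dim(a)
  conv_axis <- function(a, axis) {
    d <- dim(a)
    n <- d[axis]
    K <- matrix(0, n, n)
    for (off in -r:r) {
      i <- seq_len(n)
      j <- i + off
      ok <- j >= 1 & j <= n
      K[cbind(i[ok], j[ok])] <- K[cbind(i[ok], j[ok])] + w[off + r + 1]
    }
    K <- K / rowSums(K)                       # renormalize at the edges
    perm <- c(axis, setdiff(1:3, axis))
    ap <- aperm(a, perm)
    m <- matrix(ap, nrow = n)
    m <- K %*% m
    ap <- array(m, dim = d[perm])
    aperm(ap, order(perm))
  }
  for (ax in 1:3) a <- conv_axis(a, ax)
  a
}

#' Generate a ground-truthed CT phantom
#'
#' Rasterizes the primitives at their gray levels (precedence when regions
#' overlap: tooth wall > tooth interior > bone > matrix), applies one
#' partial-volume gaussian blur pass, adds gaussian image noise, injects
#' streak artifacts, applies beam hardening, and clips to `[0, 1]`.
#' Deterministic for a fixed spec (the seed lives in the spec).
#'
#' @param spec a [PhantomSpec-class].
#' @return list with elements `volume` (a [VoxelVolume-class]) and `truth`
#'   (a [PhantomTruth-class]; its `info` records the streak mask and overlap
#'   counts).
#' @examples
#' spec <- PhantomSpec(gridShape = c(32, 32, 32), primitives = list(
#'   phantomPrimitive("sphere", "bone", gray = 0.9,
#'                    center = c(16, 16, 16), radius = 8)))
#' ph <- generatePhantom(spec)
#' ph$volume
#' @export
generatePhantom <- function(spec) {
  validObject(spec)
  d <- spec@gridShape
  if (!length(spec@primitives))
    warning("no primitives: generating a background-only volume")
  .with_seed(spec@seed, {
    vals <- array(spec@backgroundGray, d)
    labels <- array(.LBL[["background"]], d)
    surfaces <- list()
    overlaps <- 0L
    # rasterize in precedence order: matrix, then bone, then teeth
    ord <- order(match(vapply(spec@primitives, `[[`, "", "label"),
                       c("matrix", "bone", "tooth")))
    for (p in spec@primitives[ord]) {
      mk <- .prim_masks(p, d)
      if (p$label == "tooth") {
        overlaps <- overlaps + sum(labels[mk$solid] %in%
                                     .LBL[c("bone", "matrix")])
        vals[mk$interior] <- p$interiorGray
        vals[mk$wall] <- p$gray
        labels[mk$interior] <- .LBL[["tooth_interior"]]
        labels[mk$wall] <- .LBL[["tooth_wall"]]
      } else {
        lbl <- .LBL[[p$label]]
        prev <- labels[mk$solid]
        overlaps <- overlaps + sum(prev > lbl)
        keep <- prev <= lbl              # never overwrite higher precedence
        idx <- which(mk$solid)[keep]
        if (p$type == "slab" && !is.null(p$grayRamp)) {
          ax <- .axis_index(p$axis)
          A <- slice.index(vals, ax)[idx]
          lo <- p$center[ax] - p$thickness / 2
          tfrac <- .clip01((A - lo) / p$thickness)
          vals[idx] <- p$grayRamp[1] + tfrac * diff(p$grayRamp)
        } else {
          vals[idx] <- p$gray
        }
        labels[idx] <- lbl
      }
      surfaces[[length(surfaces) + 1L]] <-
        .prim_surface(p, spec@voxelSpacingMm, d)
    }
    if (overlaps > 0L)
      .log_msg("phantom: %d voxels resolved by label precedence", overlaps)
    vals <- .gauss_blur3(vals, spec@blurSigmaVox)
    if (spec@noiseSd > 0)
      vals <- vals + array(rnorm(length(vals), 0, spec@noiseSd), d)
    vals <- .clip01(vals)
    streakMask <- array(FALSE, d)
    if (isTRUE(spec@streakParams$count > 0)) {
      sr <- .inject_streaks_core(vals, spec@streakParams)
      vals <- sr$values
      streakMask <- sr$mask
      labels[streakMask & labels %in% .LBL[c("background", "matrix")]] <-
        .LBL[["streak"]]
    }
    if (spec@beamHardeningStrength > 0) {
      vals <- .beam_hardening_core(vals, spec@beamHardeningStrength,
                                   spec@voxelSpacingMm)
    }
    vol <- VoxelVolume(vals, spec@voxelSpacingMm)
    truth <- new("PhantomTruth", labelMap = labels, surfaces = surfaces,
                 streakMask = streakMask,
                 info = list(seed = spec@seed, overlapVoxels = overlaps,
                             labels = .LBL))
    list(volume = vol, truth = truth)
  })
}

# ---------------------------------------------------------------------------
# streaks
# ---------------------------------------------------------------------------

# core: operates on a raw array using the current RNG state.  Streak slice
# positions (Y) are drawn from separated slots so distinct streaks never
# merge into one surface component: real streaks are per-slice reconstruction
# events, and the ground truth needs separable components.
.inject_streaks_core <- function(vals, sp) {
  d <- dim(vals)
  mask <- array(FALSE, d)
  count <- as.integer(sp$count)
  thick <- max(1L, as.integer(sp$thickness))
  axes <- sp$axes
  clipped <- 0L
  ySep <- thick + 3L
  ySlots <- seq(2L, max(2L, d[2] - thick - 1L), by = ySep)
  if (count > length(ySlots)) {
    warning("streak count ", count, " exceeds the ", length(ySlots),
            " separable slice slots; capping")
    count <- length(ySlots)
  }
  yPos <- sample(ySlots, count)
  for (k in seq_len(count)) {
    axis <- if (length(axes) == 1L) axes else sample(axes, 1L)
    ai <- .axis_index(axis)
    len <- min(d[ai], round(runif(1, sp$lengthRange[1], sp$lengthRange[2])))
    start <- sample.int(max(1L, d[ai] - len + 1L), 1L)
    other <- setdiff(1:3, ai)
    o1 <- if (other[1] == 2L) yPos[k]
          else sample.int(max(1L, d[other[1]] - thick + 1L), 1L)
    o2 <- if (other[2] == 2L) yPos[k]
          else sample.int(max(1L, d[other[2]] - thick + 1L), 1L)
    offset <- runif(1, sp$offsetRange[1], sp$offsetRange[2])
    pol <- switch(if (is.null(sp$polarity)) "both" else sp$polarity,
                  both = sample(c(-1, 1), 1L), bright = 1, dark = -1)
    idx <- vector("list", 3L)
    idx[[ai]] <- start:(start + len - 1L)
    idx[[other[1]]] <- o1:(o1 + thick - 1L)
    idx[[other[2]]] <- o2:(o2 + thick - 1L)
    old <- vals[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
    newv <- .clip01(old + pol * offset)
    clipped <- clipped + sum(newv != old + pol * offset)
    vals[idx[[1]], idx[[2]], idx[[3]]] <- newv
    chg <- newv != old
    mask[idx[[1]], idx[[2]], idx[[3]]] <-
      mask[idx[[1]], idx[[2]], idx[[3]]] | chg
  }
  if (clipped > 0L)
    .log_msg("injectStreaks: %d voxel values clipped to [0,1]", clipped)
  list(values = vals, mask = mask)
}

#' Inject axis-aligned streak artifacts into a volume
#'
#' Streaks are additive axis-aligned line segments of random length parallel
#' to the in-slice X and Z axes (never Y), in both bright and dark polarity
#' by default; values are clipped to `[0, 1]`.
#'
#' @param volume a [VoxelVolume-class].
#' @param streakParams list with `count`, `lengthRange` (voxels),
#'   `thickness` (voxels), `offsetRange` (gray units), `axes` (subset of
#'   "X","Z"), `polarity` ("both"/"bright"/"dark").
#' @param seed integer RNG seed.
#' @return list with `volume` (modified copy) and `mask` (logical array
#'   marking exactly the modified voxels).
#' @export
injectStreaks <- function(volume, streakParams, seed = 1L) {
  stopifnot(is(volume, "VoxelVolume"))
  proto <- new("PhantomSpec")@streakParams
  proto[names(streakParams)] <- streakParams
  sp <- proto
  if (!all(sp$axes %in% c("X", "Z")))
    stop('streak axes must be a subset of c("X", "Z")')
  if (!isTRUE(sp$count > 0))
    return(list(volume = volume, mask = array(FALSE, dim(volume@values))))
  .with_seed(seed, {
    r <- .inject_streaks_core(volume@values, sp)
    list(volume = VoxelVolume(r$values, volume@spacingMm), mask = r$mask)
  })
}

# ---------------------------------------------------------------------------
# beam hardening
# ---------------------------------------------------------------------------

.beam_hardening_core <- function(vals, strength, spacing) {
  d <- dim(vals)
  x <- ((seq_len(d[1]) - (d[1] + 1) / 2)) * spacing[1]
  z <- ((seq_len(d[3]) - (d[3] + 1) / 2)) * spacing[3]
  rmax2 <- max(x^2) + max(z^2)
  # in-slice radial profile, brighter periphery
  prof <- outer(x^2, z^2, "+") / rmax2          # nx x nz, normalized r^2
  f <- 1 + strength * prof
  fArr <- aperm(array(f, c(d[1], d[3], d[2])), c(1, 3, 2))
  .clip01(vals * fArr)
}

#' Apply a radial beam-hardening gradient
#'
#' Multiplies gray values by the smooth in-slice radial profile
#' `1 + strength * (r / rmax)^2` (brighter periphery), where `r` is the
#' distance from the slice center in the X-Z plane, then clips to `[0, 1]`.
#' Strength 0 is the identity.
#'
#' @param volume a [VoxelVolume-class].
#' @param strength dimensionless amplitude, >= 0.
#' @return the modified [VoxelVolume-class].
#' @export
applyBeamHardening <- function(volume, strength) {
  stopifnot(is(volume, "VoxelVolume"), strength >= 0)
  if (strength == 0) return(volume)
  VoxelVolume(.beam_hardening_core(volume@values, strength,
                                   volume@spacingMm),
              volume@spacingMm)
}

#' Sample points on a phantom truth surface
#'
#' Quasi-uniform points on the closed-form outer surface of a primitive, for
#' distance-based recovery checks against reconstructed meshes.
#'
#' @param surface one element of the `surfaces` slot of a
#'   [PhantomTruth-class].
#' @param spacingMm voxel spacing (mm), used for slab extents.
#' @param n approximate number of points.
#' @return numeric matrix (n x 3) of points in mm.
#' @export
truthSurfacePoints <- function(surface, spacingMm, n = 2000L) {
  if (surface$type %in% c("sphere", "ellipsoid", "toothShell")) {
    dirs <- .fibonacci_sphere(n, rotate = FALSE)
    ctr <- surface$centerMm
    return(sweep(dirs %*% diag(surface$radiiMm), 2, ctr, "+"))
  }
  # slab: sample all six box faces, proportionally to their areas
  lim <- surface$boxVox
  ext <- vapply(lim, diff, numeric(1))
  faceArea <- c(ext[2] * ext[3], ext[1] * ext[3], ext[1] * ext[2])
  totalArea <- 2 * sum(faceArea)
  pts <- NULL
  for (ax in 1:3) {
    other <- setdiff(1:3, ax)
    nf <- max(4L, round(n * faceArea[ax] / totalArea))
    m <- ceiling(sqrt(nf))
    g1 <- seq(lim[[other[1]]][1], lim[[other[1]]][2], length.out = m)
    g2 <- seq(lim[[other[2]]][1], lim[[other[2]]][2], length.out = m)
    gg <- expand.grid(a = g1, b = g2)
    for (pl in lim[[ax]]) {
      p <- matrix(0, nrow(gg), 3)
      p[, ax] <- pl
      p[, other[1]] <- gg$a
      p[, other[2]] <- gg$b
      pts <- rbind(pts, p)
    }
  }
  sweep(pts - 1, 2, spacingMm, "*")
}
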