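# Central S4 classes.  Axis convention used throughout: array dimension 1 is
# the in-slice X axis, dimension 2 is the slice index (scanner Y), dimension 3
# is the in-slice Z axis.  Streak artifacts run parallel to X or Z.

#' VoxelVolume: a 3D scalar CT volume with physical spacing
#'
#' Gray values are normalized to `[0, 1]`.  Dimension 1 is the in-slice X
#' axis, dimension 2 the slice index (Y), dimension 3 the in-slice Z axis,
#' so CT streak artifacts run along array dimensions 1 and 3.
#'
#' @slot values 3D numeric array, values in `[0, 1]`.
#' @slot spacingMm numeric(3), physical voxel pitch per axis in mm.
#' @slot axes character(3), fixed axis labels `c("X","Y","Z")` recorded so the
#'   convention round-trips through file I/O.
#' @exportClass VoxelVolume
setClass("VoxelVolume",
  representation(values = "array", spacingMm = "numeric", axes = "character"),
  prototype(spacingMm = rep(0.038, 3), axes = c("X", "Y", "Z"))
)

setValidity("VoxelVolume", function(object) {
  msg <- character()
  if (length(dim(object@values)) != 3L)
    msg <- c(msg, "values must be a 3D array")
  rng <- suppressWarnings(range(object@values, finite = TRUE))
  if (length(object@values) && (rng[1] < -1e-9 || rng[2] > 1 + 1e-9))
    msg <- c(msg, "values must lie in [0, 1]")
  if (length(object@spacingMm) != 3L || any(!is.finite(object@spacingMm)) ||
      any(object@spacingMm <= 0))
    msg <- c(msg, "spacingMm must be 3 strictly positive numbers")
  if (!identical(object@axes, c("X", "Y", "Z")))
    msg <- c(msg, 'axes must be c("X","Y","Z")')
  if (length(msg)) msg else TRUE
})

#' PhantomSpec: parameters of a synthetic CT phantom
#'
#' Describes a ground-truthed phantom emulating a compacted fossil scan:
#' thin bone plates, thin-walled tooth shells with darker interiors, dense
#' concretion matrix, axis-aligned streak noise, beam hardening, and additive
#' gaussian image noise.
#'
#' @slot gridShape integer(3), voxel counts (X, Y slices, Z).
#' @slot voxelSpacingMm numeric(3), voxel pitch (default 0.038 mm).
#' @slot seed integer RNG seed.
#' @slot backgroundGray numeric in `[0,1]`.
#' @slot primitives list of primitive descriptions (see [phantomPrimitive()]).
#' @slot streakParams list: `count`, `lengthRange` (voxels), `thickness`
#'   (voxels), `offsetRange` (gray units), `axes` (subset of "X","Z"),
#'   `polarity` ("both", "bright" or "dark").
#' @slot beamHardeningStrength numeric >= 0, amplitude of the radial profile.
#' @slot blurSigmaVox numeric, partial-volume gaussian sigma in voxels.
#' @slot noiseSd numeric, additive gaussian noise standard deviation.
#' @exportClass PhantomSpec
setClass("PhantomSpec",
  representation(gridShape = "integer", voxelSpacingMm = "numeric",
                 seed = "integer", backgroundGray = "numeric",
                 primitives = "list", streakParams = "list",
                 beamHardeningStrength = "numeric", blurSigmaVox = "numeric",
                 noiseSd = "numeric"),
  prototype(gridShape = c(160L, 120L, 160L),
            voxelSpacingMm = rep(0.038, 3), seed = 1L,
            backgroundGray = 0.1, primitives = list(),
            streakParams = list(count = 0L, lengthRange = c(60, 140),
                                thickness = 1L, offsetRange = c(0.2, 0.45),
                                axes = c("X", "Z"), polarity = "both"),
            beamHardeningStrength = 0, blurSigmaVox = 0.7, noiseSd = 0.02)
)

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (length(object@gridShape) != 3L || any(object@gridShape < 2L))
    msg <- c(msg, "gridShape must be 3 positive voxel counts")
  if (any(object@voxelSpacingMm <= 0)) msg <- c(msg, "spacing must be positive")
  if (object@backgroundGray < 0 || object@backgroundGray > 1)
    msg <- c(msg, "backgroundGray must be in [0,1]")
  for (p in object@primitives) {
    if (!is.null(p$gray) && (p$gray < 0 || p$gray > 1))
      msg <- c(msg, "primitive gray levels must be in [0,1]")
    if (!is.null(p$interiorGray) && (p$interiorGray < 0 || p$interiorGray > 1))
      msg <- c(msg, "interior gray levels must be in [0,1]")
    if (!is.null(p$wallThickness) && p$wallThickness < 1)
      msg <- c(msg, "wall thickness must be >= 1 voxel")
  }
  sp <- object@streakParams
  if (!is.null(sp$axes) && !all(sp$axes %in% c("X", "Z")))
    msg <- c(msg, 'streak axes must be a subset of c("X","Z")')
  if (object@beamHardeningStrength < 0)
    msg <- c(msg, "beamHardeningStrength must be >= 0")
  if (length(msg)) msg else TRUE
})

#' PhantomTruth: ground truth accompanying a generated phantom
#'
#' @slot labelMap integer array, same shape as the volume; labels:
#'   0 background, 1 matrix, 2 bone, 3 tooth wall, 4 tooth interior, 5 streak.
#' @slot surfaces list of closed-form outer-surface descriptions per primitive
#'   (type, center/plane parameters, radii, label).
#' @slot streakMask logical array marking injected streak voxels.
#' @slot info list of bookkeeping (overlap counts, seed).
#' @exportClass PhantomTruth
setClass("PhantomTruth",
  representation(labelMap = "array", surfaces = "list",
                 streakMask = "array", info = "list"),
  prototype(info = list())
)

setValidity("PhantomTruth", function(object) {
  msg <- character()
  if (length(dim(object@labelMap)) != 3L)
    msg <- c(msg, "labelMap must be a 3D array")
  if (length(object@streakMask) &&
      !identical(dim(object@streakMask), dim(object@labelMap)))
    msg <- c(msg, "streakMask must match labelMap shape")
  if (length(msg)) msg else TRUE
})

#' IsoSurfaceMesh: a triangle mesh tagged with its extraction isovalue
#'
#' @slot vertices numeric matrix (n x 3), coordinates in mm.
#' @slot faces integer matrix (m x 3), 1-based vertex indices.
#' @slot isovalue numeric(1), gray level of extraction in `[0,1]`
#'   (`NA` for merged meshes).
#' @slot componentIds integer per-face connected-component label (length 0
#'   when not yet computed).
#' @slot provenance list: source volume id, pipeline stage, per-face source
#'   isovalues after merging.
#' @exportClass IsoSurfaceMesh
setClass("IsoSurfaceMesh",
  representation(vertices = "matrix", faces = "matrix", isovalue = "numeric",
                 componentIds = "integer", provenance = "list"),
  prototype(vertices = matrix(numeric(), 0, 3),
            faces = matrix(integer(), 0, 3), isovalue = NA_real_,
            componentIds = integer(), provenance = list())
)

setValidity("IsoSurfaceMesh", function(object) {
  msg <- character()
  if (ncol(object@vertices) != 3L) msg <- c(msg, "vertices must be n x 3")
  if (ncol(object@faces) != 3L) msg <- c(msg, "faces must be m x 3")
  if (nrow(object@faces) &&
      (min(object@faces) < 1L || max(object@faces) > nrow(object@vertices)))
    msg <- c(msg, "face indices out of vertex range")
  if (!is.na(object@isovalue) &&
      (object@isovalue < 0 || object@isovalue > 1))
    msg <- c(msg, "isovalue must be in [0,1]")
  if (length(object@componentIds) &&
      length(object@componentIds) != nrow(object@faces))
    msg <- c(msg, "componentIds must have one entry per face")
  if (length(msg)) msg else TRUE
})

#' SITConfig: configuration of the Sequential Isosurface Trimming pipeline
#'
#' Defaults follow the published workflow where stated (20 isosurfaces) and
#' declared choices elsewhere: isovalues evenly spaced between the 60th and
#' 99.5th gray percentiles of the denoised volume; a weak 3 x 3 per-slice box
#' kernel; a streak classifier requiring axis-aligned elongation >= 10 with
#' off-axis extent <= 5 voxel spacings; redundancy at mean symmetric
#' nearest-vertex distance <= 1 voxel spacing with mutual coverage >= 0.9;
#' ambient-occlusion culling below accessibility 0.05 using 64 directions.
#'
#' @slot nLevels integer, number of isovalues (default 20).
#' @slot levelRange numeric(2), low/high percentiles of the gray histogram.
#' @slot kernel numeric matrix (2D, applied per slice) or 3D array; weights
#'   must sum to 1.
#' @slot streakElongationMin numeric, min (extent along X or Z) / (max other
#'   extent) ratio for a streak.
#' @slot streakThicknessMaxMm numeric, max off-axis extent; `NA` = 5 voxel
#'   spacings, resolved against the volume.
#' @slot redundancyDistanceMm numeric, mean symmetric nearest-vertex distance
#'   below which surfaces are redundant; `NA` = 1 voxel spacing.
#' @slot redundancyCoverageMin numeric, fraction of vertices that must be
#'   mutually matched.
#' @slot minComponentDiagMm numeric, components whose bounding-box diagonal
#'   is below this are removed as noise specks during trimming (`NA` = 8
#'   voxel spacings; 0 disables).  Scattered sub-structure-scale surface
#'   crumbs are the mesh-space face of image noise.
#' @slot aoNDirs integer, ray directions per face.
#' @slot aoAccessibilityMin numeric in `[0,1]`, cull faces below this.
#' @slot aoEpsMm numeric, ray-origin offset along the face normal; `NA` = 1e-4
#'   of the mesh bounding-box diagonal (ray-cast method only).
#' @slot aoMethod "depthmap" (default: multi-directional depth-map
#'   visibility, linear in faces) or "raycast" (exact per-ray intersection
#'   tests; accurate but far slower on large meshes).
#' @slot seed integer, seed for ambient-occlusion direction sampling.
#' @exportClass SITConfig
setClass("SITConfig",
  representation(nLevels = "integer", levelRange = "numeric", kernel = "ANY",
                 streakElongationMin = "numeric",
                 streakThicknessMaxMm = "numeric",
                 redundancyDistanceMm = "numeric",
                 redundancyCoverageMin = "numeric",
                 minComponentDiagMm = "numeric",
                 aoNDirs = "integer", aoAccessibilityMin = "numeric",
                 aoEpsMm = "numeric", aoMethod = "character",
                 seed = "integer"),
  prototype(nLevels = 20L, levelRange = c(60, 99.5),
            kernel = matrix(1 / 9, 3, 3), streakElongationMin = 10,
            streakThicknessMaxMm = NA_real_, redundancyDistanceMm = NA_real_,
            redundancyCoverageMin = 0.9, minComponentDiagMm = NA_real_,
            aoNDirs = 64L,
            aoAccessibilityMin = 0.05, aoEpsMm = NA_real_,
            aoMethod = "depthmap", seed = 1L)
)

setValidity("SITConfig", function(object) {
  msg <- character()
  lr <- object@levelRange
  if (length(lr) != 2 || !(lr[1] > 0 && lr[1] < lr[2] && lr[2] <= 100))
    msg <- c(msg, "levelRange must satisfy 0 < low < high <= 100")
  if (object@nLevels < 1L) msg <- c(msg, "nLevels must be >= 1")
  for (s in c("streakElongationMin", "streakThicknessMaxMm",
              "redundancyDistanceMm")) {
    v <- slot(object, s)
    if (!is.na(v) && v <= 0) msg <- c(msg, paste(s, "must be positive"))
  }
  if (object@redundancyCoverageMin < 0 || object@redundancyCoverageMin > 1)
    msg <- c(msg, "redundancyCoverageMin must be in [0,1]")
  if (object@aoNDirs < 4L) msg <- c(msg, "aoNDirs must be >= 4")
  if (object@aoAccessibilityMin < 0 || object@aoAccessibilityMin > 1)
    msg <- c(msg, "aoAccessibilityMin must be in [0,1]")
  if (!object@aoMethod %in% c("depthmap", "raycast"))
    msg <- c(msg, 'aoMethod must be "depthmap" or "raycast"')
  if (length(msg)) msg else TRUE
})

#' TrimReport: per-stage accounting of the SIT pipeline
#'
#' Each stage entry records faces in, faces kept, faces removed (kept +
#' removed = in, assertable), the thresholds used, and stage-specific detail
#' (streak component ids, pruned isovalues, accessibility summaries).
#'
#' @slot stages list of per-stage records.
#' @exportClass TrimReport
setClass("TrimReport", representation(stages = "list"),
         prototype(stages = list()))

setValidity("TrimReport", function(object) {
  for (st in object@stages) {
    if (!is.null(st$facesIn)) {
      if (st$facesKept < 0 || st$facesRemoved < 0)
        return("face counts must be non-negative")
      if (st$facesKept + st$facesRemoved != st$facesIn)
        return("facesKept + facesRemoved must equal facesIn")
    }
  }
  TRUE
})

#' RamusLandmarks: anatomical landmarks on a mandibular ramus mesh
#'
#' @slot jointPoint numeric(3), mm, jaw-joint contact point.
#' @slot anteriorTip numeric(3), mm, rostral tip.
#' @slot longAxis numeric(3), unit direction from tip to joint.
#' @exportClass RamusLandmarks
setClass("RamusLandmarks",
  representation(jointPoint = "numeric", anteriorTip = "numeric",
                 longAxis = "numeric"))

setValidity("RamusLandmarks", function(object) {
  msg <- character()
  if (any(!is.finite(c(object@jointPoint, object@anteriorTip))))
    msg <- c(msg, "landmark points must be finite")
  if (sqrt(sum((object@jointPoint - object@anteriorTip)^2)) < 1e-12)
    msg <- c(msg, "joint and tip must be distinct")
  if (abs(sqrt(sum(object@longAxis^2)) - 1) > 1e-6)
    msg <- c(msg, "longAxis must have unit norm")
  if (length(msg)) msg else TRUE
})

#' PoseConfig: constraints and search settings for the bilateral jaw pose
#'
#' The solver pins the jaw-joint points at plus/minus half the skull width
#' from the sagittal plane (x = 0), searches inclination about the ramus long
#' axis and yaw, and minimizes the anterior-tip distance to the sagittal
#' plane subject to no mirror overlap and no lateral tip divergence.
#'
#' @slot skullWidthMm numeric, target joint-to-joint separation (default
#'   30.2 mm, the bilateral skull-width estimate).
#' @slot angleGridDeg numeric, angular grid resolution (default 1 degree).
#' @slot overlapToleranceMm numeric, minimum allowed clearance between the
#'   two rami (default 0: touching allowed, interpenetration not).
#' @slot inclinationRangeDeg numeric(2), search range for inclination.
#' @slot yawRangeDeg numeric(2), search range for yaw.
#' @slot refine logical, run local refinement after the grid search.
#' @exportClass PoseConfig
setClass("PoseConfig",
  representation(skullWidthMm = "numeric", angleGridDeg = "numeric",
                 overlapToleranceMm = "numeric",
                 inclinationRangeDeg = "numeric", yawRangeDeg = "numeric",
                 refine = "logical"),
  prototype(skullWidthMm = 30.2, angleGridDeg = 1, overlapToleranceMm = 0,
            inclinationRangeDeg = c(-90, 90), yawRangeDeg = c(-60, 60),
            refine = TRUE)
)

setValidity("PoseConfig", function(object) {
  msg <- character()
  if (object@skullWidthMm <= 0) msg <- c(msg, "skullWidthMm must be > 0")
  if (object@angleGridDeg <= 0) msg <- c(msg, "angleGridDeg must be > 0")
  if (length(msg)) msg else TRUE
})

#' PoseSolution: mirrored rigid placements of the two mandibular rami
#'
#' @slot rightTransform 4x4 rigid transform applied to the right ramus mesh.
#' @slot leftTransform 4x4 transform of the left ramus (sagittal mirror of
#'   the right's pose; determinant -1 because it includes the reflection).
#' @slot tipGapMm numeric, distance between the two anterior tips.
#' @slot objectiveValue numeric, anterior-tip distance to the sagittal plane.
#' @slot constraintsSatisfied named logical: `width`, `noOverlap`,
#'   `noDivergence`.
#' @slot feasible logical(1), all constraints satisfied.
#' @slot anglesDeg numeric(2), (inclination, yaw) at the solution.
#' @exportClass PoseSolution
setClass("PoseSolution",
  representation(rightTransform = "matrix", leftTransform = "matrix",
                 tipGapMm = "numeric", objectiveValue = "numeric",
                 constraintsSatisfied = "logical", feasible = "logical",
                 anglesDeg = "numeric"))

setValidity("PoseSolution", function(object) {
  msg <- character()
  R <- object@rightTransform[1:3, 1:3]
  if (max(abs(crossprod(R) - diag(3))) > 1e-6 || det(R) < 0)
    msg <- c(msg, "rightTransform must be proper rigid")
  if (object@tipGapMm < -1e-9) msg <- c(msg, "tipGapMm must be >= 0")
  if (isTRUE(object@feasible) && !all(object@constraintsSatisfied))
    msg <- c(msg, "a feasible solution must satisfy all constraints")
  if (length(msg)) msg else TRUE
})

#' GuildAssessment: Massare feeding-guild metrics and classification
#'
#' @slot crownShapeIndex numeric, max crown diameter / crown height
#'   (3 significant figures).
#' @slot relativeToothSize numeric, max crown dimension / skull width
#'   (3 significant figures).
#' @slot skullWidthMm numeric.
#' @slot guildLabel character, "crushing" or "not_crushing".
#' @slot criteriaTrace list: raw full-precision values and which thresholds
#'   fired (crown shape index strictly above 1.0; relative tooth size at or
#'   above 0.1).
#' @exportClass GuildAssessment
setClass("GuildAssessment",
  representation(crownShapeIndex = "numeric", relativeToothSize = "numeric",
                 skullWidthMm = "numeric", guildLabel = "character",
                 criteriaTrace = "list"))

setValidity("GuildAssessment", function(object) {
  msg <- character()
  if (object@crownShapeIndex <= 0 || object@relativeToothSize <= 0)
    msg <- c(msg, "indices must be positive")
  if (!object@guildLabel %in% c("crushing", "not_crushing"))
    msg <- c(msg, "guildLabel must be crushing or not_crushing")
  tr <- object@criteriaTrace
  if (!is.null(tr$csiAbove) && !is.null(tr$rtsAtOrAbove)) {
    expected <- if (tr$csiAbove && tr$rtsAtOrAbove) "crushing" else "not_crushing"
    if (!identical(object@guildLabel, expected))
      msg <- c(msg, "guildLabel inconsistent with criteriaTrace")
  }
  if (length(msg)) msg else TRUE
})

#' ParsimonyResult: ordered-character Sankoff reconstruction summary
#'
#' @slot minCost numeric, minimum total step cost.
#' @slot mprSets list, per node (ape numbering), the set of states occurring
#'   in at least one minimum-cost reconstruction.
#' @slot originRange integer(2), min and max count, over all minimum-cost
#'   reconstructions, of edges whose parent state is 0 and child state is
#'   1 or 2 (independent origins of the molariform condition).
#' @slot costVectors numeric matrix (states x nodes) of subtree costs.
#' @slot states integer vector of the state alphabet.
#' @exportClass ParsimonyResult
setClass("ParsimonyResult",
  representation(minCost = "numeric", mprSets = "list",
                 originRange = "integer", costVectors = "matrix",
                 states = "integer"))

setValidity("ParsimonyResult", function(object) {
  msg <- character()
  if (object@minCost < 0) msg <- c(msg, "minCost must be >= 0")
  if (any(lengths(object@mprSets) == 0))
    msg <- c(msg, "every MPR set must be non-empty")
  if (length(object@originRange) != 2L ||
      object@originRange[1] > object@originRange[2])
    msg <- c(msg, "originRange must be [min, max] with min <= max")
  if (length(msg)) msg else TRUE
})

#' MkResult: equal-rates Mk likelihood reconstruction summary
#'
#' @slot rateHat numeric, ML substitution rate (per unit branch length).
#' @slot logLik numeric, log-likelihood at `rateHat`.
#' @slot marginals numeric matrix (nodes x states) of marginal posterior
#'   state probabilities; rows sum to 1.
#' @slot mlOriginRange integer(2), origins counted on argmax states; ties
#'   broaden the range.
#' @slot identifiable logical, FALSE when the data carry no signal about the
#'   rate (all tips identical) and `rateHat` sits at the lower bound.
#' @slot states integer state alphabet.
#' @exportClass MkResult
setClass("MkResult",
  representation(rateHat = "numeric", logLik = "numeric",
                 marginals = "matrix", mlOriginRange = "integer",
                 identifiable = "logical", states = "integer"))

setValidity("MkResult", function(object) {
  msg <- character()
  if (object@rateHat <= 0) msg <- c(msg, "rateHat must be > 0")
  if (!is.finite(object@logLik)) msg <- c(msg, "logLik must be finite")
  if (nrow(object@marginals) &&
      max(abs(rowSums(object@marginals) - 1)) > 1e-9)
    msg <- c(msg, "marginal rows must sum to 1 (tolerance 1e-9)")
  if (length(msg)) msg else TRUE
})
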