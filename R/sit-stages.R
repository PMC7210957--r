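# Trimming stages of the SIT pipeline: streak-component classification and
# removal, redundancy pruning across gray levels, merging, and
# ambient-occlusion culling.  Every stage reports faces in / kept / removed
# with kept + removed = in.

.stage_record <- function(stage, facesIn, facesKept, details = list()) {
  c(list(stage = stage, facesIn = as.integer(facesIn),
         facesKept = as.integer(facesKept),
         facesRemoved = as.integer(facesIn - facesKept)), details)
}

#' Combine trim reports
#'
#' @param ... [TrimReport-class] objects.
#' @return a single [TrimReport-class] chaining all stages.
#' @export
combineReports <- function(...) {
  new("TrimReport", stages = do.call(c, lapply(list(...), trimStages)))
}

# resolve NA thresholds against the volume spacing (5 / 1 / 8 voxels)
.resolve_config <- function(config, spacingMm) {
  if (is.na(config@streakThicknessMaxMm))
    config@streakThicknessMaxMm <- 5 * max(spacingMm)
  if (is.na(config@redundancyDistanceMm))
    config@redundancyDistanceMm <- 1 * max(spacingMm)
  if (is.na(config@minComponentDiagMm))
    config@minComponentDiagMm <- 8 * max(spacingMm)
  config
}

# ---------------------------------------------------------------------------
# streaks
# ---------------------------------------------------------------------------

# per-component bounding-box extents (components x 3), NULL if no components;
# vectorized via per-face extrema + tapply so large meshes stay cheap
.component_extents <- function(mesh) {
  if (!length(mesh@componentIds)) mesh <- meshComponents(mesh)
  ids <- mesh@componentIds
  if (!length(ids)) return(NULL)
  comp <- sort(unique(ids))
  idsF <- factor(ids, levels = comp)
  ext <- matrix(0, length(comp), 3)
  rownames(ext) <- comp
  for (ax in 1:3) {
    co <- mesh@vertices[, ax]
    faceCo <- matrix(co[mesh@faces], ncol = 3)
    fmin <- pmin(faceCo[, 1], faceCo[, 2], faceCo[, 3])
    fmax <- pmax(faceCo[, 1], faceCo[, 2], faceCo[, 3])
    ext[, ax] <- as.numeric(tapply(fmax, idsF, max) -
                            tapply(fmin, idsF, min))
  }
  ext
}

#' Classify mesh components as streak artifacts
#'
#' A component is a streak iff its axis-aligned bounding box is strongly
#' elongated along the in-slice X or Z axis: (extent along X or Z) / (max
#' extent along the other two axes) >= `streakElongationMin`, with both
#' off-axis extents <= `streakThicknessMaxMm`.  Smooth bone surfaces are wide
#' in at least two axes and never meet the rule at defaults.
#'
#' @param mesh an [IsoSurfaceMesh-class] (components computed if absent).
#' @param config a [SITConfig-class]; `streakThicknessMaxMm` must be resolved
#'   (pass `spacingMm` if it is `NA`).
#' @param spacingMm voxel spacing used to resolve an `NA` thickness cap.
#' @return list with integer vectors `streak` and `kept` (component ids);
#'   the partition is exhaustive and disjoint.
#' @export
classifyStreakComponents <- function(mesh, config = SITConfig(),
                                     spacingMm = NULL) {
  if (is.na(config@streakThicknessMaxMm)) {
    if (is.null(spacingMm))
      stop("streakThicknessMaxMm is NA: supply spacingMm to resolve it")
    config <- .resolve_config(config, spacingMm)
  }
  if (!length(mesh@componentIds)) mesh <- meshComponents(mesh)
  ext <- .component_extents(mesh)
  if (is.null(ext))
    return(list(streak = integer(), kept = integer()))
  comp <- as.integer(rownames(ext))
  # floor the off-axis extent at one voxel so degenerate (flat or line-like)
  # micro-components do not register as infinitely elongated
  eps <- config@streakThicknessMaxMm / 5
  isStreak <- logical(length(comp))
  for (axis in c(1L, 3L)) {               # X and Z
    other <- setdiff(1:3, axis)
    elong <- ext[, axis] / pmax(ext[, other[1]], ext[, other[2]], eps)
    thin <- ext[, other[1]] <= config@streakThicknessMaxMm &
            ext[, other[2]] <= config@streakThicknessMaxMm
    isStreak <- isStreak | (elong >= config@streakElongationMin & thin)
  }
  list(streak = comp[isStreak], kept = comp[!isStreak])
}

#' Remove streak-classified components and noise specks from a mesh
#'
#' Removes the faces of streak-classified components together with noise
#' specks: components whose bounding-box diagonal falls below
#' `minComponentDiagMm` (default 8 voxel spacings, smaller than any real
#' structure at scan resolution).  The speck filter is the deterministic
#' face of the manual "remove noisy areas" editing step; scattered
#' sub-structure crumbs arise from image noise and from partially visible
#' artifacts.
#'
#' @inheritParams classifyStreakComponents
#' @param stage stage label recorded in the report.
#' @return list with `mesh` (vertex array compacted) and `report` (a
#'   [TrimReport-class] recording streak and speck components separately).
#' @export
trimStreaks <- function(mesh, config = SITConfig(), spacingMm = NULL,
                        stage = "trim_streaks") {
  if (!is.null(spacingMm)) config <- .resolve_config(config, spacingMm)
  if (is.na(config@streakThicknessMaxMm))
    stop("streakThicknessMaxMm is NA: supply spacingMm to resolve it")
  if (is.na(config@minComponentDiagMm))
    config@minComponentDiagMm <- 0      # speck filter off without a spacing
  if (!length(mesh@componentIds)) mesh <- meshComponents(mesh)
  cls <- classifyStreakComponents(mesh, config)
  ext <- .component_extents(mesh)
  specks <- integer()
  if (!is.null(ext) && config@minComponentDiagMm > 0) {
    diag_ <- sqrt(rowSums(ext^2))
    specks <- setdiff(as.integer(rownames(ext)[diag_ <
                                                 config@minComponentDiagMm]),
                      cls$streak)
  }
  nIn <- nrow(mesh@faces)
  drop_ <- c(cls$streak, specks)
  keep <- !(mesh@componentIds %in% drop_)
  out <- mesh
  out@faces <- mesh@faces[keep, , drop = FALSE]
  out@componentIds <- mesh@componentIds[keep]
  if (!is.null(out@provenance$faceIsovalue))
    out@provenance$faceIsovalue <- out@provenance$faceIsovalue[keep]
  out <- .compact_mesh(out)
  out@provenance$stage <- stage
  rep_ <- new("TrimReport", stages = list(.stage_record(
    stage, nIn, sum(keep),
    list(streakComponents = cls$streak,
         speckComponents = specks,
         isovalue = mesh@isovalue,
         thresholds = list(elongationMin = config@streakElongationMin,
                           thicknessMaxMm = config@streakThicknessMaxMm,
                           minComponentDiagMm = config@minComponentDiagMm)))))
  list(mesh = out, report = rep_)
}

# ---------------------------------------------------------------------------
# redundancy pruning
# ---------------------------------------------------------------------------

# deterministic stride subsample of vertex rows
.subsample_rows <- function(V, m) {
  n <- nrow(V)
  if (n <= m) return(V)
  V[unique(round(seq(1, n, length.out = m))), , drop = FALSE]
}

#' Prune redundant isosurfaces, keeping the lowest gray level
#'
#' Two surfaces are redundant when their mean symmetric nearest-vertex
#' distance is at most `redundancyDistanceMm` and, in both directions, at
#' least `redundancyCoverageMin` of vertices find a match within that
#' distance.  Redundancy groups are built by single linkage over redundant
#' pairs; from each group exactly the member with the lowest isovalue
#' survives.  Empty meshes are dropped (reported).
#'
#' @param meshes list of [IsoSurfaceMesh-class] in a shared coordinate frame.
#' @param config a [SITConfig-class].
#' @param spacingMm spacing to resolve an `NA` redundancy distance.
#' @param maxVerts per-mesh vertex subsample cap for the distance statistics
#'   (deterministic stride; distances are between welded vertices, so a few
#'   thousand suffice).
#' @return list with `meshes` (survivors, increasing isovalue) and `report`.
#' @export
pruneRedundant <- function(meshes, config = SITConfig(), spacingMm = NULL,
                           maxVerts = 4000L) {
  if (is.na(config@redundancyDistanceMm)) {
    if (is.null(spacingMm))
      stop("redundancyDistanceMm is NA: supply spacingMm to resolve it")
    config <- .resolve_config(config, spacingMm)
  }
  if (!length(meshes))
    return(list(meshes = list(),
                report = new("TrimReport", stages = list(
                  list(stage = "prune_redundant", note = "empty input")))))
  nonEmpty <- vapply(meshes, function(m) nrow(m@vertices) > 0, logical(1))
  dropped <- which(!nonEmpty)
  ms <- meshes[nonEmpty]
  n <- length(ms)
  if (n == 0L)
    return(list(meshes = list(),
                report = new("TrimReport", stages = list(
                  list(stage = "prune_redundant",
                       note = "all meshes empty")))))
  dmax <- config@redundancyDistanceMm
  cmin <- config@redundancyCoverageMin
  sub <- lapply(ms, function(m) .subsample_rows(m@vertices, maxVerts))
  parent <- seq_len(n)
  find <- function(a) {
    while (parent[a] != a) { parent[a] <<- parent[parent[a]]; a <- parent[a] }
    a
  }
  pairStats <- list()
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    # cheap bbox gate first
    bi <- .mesh_bbox(sub[[i]]); bj <- .mesh_bbox(sub[[j]])
    if (any(bi[1, ] > bj[2, ] + dmax) || any(bj[1, ] > bi[2, ] + dmax))
      next
    dij <- .nn_dist(sub[[i]], sub[[j]])
    dji <- .nn_dist(sub[[j]], sub[[i]])
    meanSym <- mean(c(dij, dji))
    cov_ <- min(mean(dij <= dmax), mean(dji <= dmax))
    if (meanSym <= dmax && cov_ >= cmin) {
      ra <- find(i); rb <- find(j)
      if (ra != rb) parent[rb] <- ra
      pairStats[[length(pairStats) + 1L]] <-
        list(pair = c(i, j), meanSymmetricMm = meanSym, coverage = cov_)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  isoVals <- vapply(ms, function(m) m@isovalue, numeric(1))
  survivors <- logical(n)
  for (g in unique(roots)) {
    member <- which(roots == g)
    survivors[member[which.min(isoVals[member])]] <- TRUE
  }
  kept <- ms[survivors]
  ord <- order(vapply(kept, function(m) m@isovalue, numeric(1)))
  kept <- kept[ord]
  facesIn <- sum(vapply(ms, function(m) nrow(m@faces), integer(1)))
  facesKept <- sum(vapply(kept, function(m) nrow(m@faces), integer(1)))
  rep_ <- new("TrimReport", stages = list(.stage_record(
    "prune_redundant", facesIn, facesKept,
    list(surfacesIn = n, surfacesKept = length(kept),
         prunedIsovalues = sort(isoVals[!survivors]),
         keptIsovalues = sort(isoVals[survivors]),
         emptyDropped = length(dropped),
         thresholds = list(distanceMm = dmax, coverageMin = cmin)))))
  list(meshes = kept, report = rep_)
}

# ---------------------------------------------------------------------------
# merge
# ---------------------------------------------------------------------------

#' Merge meshes by concatenation
#'
#' Vertices and faces are concatenated with index re-offset; no remeshing and
#' no vertex welding, so the total face count equals the sum of the inputs
#' and per-source provenance (face-wise isovalues) is preserved.
#'
#' @param meshes list of [IsoSurfaceMesh-class] in a shared frame.
#' @return a single [IsoSurfaceMesh-class] (`isovalue` is `NA` when sources
#'   differ; per-face source isovalues live in
#'   `provenance$faceIsovalue`).
#' @export
mergeMeshes <- function(meshes) {
  meshes <- Filter(function(m) is(m, "IsoSurfaceMesh"), meshes)
  if (!length(meshes))
    return(IsoSurfaceMesh(matrix(numeric(), 0, 3), matrix(integer(), 0, 3),
                          provenance = list(stage = "merge")))
  V <- do.call(rbind, lapply(meshes, function(m) m@vertices))
  off <- cumsum(c(0L, vapply(meshes, nVertices, integer(1))))
  F <- do.call(rbind, lapply(seq_along(meshes), function(i)
    meshes[[i]]@faces + off[i]))
  if (is.null(F)) F <- matrix(integer(), 0, 3)
  isoPerFace <- unlist(lapply(meshes, function(m)
    rep(m@isovalue, nrow(m@faces))))
  isos <- unique(vapply(meshes, function(m) m@isovalue, numeric(1)))
  m <- IsoSurfaceMesh(V, F,
                      isovalue = if (length(isos) == 1L) isos else NA_real_,
                      provenance = list(stage = "merge",
                                        faceIsovalue = isoPerFace,
                                        sourceIsovalues = isos))
  meshComponents(m)
}

# ---------------------------------------------------------------------------
# ambient-occlusion culling
# ---------------------------------------------------------------------------

#' Per-face ambient-occlusion accessibility
#'
#' Accessibility of a face is the fraction of quasi-uniform sphere directions
#' from which the face is not concealed by the rest of the mesh;
#' 1 = fully exposed, 0 = fully concealed.  Direction sampling is seeded and
#' reproducible.  Two backends implement the occlusion test: `"depthmap"`
#' (default) rasterizes face centroids into a per-direction depth buffer and
#' marks a face visible when its depth is within one pixel of the nearest
#' depth in its screen cell — linear in the face count and the standard
#' accelerated formulation; `"raycast"` shoots one ray per direction from
#' the face centroid (offset `aoEpsMm` along the normal) and tests exact
#' triangle intersections — slower, used as the reference on small meshes.
#' Both are monotone under added occluders.
#'
#' @param mesh a non-empty [IsoSurfaceMesh-class].
#' @param config a [SITConfig-class] (`aoNDirs`, `aoMethod`, `aoEpsMm`,
#'   `seed`).
#' @return numeric vector of per-face accessibility in `[0, 1]`.
#' @export
faceAccessibility <- function(mesh, config = SITConfig()) {
  if (!nrow(mesh@faces)) stop("mesh is empty")
  if (config@aoNDirs < 4L) stop("aoNDirs must be >= 4")
  dirs <- .with_seed(config@seed, .fibonacci_sphere(config@aoNDirs))
  if (config@aoMethod == "raycast") {
    eps <- config@aoEpsMm
    if (is.na(eps)) {
      bb <- .mesh_bbox(mesh@vertices)
      eps <- 1e-4 * sqrt(sum((bb[2, ] - bb[1, ])^2))
    }
    .ao_accessibility(mesh@vertices, mesh@faces, dirs, eps)
  } else {
    pixel <- 2 * sqrt(mean(.face_areas(mesh)))
    .ao_depthmap(mesh@vertices, mesh@faces, dirs, pixel, pixel)
  }
}

#' Cull faces that are largely concealed from outside
#'
#' Faces with accessibility below `aoAccessibilityMin` are removed (the
#' published workflow's removal of low-ambient-occlusion faces).
#'
#' @inheritParams faceAccessibility
#' @return list with `mesh` and `report`; the report records the
#'   accessibility summary.
#' @export
cullOccluded <- function(mesh, config = SITConfig()) {
  acc <- faceAccessibility(mesh, config)
  keep <- acc >= config@aoAccessibilityMin
  nIn <- nrow(mesh@faces)
  out <- mesh
  out@faces <- mesh@faces[keep, , drop = FALSE]
  if (length(mesh@componentIds))
    out@componentIds <- mesh@componentIds[keep]
  if (!is.null(out@provenance$faceIsovalue))
    out@provenance$faceIsovalue <- out@provenance$faceIsovalue[keep]
  out <- .compact_mesh(out)
  out@provenance$stage <- "cull_occluded"
  rep_ <- new("TrimReport", stages = list(.stage_record(
    "cull_occluded", nIn, sum(keep),
    list(accessibilityMin = config@aoAccessibilityMin,
         nDirs = config@aoNDirs,
         accessibilityQuartiles = unname(quantile(acc,
                                                  c(0, .25, .5, .75, 1)))))))
  list(mesh = out, report = rep_)
}
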