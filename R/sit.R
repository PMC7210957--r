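#' Run the full Sequential Isosurface Trimming pipeline
#'
#' Executes denoise, isosurface extraction at `nLevels` gray levels,
#' per-surface streak-component removal, redundancy pruning (keeping the
#' lowest gray level of each redundancy group), merging, and
#' ambient-occlusion culling of concealed faces.  Deterministic for a fixed
#' volume, config and seed.
#'
#' @param volume a [VoxelVolume-class].
#' @param config a [SITConfig-class]; `NA` mm thresholds are resolved against
#'   the volume spacing (streak thickness cap 5 voxels, redundancy distance
#'   1 voxel).
#' @param keepComponents,dropComponents optional escape hatch: lists (indexed
#'   by surface) of component ids to force-keep or force-drop regardless of
#'   the streak classifier.
#' @return list with `mesh` (the final [IsoSurfaceMesh-class]), `report`
#'   (chained [TrimReport-class]), and `meshes` (the per-level surfaces after
#'   streak trimming, for inspection).
#' @examples
#' \donttest{
#' ph <- generatePhantom(compactedSkullSpec(c(64L, 48L, 64L), streakCount = 10L))
#' res <- runSIT(ph$volume, SITConfig(nLevels = 6L))
#' res$report
#' }
#' @export
runSIT <- function(volume, config = SITConfig(), keepComponents = NULL,
                   dropComponents = NULL) {
  validObject(config)
  config <- .resolve_config(config, volume@spacingMm)
  den <- denoise(volume, config@kernel)
  surfaces <- extractIsosurfaces(den, config)
  reports <- list()
  trimmed <- vector("list", length(surfaces))
  for (i in seq_along(surfaces)) {
    m <- surfaces[[i]]
    if (!nrow(m@faces)) { trimmed[[i]] <- m; next }
    tr <- trimStreaks(m, config)
    mT <- tr$mesh
    # manual escape hatch on top of the deterministic classifier
    if (!is.null(dropComponents) && length(dropComponents) >= i &&
        length(dropComponents[[i]])) {
      m2 <- meshComponents(mT)
      keep <- !(m2@componentIds %in% dropComponents[[i]])
      mT@faces <- m2@faces[keep, , drop = FALSE]
      mT@componentIds <- m2@componentIds[keep]
      mT <- .compact_mesh(mT)
    }
    if (!is.null(keepComponents) && length(keepComponents) >= i &&
        length(keepComponents[[i]])) {
      mc <- meshComponents(m)
      keepF <- mc@componentIds %in% keepComponents[[i]] &
        !(mc@componentIds %in% componentIds(meshComponents(tr$mesh)))
      if (any(keepF)) {
        extra <- mc
        extra@faces <- mc@faces[keepF, , drop = FALSE]
        extra@componentIds <- mc@componentIds[keepF]
        mT <- mergeMeshes(list(mT, .compact_mesh(extra)))
        mT@isovalue <- m@isovalue
      }
    }
    trimmed[[i]] <- mT
    reports[[length(reports) + 1L]] <- tr$report
  }
  pr <- pruneRedundant(trimmed, config)
  reports[[length(reports) + 1L]] <- pr$report
  merged <- mergeMeshes(pr$meshes)
  mergeRep <- new("TrimReport", stages = list(.stage_record(
    "merge", nrow(merged@faces), nrow(merged@faces),
    list(surfacesMerged = length(pr$meshes)))))
  reports[[length(reports) + 1L]] <- mergeRep
  if (nrow(merged@faces)) {
    cu <- cullOccluded(merged, config)
    reports[[length(reports) + 1L]] <- cu$report
    # culling fragments partially concealed surfaces; re-apply the noise
    # trim so crumbs and newly exposed sliver components do not survive
    post <- trimStreaks(meshComponents(cu$mesh), config,
                        stage = "trim_after_cull")
    final <- post$mesh
    reports[[length(reports) + 1L]] <- post$report
  } else {
    final <- merged
  }
  final@provenance$pipeline <- "sequential_isosurface_trimming"
  final@provenance$seed <- config@seed
  list(mesh = final, report = do.call(combineReports, reports),
       meshes = trimmed)
}
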