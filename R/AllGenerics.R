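# Generics, accessors and show methods.

#' @name accessors
#' @title Accessors for SeqIsoTrim classes
#' @param x an object.
#' @param object an object.
#' @return the slot contents.
NULL

#' @rdname accessors
#' @export
setGeneric("volValues", function(x) standardGeneric("volValues"))
#' @rdname accessors
#' @export
setMethod("volValues", "VoxelVolume", function(x) x@values)

#' @rdname accessors
#' @export
setGeneric("spacingMm", function(x) standardGeneric("spacingMm"))
#' @rdname accessors
#' @export
setMethod("spacingMm", "VoxelVolume", function(x) x@spacingMm)

#' @rdname accessors
#' @export
setGeneric("meshVertices", function(x) standardGeneric("meshVertices"))
#' @rdname accessors
#' @export
setMethod("meshVertices", "IsoSurfaceMesh", function(x) x@vertices)

#' @rdname accessors
#' @export
setGeneric("meshFaces", function(x) standardGeneric("meshFaces"))
#' @rdname accessors
#' @export
setMethod("meshFaces", "IsoSurfaceMesh", function(x) x@faces)

#' @rdname accessors
#' @export
setGeneric("isovalue", function(x) standardGeneric("isovalue"))
#' @rdname accessors
#' @export
setMethod("isovalue", "IsoSurfaceMesh", function(x) x@isovalue)

#' @rdname accessors
#' @export
setGeneric("componentIds", function(x) standardGeneric("componentIds"))
#' @rdname accessors
#' @export
setMethod("componentIds", "IsoSurfaceMesh", function(x) x@componentIds)

#' @rdname accessors
#' @export
setGeneric("nFaces", function(x) standardGeneric("nFaces"))
#' @rdname accessors
#' @export
setMethod("nFaces", "IsoSurfaceMesh", function(x) nrow(x@faces))

#' @rdname accessors
#' @export
setGeneric("nVertices", function(x) standardGeneric("nVertices"))
#' @rdname accessors
#' @export
setMethod("nVertices", "IsoSurfaceMesh", function(x) nrow(x@vertices))

#' @rdname accessors
#' @export
setGeneric("trimStages", function(x) standardGeneric("trimStages"))
#' @rdname accessors
#' @export
setMethod("trimStages", "TrimReport", function(x) x@stages)

#' @rdname accessors
#' @export
setGeneric("minCost", function(x) standardGeneric("minCost"))
#' @rdname accessors
#' @export
setMethod("minCost", "ParsimonyResult", function(x) x@minCost)

#' @rdname accessors
#' @export
setGeneric("mprSets", function(x) standardGeneric("mprSets"))
#' @rdname accessors
#' @export
setMethod("mprSets", "ParsimonyResult", function(x) x@mprSets)

#' @rdname accessors
#' @export
setGeneric("originRange", function(x) standardGeneric("originRange"))
#' @rdname accessors
#' @export
setMethod("originRange", "ParsimonyResult", function(x) x@originRange)
#' @rdname accessors
#' @export
setMethod("originRange", "MkResult", function(x) x@mlOriginRange)

#' @rdname accessors
#' @export
setGeneric("rateHat", function(x) standardGeneric("rateHat"))
#' @rdname accessors
#' @export
setMethod("rateHat", "MkResult", function(x) x@rateHat)

#' @rdname accessors
#' @export
setGeneric("marginals", function(x) standardGeneric("marginals"))
#' @rdname accessors
#' @export
setMethod("marginals", "MkResult", function(x) x@marginals)

#' @rdname accessors
#' @export
setGeneric("guildLabel", function(x) standardGeneric("guildLabel"))
#' @rdname accessors
#' @export
setMethod("guildLabel", "GuildAssessment", function(x) x@guildLabel)

# ---- show methods ----------------------------------------------------------

setMethod("show", "VoxelVolume", function(object) {
  d <- dim(object@values)
  cat(sprintf("VoxelVolume: %d x %d x %d voxels (X, Y slices, Z)\n",
              d[1], d[2], d[3]))
  cat(sprintf("  spacing: %s mm; extent: %s mm\n",
              paste(signif(object@spacingMm, 4), collapse = " x "),
              paste(signif(d * object@spacingMm, 4), collapse = " x ")))
  cat(sprintf("  gray range: [%.3f, %.3f]\n",
              min(object@values), max(object@values)))
})

setMethod("show", "IsoSurfaceMesh", function(object) {
  cat(sprintf("IsoSurfaceMesh: %d vertices, %d faces", nrow(object@vertices),
              nrow(object@faces)))
  if (!is.na(object@isovalue))
    cat(sprintf(", isovalue %.4f", object@isovalue))
  if (length(object@componentIds))
    cat(sprintf(", %d components", length(unique(object@componentIds))))
  cat("\n")
  if (!is.null(object@provenance$stage))
    cat(sprintf("  stage: %s\n", object@provenance$stage))
})

setMethod("show", "TrimReport", function(object) {
  cat("TrimReport:\n")
  for (st in object@stages) {
    if (!is.null(st$facesIn))
      cat(sprintf("  %-18s faces in %8d kept %8d removed %8d\n",
                  st$stage, st$facesIn, st$facesKept, st$facesRemoved))
    else cat(sprintf("  %-18s %s\n", st$stage,
                     if (!is.null(st$note)) st$note else ""))
  }
})

setMethod("show", "PoseSolution", function(object) {
  cat(sprintf("PoseSolution: %s\n",
              if (object@feasible) "feasible" else "INFEASIBLE"))
  cat(sprintf("  inclination %.2f deg, yaw %.2f deg\n",
              object@anglesDeg[1], object@anglesDeg[2]))
  cat(sprintf("  tip gap %.4f mm (tip-to-plane %.4f mm)\n",
              object@tipGapMm, object@objectiveValue))
  cs <- object@constraintsSatisfied
  cat(sprintf("  constraints: %s\n",
              paste(sprintf("%s=%s", names(cs), cs), collapse = ", ")))
})

setMethod("show", "GuildAssessment", function(object) {
  cat(sprintf("GuildAssessment: %s\n", object@guildLabel))
  cat(sprintf("  crown shape index: %.3g (crushing if > 1.0)\n",
              object@crownShapeIndex))
  cat(sprintf("  relative tooth size: %.3g (crushing if >= 0.1)\n",
              object@relativeToothSize))
  cat(sprintf("  skull width: %.4g mm\n", object@skullWidthMm))
})

setMethod("show", "ParsimonyResult", function(object) {
  cat(sprintf("ParsimonyResult: min cost %g, origins in [%d, %d]\n",
              object@minCost, object@originRange[1], object@originRange[2]))
})

setMethod("show", "MkResult", function(object) {
  cat(sprintf("MkResult: rate %.4g, logLik %.4f, ML origins in [%d, %d]%s\n",
              object@rateHat, object@logLik, object@mlOriginRange[1],
              object@mlOriginRange[2],
              if (object@identifiable) "" else " (rate unidentifiable)"))
})
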