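# Massare feeding-guild morphometrics for marine reptiles: the crushing
# guild is separated by a crown shape index strictly above 1.0 together with
# a relative tooth size at or above 0.1.

#' Estimate skull width from a hemi-width
#'
#' Doubles the measured distance between the lateral margin of the skull
#' roof and the sagittal line (used when only one articulated side of a
#' compacted skull can be measured).
#'
#' @param hemiWidthMm distance from the lateral skull margin to the sagittal
#'   line, mm; must be positive.
#' @return skull width in mm.
#' @examples
#' estimateSkullWidth(15.1)  # 30.2
#' @export
estimateSkullWidth <- function(hemiWidthMm) {
  if (!is.numeric(hemiWidthMm) || any(hemiWidthMm <= 0))
    stop("hemiWidthMm must be positive")
  2 * hemiWidthMm
}

#' Crown shape index
#'
#' Ratio of the largest tooth crown's maximum diameter (along the horizontal
#' plane) to its height, reported to 3 significant figures.  Low-crowned
#' crushing teeth have an index above 1.0.
#'
#' @param maxCrownDiameterMm maximum crown diameter, mm.
#' @param crownHeightMm crown height, mm.
#' @param raw return full precision instead of 3 significant figures.
#' @return dimensionless index.
#' @examples
#' crownShapeIndex(3.13, 1.65)  # 1.90
#' @export
crownShapeIndex <- function(maxCrownDiameterMm, crownHeightMm, raw = FALSE) {
  if (any(maxCrownDiameterMm <= 0)) stop("crown diameter must be positive")
  if (any(crownHeightMm <= 0)) stop("crown height must be positive")
  x <- maxCrownDiameterMm / crownHeightMm
  if (raw) x else signif(x, 3)
}

#' Relative tooth size
#'
#' Maximum dimension of the largest tooth crown divided by the skull width,
#' reported to 3 significant figures.  The crushing guild lies at or above
#' 0.1.
#'
#' @param maxCrownDimensionMm maximum dimension of the largest crown, mm.
#' @param skullWidthMm skull width, mm.
#' @param raw return full precision instead of 3 significant figures.
#' @return dimensionless ratio.
#' @examples
#' relativeToothSize(3.13, 30.2)  # 0.104
#' @export
relativeToothSize <- function(maxCrownDimensionMm, skullWidthMm,
                              raw = FALSE) {
  if (any(maxCrownDimensionMm <= 0)) stop("crown dimension must be positive")
  if (any(skullWidthMm <= 0)) stop("skull width must be positive")
  x <- maxCrownDimensionMm / skullWidthMm
  if (raw) x else signif(x, 3)
}

#' Classify the feeding guild from the two Massare metrics
#'
#' Crushing guild iff the crown shape index is strictly above 1.0 AND the
#' relative tooth size is at or above 0.1 (boundary semantics follow the
#' guild definitions: strict for the index, inclusive for the size).
#'
#' @param csi crown shape index.
#' @param rts relative tooth size.
#' @param skullWidthMm optional skull width recorded in the assessment.
#' @return a [GuildAssessment-class].
#' @examples
#' classifyGuild(1.90, 0.104)
#' @export
classifyGuild <- function(csi, rts, skullWidthMm = NA_real_) {
  stopifnot(csi > 0, rts > 0)
  csiAbove <- csi > 1.0
  rtsAtOrAbove <- rts >= 0.1
  label <- if (csiAbove && rtsAtOrAbove) "crushing" else "not_crushing"
  new("GuildAssessment", crownShapeIndex = csi, relativeToothSize = rts,
      skullWidthMm = skullWidthMm, guildLabel = label,
      criteriaTrace = list(csiAbove = csiAbove,
                           rtsAtOrAbove = rtsAtOrAbove,
                           csiThreshold = 1.0, rtsThreshold = 0.1))
}

#' Full guild assessment from raw measurements
#'
#' Convenience wrapper: computes the skull width from a hemi-width, both
#' Massare metrics (3 significant figures, raw values kept in the trace) and
#' the crushing / not-crushing classification.
#'
#' @param maxCrownDiameterMm maximum crown diameter, mm.
#' @param crownHeightMm crown height, mm.
#' @param hemiWidthMm hemi skull width, mm (alternative to `skullWidthMm`).
#' @param skullWidthMm full skull width, mm.
#' @return a [GuildAssessment-class].
#' @examples
#' assessGuild(3.13, 1.65, hemiWidthMm = 15.1)
#' @export
assessGuild <- function(maxCrownDiameterMm, crownHeightMm,
                        hemiWidthMm = NULL, skullWidthMm = NULL) {
  if (is.null(skullWidthMm)) {
    if (is.null(hemiWidthMm))
      stop("supply hemiWidthMm or skullWidthMm")
    skullWidthMm <- estimateSkullWidth(hemiWidthMm)
  }
  csi <- crownShapeIndex(maxCrownDiameterMm, crownHeightMm)
  rts <- relativeToothSize(maxCrownDiameterMm, skullWidthMm)
  g <- classifyGuild(csi, rts, skullWidthMm)
  g@criteriaTrace$rawCrownShapeIndex <-
    crownShapeIndex(maxCrownDiameterMm, crownHeightMm, raw = TRUE)
  g@criteriaTrace$rawRelativeToothSize <-
    relativeToothSize(maxCrownDiameterMm, skullWidthMm, raw = TRUE)
  g
}
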