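#' Construct a SITConfig
#'
#' See [SITConfig-class] for the meaning and defaults of every field.
#'
#' @param nLevels number of isovalues (default 20).
#' @param levelRange low/high gray-histogram percentiles.
#' @param kernel denoising kernel (2D matrix applied per slice, or 3D array).
#' @param streakElongationMin streak classifier elongation threshold.
#' @param streakThicknessMaxMm streak off-axis cap (`NA` = 5 voxel spacings).
#' @param redundancyDistanceMm redundancy distance (`NA` = 1 voxel spacing).
#' @param redundancyCoverageMin mutual-coverage fraction for redundancy.
#' @param minComponentDiagMm noise-speck filter: drop components with a
#'   bounding-box diagonal below this (`NA` = 8 voxel spacings).
#' @param aoNDirs ambient-occlusion ray directions per face.
#' @param aoAccessibilityMin accessibility floor below which faces are culled.
#' @param aoEpsMm ray-origin offset (`NA` = 1e-4 of the bbox diagonal).
#' @param aoMethod accessibility backend: "depthmap" (default) or
#'   "raycast".
#' @param seed seed for ambient-occlusion direction sampling.
#' @return a [SITConfig-class] object.
#' @examples
#' SITConfig(nLevels = 10L)
#' @export
SITConfig <- function(nLevels = 20L, levelRange = c(60, 99.5),
                      kernel = matrix(1 / 9, 3, 3),
                      streakElongationMin = 10,
                      streakThicknessMaxMm = NA_real_,
                      redundancyDistanceMm = NA_real_,
                      redundancyCoverageMin = 0.9,
                      minComponentDiagMm = NA_real_, aoNDirs = 64L,
                      aoAccessibilityMin = 0.05, aoEpsMm = NA_real_,
                      aoMethod = "depthmap", seed = 1L) {
  new("SITConfig", nLevels = as.integer(nLevels), levelRange = levelRange,
      kernel = kernel, streakElongationMin = streakElongationMin,
      streakThicknessMaxMm = streakThicknessMaxMm,
      redundancyDistanceMm = redundancyDistanceMm,
      redundancyCoverageMin = redundancyCoverageMin,
      minComponentDiagMm = minComponentDiagMm,
      aoNDirs = as.integer(aoNDirs),
      aoAccessibilityMin = aoAccessibilityMin, aoEpsMm = aoEpsMm,
      aoMethod = aoMethod, seed = as.integer(seed))
}
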