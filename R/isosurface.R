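# Isosurface extraction: marching tetrahedra over the voxel grid with
# edge-keyed vertex welding; vertices come out in mm (spacing applied) with
# outward orientation (normals point from high gray toward low gray).

#' Isovalues for a volume under a SITConfig
#'
#' `nLevels` gray levels evenly spaced between the configured low and high
#' percentiles of the volume's gray histogram.
#'
#' @param volume a [VoxelVolume-class] (normally already denoised).
#' @param config a [SITConfig-class].
#' @return numeric vector of isovalues.
#' @export
isovalueLevels <- function(volume, config = SITConfig()) {
  v <- volume@values
  if (max(v) - min(v) < 1e-12)
    stop("volume is constant: no distinct gray levels exist")
  qs <- quantile(v, probs = config@levelRange / 100, names = FALSE)
  if (qs[2] - qs[1] < 1e-12)
    stop("degenerate percentile range: histogram has no spread there")
  if (config@nLevels == 1L) return(mean(qs))
  seq(qs[1], qs[2], length.out = config@nLevels)
}

#' Extract a single isosurface mesh
#'
#' @param volume a [VoxelVolume-class].
#' @param iso gray level in `[0,1]`.
#' @return an [IsoSurfaceMesh-class] with component labels filled in;
#'   empty (and logged) when the isovalue is outside the data range.
#' @export
extractIsosurface <- function(volume, iso) {
  v <- volume@values
  if (iso < min(v) || iso >= max(v)) {
    .log_msg("isovalue %.4f outside data range [%.4f, %.4f]: empty mesh",
             iso, min(v), max(v))
    return(IsoSurfaceMesh(matrix(numeric(), 0, 3),
                          matrix(integer(), 0, 3), isovalue = iso,
                          provenance = list(stage = "extract")))
  }
  r <- .mt_isosurface(as.numeric(v), dim(v), volume@spacingMm, iso)
  m <- IsoSurfaceMesh(r$vertices, r$faces, isovalue = iso,
                      provenance = list(stage = "extract"))
  meshComponents(m)
}

#' Extract isosurfaces at all configured gray levels
#'
#' @param volume a [VoxelVolume-class].
#' @param config a [SITConfig-class]; `nLevels` defaults to the published
#'   count of 20.
#' @param isovalues optional explicit isovalues, overriding the percentile
#'   placement.
#' @return list of [IsoSurfaceMesh-class], one per level, in increasing
#'   isovalue order.
#' @export
extractIsosurfaces <- function(volume, config = SITConfig(),
                               isovalues = NULL) {
  if (is.null(isovalues)) isovalues <- isovalueLevels(volume, config)
  lapply(isovalues, function(iso) extractIsosurface(volume, iso))
}
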