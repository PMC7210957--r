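#' Construct a VoxelVolume
#'
#' @param values 3D numeric array with gray values in `[0, 1]`.  Dimension 1
#'   is the in-slice X axis, dimension 2 the slice index (Y), dimension 3 the
#'   in-slice Z axis.
#' @param spacingMm voxel pitch per axis in mm (length 1 or 3).
#' @return a [VoxelVolume-class] object.
#' @examples
#' vol <- VoxelVolume(array(0.5, c(8, 8, 8)), spacingMm = 0.038)
#' spacingMm(vol)
#' @export
VoxelVolume <- function(values, spacingMm = 0.038) {
  if (length(spacingMm) == 1L) spacingMm <- rep(spacingMm, 3L)
  new("VoxelVolume", values = values, spacingMm = as.numeric(spacingMm),
      axes = c("X", "Y", "Z"))
}

#' Physical voxel-center coordinates of a volume
#'
#' Voxel `[i, j, k]` sits at `((i-1) sx, (j-1) sy, (k-1) sz)` mm; mesh
#' vertices produced by [extractIsosurfaces()] live in the same frame.
#'
#' @param volume a [VoxelVolume-class].
#' @return list of three numeric vectors (x, y, z coordinates in mm).
#' @export
voxelCoords <- function(volume) {
  d <- dim(volume@values)
  s <- volume@spacingMm
  list(x = (seq_len(d[1]) - 1) * s[1],
       y = (seq_len(d[2]) - 1) * s[2],
       z = (seq_len(d[3]) - 1) * s[3])
}
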