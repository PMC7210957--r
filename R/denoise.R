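#' Denoise a volume with a weak normalized convolution filter
#'
#' By default the kernel is applied per slice (2D, in the X-Z plane,
#' mirroring a slice-editor workflow); a 3D array kernel convolves in all
#' three axes.  Kernel weights must sum to 1, so constant regions are left
#' unchanged.  Edges are handled by replication.
#'
#' @param volume a [VoxelVolume-class].
#' @param kernel numeric matrix (2D per-slice kernel, default 3 x 3 box) or
#'   3D numeric array.
#' @return the denoised [VoxelVolume-class].
#' @examples
#' vol <- VoxelVolume(array(0.4, c(8, 8, 8)))
#' identical(volValues(denoise(vol)), volValues(vol))  # constant invariance
#' @export
denoise <- function(volume, kernel = matrix(1 / 9, 3, 3)) {
  stopifnot(is(volume, "VoxelVolume"))
  if (abs(sum(kernel) - 1) > 1e-8)
    stop("kernel weights must be normalized to sum 1")
  vals <- volume@values
  d <- dim(vals)
  nd <- length(dim(kernel))
  if (is.null(dim(kernel)) || !nd %in% c(2L, 3L))
    stop("kernel must be a 2D matrix or 3D array")
  kd <- dim(kernel)
  if (any(kd %% 2 == 0)) stop("kernel dimensions must be odd")
  # pad by edge replication along the convolved axes, then sum shifted copies
  if (nd == 2L) {
    rx <- (kd[1] - 1L) %/% 2L; rz <- (kd[2] - 1L) %/% 2L
    px <- c(rep(1L, rx), seq_len(d[1]), rep(d[1], rx))
    pz <- c(rep(1L, rz), seq_len(d[3]), rep(d[3], rz))
    padded <- vals[px, , pz, drop = FALSE]
    out <- array(0, d)
    for (i in seq_len(kd[1])) for (j in seq_len(kd[2])) {
      w <- kernel[i, j]
      if (w == 0) next
      out <- out + w * padded[(i - 1L) + seq_len(d[1]), ,
                              (j - 1L) + seq_len(d[3]), drop = FALSE]
    }
  } else {
    r <- (kd - 1L) %/% 2L
    px <- c(rep(1L, r[1]), seq_len(d[1]), rep(d[1], r[1]))
    py <- c(rep(1L, r[2]), seq_len(d[2]), rep(d[2], r[2]))
    pz <- c(rep(1L, r[3]), seq_len(d[3]), rep(d[3], r[3]))
    padded <- vals[px, py, pz, drop = FALSE]
    out <- array(0, d)
    for (i in seq_len(kd[1])) for (j in seq_len(kd[2]))
      for (k in seq_len(kd[3])) {
        w <- kernel[i, j, k]
        if (w == 0) next
        out <- out + w * padded[(i - 1L) + seq_len(d[1]),
                                (j - 1L) + seq_len(d[2]),
                                (k - 1L) + seq_len(d[3]), drop = FALSE]
      }
  }
  VoxelVolume(.clip01(out), volume@spacingMm)
}
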