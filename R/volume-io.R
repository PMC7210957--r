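# Volume I/O: NRRD (raw-encoded, spacing in the header) and multi-page TIFF
# stacks (spacing in a JSON sidecar, since baseline TIFF has no 3D spacing
# tag).  The axis convention (X, Y slices, Z) round-trips through both.

#' Write a volume to NRRD
#'
#' Raw-encoded little-endian NRRD with per-axis `spacings` and axis `labels`
#' in the header.  `float` preserves the normalized `[0,1]` gray scale;
#' `ushort` provides a 16-bit export path.
#'
#' @param volume a [VoxelVolume-class] (or a plain integer/numeric array for
#'   label maps, written as `int`).
#' @param path output file path (`.nrrd`).
#' @param type "float", "double" or "ushort".
#' @return `path`, invisibly.
#' @export
writeVolumeNrrd <- function(volume, path, type = c("float", "double",
                                                   "ushort")) {
  type <- match.arg(type)
  if (is(volume, "VoxelVolume")) {
    vals <- volume@values
    spacing <- volume@spacingMm
  } else {
    vals <- volume
    spacing <- rep(1, 3)
  }
  d <- dim(vals)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("NRRD0004",
           "# Complete NRRD file format specification at:",
           "# http://teem.sourceforge.net/nrrd/format.html",
           sprintf("type: %s", type),
           "dimension: 3",
           sprintf("sizes: %d %d %d", d[1], d[2], d[3]),
           sprintf("spacings: %.9g %.9g %.9g", spacing[1], spacing[2],
                   spacing[3]),
           'labels: "X" "Y" "Z"',
           "endian: little",
           "encoding: raw",
           "")
  writeLines(hdr, con, sep = "\n")
  v <- as.vector(vals)
  if (type == "ushort") {
    writeBin(as.integer(round(.clip01(v) * 65535)), con, size = 2,
             endian = "little")
  } else {
    writeBin(as.numeric(v), con,
             size = if (type == "float") 4L else 8L, endian = "little")
  }
  invisible(path)
}

#' Read a volume from NRRD
#'
#' Supports the raw-encoded subset written by [writeVolumeNrrd()] (plus
#' common integer types).  Spacing and axis labels are restored from the
#' header.
#'
#' @param path NRRD file path.
#' @param normalize rescale 16-bit data back to `[0,1]` (default TRUE).
#' @return a [VoxelVolume-class].
#' @export
readVolumeNrrd <- function(path, normalize = TRUE) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!startsWith(magic, "NRRD")) stop("not an NRRD file: ", path)
  fields <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L || !nzchar(line)) break
    if (startsWith(line, "#")) next
    kv <- regmatches(line, regexec("^([^:]+): *(.*)$", line))[[1]]
    if (length(kv) == 3L) fields[[trimws(kv[2])]] <- trimws(kv[3])
  }
  type <- fields[["type"]]
  sizes <- as.integer(strsplit(fields[["sizes"]], " +")[[1]])
  spacing <- if (!is.null(fields[["spacings"]]))
    as.numeric(strsplit(fields[["spacings"]], " +")[[1]]) else rep(1, 3)
  if (!identical(fields[["encoding"]], "raw"))
    stop("only raw encoding is supported")
  endian <- if (is.null(fields[["endian"]])) "little" else fields[["endian"]]
  n <- prod(sizes)
  v <- switch(type,
    float = readBin(con, "numeric", n = n, size = 4L, endian = endian),
    double = readBin(con, "numeric", n = n, size = 8L, endian = endian),
    ushort = ,
    `unsigned short` = ,
    uint16 = readBin(con, "integer", n = n, size = 2L, signed = FALSE,
                     endian = endian),
    int = ,
    int32 = readBin(con, "integer", n = n, size = 4L, endian = endian),
    uchar = ,
    uint8 = as.integer(readBin(con, "raw", n = n)),
    stop("unsupported NRRD type: ", type))
  if (type %in% c("ushort", "unsigned short", "uint16") && normalize)
    v <- v / 65535
  VoxelVolume(array(v, sizes), spacing)
}

#' Write a volume as a multi-page TIFF stack
#'
#' One 16-bit page per slice (slice index = Y); page rows are the Z axis and
#' columns the X axis.  Spacing and the axis convention go to a JSON sidecar
#' `<path>.json` because baseline TIFF has no 3-axis spacing tag.
#'
#' @param volume a [VoxelVolume-class].
#' @param path output `.tif` path.
#' @return `path`, invisibly.
#' @export
writeVolumeTiff <- function(volume, path) {
  vals <- volume@values
  d <- dim(vals)
  pages <- lapply(seq_len(d[2]), function(j) t(vals[, j, ]))  # Z rows, X cols
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  jsonlite::write_json(list(spacingMm = volume@spacingMm,
                            axes = c("X", "Y", "Z"),
                            pageLayout = "rows=Z, cols=X, page=Y"),
                       paste0(path, ".json"), auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Read a multi-page TIFF stack
#'
#' @param path `.tif` path written by [writeVolumeTiff()] (or any gray-scale
#'   stack with the same page layout).
#' @param spacingMm spacing override; defaults to the JSON sidecar when
#'   present, else 1 mm.
#' @return a [VoxelVolume-class].
#' @export
readVolumeTiff <- function(path, spacingMm = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  side <- paste0(path, ".json")
  if (is.null(spacingMm)) {
    spacingMm <- if (file.exists(side))
      as.numeric(jsonlite::read_json(side, simplifyVector = TRUE)$spacingMm)
    else rep(1, 3)
  }
  nzr <- nrow(pages[[1]]); nxc <- ncol(pages[[1]])
  vals <- array(0, c(nxc, length(pages), nzr))
  for (j in seq_along(pages)) vals[, j, ] <- t(pages[[j]])
  VoxelVolume(vals, spacingMm)
}

#' Write / read a volume by file extension
#'
#' Dispatches on `.nrrd` vs `.tif`/`.tiff`.
#'
#' @param volume a [VoxelVolume-class].
#' @param path file path.
#' @return `path` (write) or a [VoxelVolume-class] (read).
#' @export
writeVolume <- function(volume, path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         nrrd = writeVolumeNrrd(volume, path),
         tif = ,
         tiff = writeVolumeTiff(volume, path),
         stop("unsupported volume format: .", ext))
}

#' @rdname writeVolume
#' @export
readVolume <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         nrrd = readVolumeNrrd(path),
         tif = ,
         tiff = readVolumeTiff(path),
         stop("unsupported volume format: .", ext))
}
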