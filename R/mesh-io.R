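# Triangle-mesh I/O: PLY (ASCII and binary little-endian) and OBJ.
# The isovalue travels in a PLY comment so trimmed surfaces keep their gray
# level across files.

#' Write a mesh to PLY
#'
#' @param mesh an [IsoSurfaceMesh-class].
#' @param path output `.ply` path.
#' @param binary write binary little-endian (default) or ASCII.
#' @return `path`, invisibly.
#' @export
writeMeshPly <- function(mesh, path, binary = TRUE) {
  V <- mesh@vertices; F <- mesh@faces
  hdr <- c("ply",
           sprintf("format %s 1.0",
                   if (binary) "binary_little_endian" else "ascii"),
           "comment SeqIsoTrim mesh",
           sprintf("comment isovalue %.10g",
                   if (is.na(mesh@isovalue)) -1 else mesh@isovalue),
           sprintf("element vertex %d", nrow(V)),
           "property float x", "property float y", "property float z",
           sprintf("element face %d", nrow(F)),
           "property list uchar int vertex_indices",
           "end_header")
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(hdr, con, sep = "\n")
    writeBin(as.numeric(t(V)), con, size = 4L, endian = "little")
    if (nrow(F)) {
      # interleave uchar count 3 with three int32 indices, vectorized
      idx <- writeBin(as.integer(t(F) - 1L), raw(), size = 4L,
                      endian = "little")
      rec <- rbind(matrix(as.raw(3L), 1L, nrow(F)),
                   matrix(idx, nrow = 12L))
      writeBin(as.vector(rec), con)
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(hdr, con)
    if (nrow(V))
      writeLines(sprintf("%.9g %.9g %.9g", V[, 1], V[, 2], V[, 3]), con)
    if (nrow(F))
      writeLines(sprintf("3 %d %d %d", F[, 1] - 1L, F[, 2] - 1L,
                         F[, 3] - 1L), con)
  }
  invisible(path)
}

#' Read a mesh from PLY
#'
#' Supports ASCII and binary little-endian triangle PLY with float vertex
#' coordinates (the subset written by [writeMeshPly()]).
#'
#' @param path `.ply` file path.
#' @return an [IsoSurfaceMesh-class].
#' @export
readMeshPly <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character()
  repeat {
    line <- readLines(con, n = 1L)
    hdr <- c(hdr, line)
    if (identical(line, "end_header")) break
    if (length(hdr) > 1000L) stop("malformed PLY header")
  }
  fmt <- grep("^format", hdr, value = TRUE)
  binary <- grepl("binary_little_endian", fmt)
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex", hdr, value = TRUE)))
  nf <- as.integer(sub("element face ", "",
                       grep("^element face", hdr, value = TRUE)))
  isoLine <- grep("^comment isovalue", hdr, value = TRUE)
  iso <- if (length(isoLine)) as.numeric(sub("comment isovalue ", "",
                                             isoLine)) else NA_real_
  if (!is.na(iso) && iso < 0) iso <- NA_real_
  if (binary) {
    V <- matrix(readBin(con, "numeric", n = 3L * nv, size = 4L,
                        endian = "little"), ncol = 3, byrow = TRUE)
    rawF <- matrix(readBin(con, "raw", n = 13L * nf), nrow = 13L)
    if (nf && any(as.integer(rawF[1L, ]) != 3L))
      stop("only triangle PLY faces are supported")
    F <- matrix(readBin(as.vector(rawF[-1L, , drop = FALSE]), "integer",
                        n = 3L * nf, size = 4L, endian = "little"),
                ncol = 3, byrow = TRUE) + 1L
  } else {
    txt <- readLines(con)
    vl <- utils::head(txt, nv)
    V <- matrix(as.numeric(unlist(strsplit(trimws(vl), " +"))), ncol = 3,
                byrow = TRUE)
    fl <- txt[(nv + 1L):(nv + nf)]
    fm <- matrix(as.integer(unlist(strsplit(trimws(fl), " +"))), ncol = 4,
                 byrow = TRUE)
    if (any(fm[, 1] != 3L)) stop("only triangle PLY faces are supported")
    F <- fm[, 2:4, drop = FALSE] + 1L
  }
  IsoSurfaceMesh(V, F, isovalue = iso,
                 provenance = list(source = path))
}

#' Write / read a mesh as Wavefront OBJ
#'
#' @param mesh an [IsoSurfaceMesh-class].
#' @param path `.obj` path.
#' @return `path` (write) or an [IsoSurfaceMesh-class] (read).
#' @export
writeMeshObj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# SeqIsoTrim mesh", con)
  V <- mesh@vertices; F <- mesh@faces
  if (nrow(V))
    writeLines(sprintf("v %.9g %.9g %.9g", V[, 1], V[, 2], V[, 3]), con)
  if (nrow(F))
    writeLines(sprintf("f %d %d %d", F[, 1], F[, 2], F[, 3]), con)
  invisible(path)
}

#' @rdname writeMeshObj
#' @export
readMeshObj <- function(path) {
  txt <- readLines(path)
  vl <- grep("^v ", txt, value = TRUE)
  fl <- grep("^f ", txt, value = TRUE)
  V <- matrix(as.numeric(unlist(strsplit(sub("^v +", "", vl), " +"))),
              ncol = 3, byrow = TRUE)
  ftok <- strsplit(sub("^f +", "", fl), " +")
  F <- t(vapply(ftok, function(t) as.integer(sub("/.*$", "", t)),
                integer(3)))
  IsoSurfaceMesh(V, F, provenance = list(source = path))
}

#' Write a mesh by file extension (.ply, .obj, .stl)
#'
#' STL output is ASCII.
#'
#' @param mesh an [IsoSurfaceMesh-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeMesh <- function(mesh, path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         ply = writeMeshPly(mesh, path),
         obj = writeMeshObj(mesh, path),
         stl = .writeMeshStl(mesh, path),
         stop("unsupported mesh format: .", ext))
}

#' @rdname writeMesh
#' @export
readMesh <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         ply = readMeshPly(path),
         obj = readMeshObj(path),
         stop("unsupported mesh format: .", ext))
}

.writeMeshStl <- function(mesh, path) {
  V <- mesh@vertices; F <- mesh@faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid SeqIsoTrim", con)
  for (i in seq_len(nrow(F))) {
    a <- V[F[i, 1], ]; b <- V[F[i, 2], ]; c_ <- V[F[i, 3], ]
    n <- pracma_cross(b - a, c_ - a)
    nn <- sqrt(sum(n^2)); if (nn > 0) n <- n / nn
    writeLines(c(sprintf("facet normal %.9g %.9g %.9g", n[1], n[2], n[3]),
                 "  outer loop",
                 sprintf("    vertex %.9g %.9g %.9g", a[1], a[2], a[3]),
                 sprintf("    vertex %.9g %.9g %.9g", b[1], b[2], b[3]),
                 sprintf("    vertex %.9g %.9g %.9g", c_[1], c_[2], c_[3]),
                 "  endloop", "endfacet"), con)
  }
  writeLines("endsolid SeqIsoTrim", con)
  invisible(path)
}
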