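# IsoSurfaceMesh construction, basic geometry, and parametric toy meshes used
# in validation (spheres, tubes, torus arcs, a toy mandibular ramus).

#' Construct an IsoSurfaceMesh
#'
#' @param vertices numeric matrix (n x 3), mm.
#' @param faces integer matrix (m x 3), 1-based vertex indices.
#' @param isovalue extraction gray level (`NA` for synthetic or merged
#'   meshes).
#' @param componentIds optional per-face component labels; computed on demand
#'   by [meshComponents()].
#' @param provenance free-form list (source id, stage).
#' @return an [IsoSurfaceMesh-class].
#' @export
IsoSurfaceMesh <- function(vertices, faces, isovalue = NA_real_,
                           componentIds = integer(), provenance = list()) {
  storage.mode(faces) <- "integer"
  vertices <- as.matrix(vertices)
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  new("IsoSurfaceMesh", vertices = vertices, faces = faces,
      isovalue = isovalue, componentIds = as.integer(componentIds),
      provenance = provenance)
}

#' Label connected components of a mesh
#'
#' Components are maximal sets of faces connected through shared vertices.
#'
#' @param mesh an [IsoSurfaceMesh-class].
#' @return the mesh with `componentIds` filled in.
#' @export
meshComponents <- function(mesh) {
  if (!nrow(mesh@faces)) {
    mesh@componentIds <- integer()
    return(mesh)
  }
  mesh@componentIds <- .mesh_face_components(mesh@faces, nrow(mesh@vertices))
  mesh
}

#' Apply a 4x4 homogeneous transform to a mesh
#'
#' Reflections (determinant -1) flip the face winding so the surface
#' orientation is preserved.
#'
#' @param mesh an [IsoSurfaceMesh-class].
#' @param transform 4x4 matrix.
#' @return the transformed mesh.
#' @export
transformMesh <- function(mesh, transform) {
  stopifnot(all(dim(transform) == c(4, 4)))
  V <- cbind(mesh@vertices, 1) %*% t(transform)
  mesh@vertices <- V[, 1:3, drop = FALSE]
  if (det(transform[1:3, 1:3]) < 0)
    mesh@faces <- mesh@faces[, c(1, 3, 2), drop = FALSE]
  mesh
}

# axis-aligned bounding box: 2 x 3 matrix (min; max)
.mesh_bbox <- function(vertices) {
  rbind(apply(vertices, 2, min), apply(vertices, 2, max))
}

# drop unreferenced vertices, remapping faces
.compact_mesh <- function(mesh) {
  if (!nrow(mesh@faces)) {
    mesh@vertices <- matrix(numeric(), 0, 3)
    return(mesh)
  }
  used <- sort(unique(as.vector(mesh@faces)))
  remap <- integer(nrow(mesh@vertices))
  remap[used] <- seq_along(used)
  mesh@vertices <- mesh@vertices[used, , drop = FALSE]
  f <- matrix(remap[mesh@faces], ncol = 3)
  storage.mode(f) <- "integer"
  mesh@faces <- f
  mesh
}

# total area and per-face areas
.face_areas <- function(mesh) {
  V <- mesh@vertices; F <- mesh@faces
  if (!nrow(F)) return(numeric())
  a <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  b <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  0.5 * sqrt(rowSums(cr^2))
}

# ---------------------------------------------------------------------------
# parametric toy meshes
# ---------------------------------------------------------------------------

#' Parametric toy meshes
#'
#' Closed-form triangle meshes used to validate the pipeline: a UV sphere, an
#' axis-aligned capped tube (streak-like), a torus arc, and a curved toy
#' mandibular ramus (a quarter-torus tube, tip curving medially and upward).
#'
#' @param center sphere center (mm).
#' @param radius sphere / tube / torus tube radius (mm).
#' @param nTheta,nPhi angular resolution.
#' @return an [IsoSurfaceMesh-class] with `isovalue = NA`.
#' @name toyMeshes
NULL

#' @rdname toyMeshes
#' @export
uvSphereMesh <- function(center = c(0, 0, 0), radius = 1, nTheta = 24L,
                         nPhi = 16L) {
  th <- seq(0, 2 * pi, length.out = nTheta + 1L)[-1L]
  ph <- seq(0, pi, length.out = nPhi + 1L)
  ring <- function(p) cbind(radius * sin(p) * cos(th),
                            radius * sin(p) * sin(th),
                            rep(radius * cos(p), nTheta))
  V <- rbind(c(0, 0, radius), do.call(rbind, lapply(ph[-c(1, nPhi + 1L)],
                                                    ring)), c(0, 0, -radius))
  V <- sweep(V, 2, center, "+")
  nr <- nPhi - 1L                        # interior rings
  id <- function(r, t) 1L + (r - 1L) * nTheta + ((t - 1L) %% nTheta) + 1L
  F <- list()
  for (t in seq_len(nTheta)) {            # top cap
    F[[length(F) + 1L]] <- c(1L, id(1L, t), id(1L, t + 1L))
  }
  if (nr > 1L) for (r in seq_len(nr - 1L)) for (t in seq_len(nTheta)) {
    a <- id(r, t); b <- id(r, t + 1L); c_ <- id(r + 1L, t); d <- id(r + 1L, t + 1L)
    F[[length(F) + 1L]] <- c(a, c_, b)
    F[[length(F) + 1L]] <- c(b, c_, d)
  }
  bot <- nrow(V)
  for (t in seq_len(nTheta)) {            # bottom cap
    F[[length(F) + 1L]] <- c(bot, id(nr, t + 1L), id(nr, t))
  }
  IsoSurfaceMesh(V, do.call(rbind, F), provenance = list(stage = "toy"))
}

#' @rdname toyMeshes
#' @param start,end segment endpoints (mm) of the tube axis.
#' @param nSeg segments along the tube.
#' @export
tubeMesh <- function(start, end, radius = 0.05, nTheta = 8L, nSeg = 8L) {
  axis <- .unit(end - start)
  ref <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- .unit(pracma_cross(axis, ref))
  w <- pracma_cross(axis, u)
  th <- seq(0, 2 * pi, length.out = nTheta + 1L)[-1L]
  ts <- seq(0, 1, length.out = nSeg + 1L)
  V <- do.call(rbind, lapply(ts, function(t) {
    ctr <- start + t * (end - start)
    sweep(radius * (outer(cos(th), u) + outer(sin(th), w)), 2, ctr, "+")
  }))
  V <- rbind(V, start, end)
  iS <- nrow(V) - 1L; iE <- nrow(V)
  id <- function(s, t) (s - 1L) * nTheta + ((t - 1L) %% nTheta) + 1L
  F <- list()
  for (s in seq_len(nSeg)) for (t in seq_len(nTheta)) {
    a <- id(s, t); b <- id(s, t + 1L); c_ <- id(s + 1L, t); d <- id(s + 1L, t + 1L)
    F[[length(F) + 1L]] <- c(a, b, c_)
    F[[length(F) + 1L]] <- c(b, d, c_)
  }
  for (t in seq_len(nTheta)) {
    F[[length(F) + 1L]] <- c(iS, id(1L, t + 1L), id(1L, t))
    F[[length(F) + 1L]] <- c(iE, id(nSeg + 1L, t), id(nSeg + 1L, t + 1L))
  }
  IsoSurfaceMesh(V, do.call(rbind, F), provenance = list(stage = "toy"))
}

#' @rdname toyMeshes
#' @param arcRadius radius of the torus centerline (mm).
#' @param tubeRadius radius of the tube (mm).
#' @param arcDeg arc span in degrees (90 = quarter torus).
#' @param nArc,nTube resolution along / around the arc.
#' @details `torusArcMesh` builds the arc in the x-y plane, centered at the
#'   origin, starting at `(arcRadius, 0, 0)` and ending at the angle
#'   `arcDeg`; tube cross-sections are circles.
#' @export
torusArcMesh <- function(arcRadius = 15, tubeRadius = 1.5, arcDeg = 90,
                         nArc = 24L, nTube = 12L) {
  al <- seq(0, arcDeg * pi / 180, length.out = nArc + 1L)
  th <- seq(0, 2 * pi, length.out = nTube + 1L)[-1L]
  V <- do.call(rbind, lapply(al, function(a) {
    ctr <- c(arcRadius * cos(a), arcRadius * sin(a), 0)
    radial <- c(cos(a), sin(a), 0)
    vert <- c(0, 0, 1)
    sweep(tubeRadius * (outer(cos(th), radial) + outer(sin(th), vert)),
          2, ctr, "+")
  }))
  startCtr <- c(arcRadius, 0, 0)
  endCtr <- c(arcRadius * cos(max(al)), arcRadius * sin(max(al)), 0)
  V <- rbind(V, startCtr, endCtr)
  iS <- nrow(V) - 1L; iE <- nrow(V)
  id <- function(s, t) (s - 1L) * nTube + ((t - 1L) %% nTube) + 1L
  F <- list()
  for (s in seq_len(nArc)) for (t in seq_len(nTube)) {
    a <- id(s, t); b <- id(s, t + 1L); c_ <- id(s + 1L, t); d <- id(s + 1L, t + 1L)
    F[[length(F) + 1L]] <- c(a, b, c_)
    F[[length(F) + 1L]] <- c(b, d, c_)
  }
  for (t in seq_len(nTube)) {
    F[[length(F) + 1L]] <- c(iS, id(1L, t + 1L), id(1L, t))
    F[[length(F) + 1L]] <- c(iE, id(nArc + 1L, t), id(nArc + 1L, t + 1L))
  }
  IsoSurfaceMesh(V, do.call(rbind, F), provenance = list(stage = "toy"))
}

#' @rdname toyMeshes
#' @param jointToTipLateralMm lateral offset between the jaw joint and the
#'   anterior tip of the toy ramus (defaults to half the 30.2 mm skull-width
#'   estimate, so the tips can just reach the sagittal plane).
#' @details `toyRamusMesh` returns a list: `mesh` plus a
#'   [RamusLandmarks-class] with the joint at the arc start and the tip at
#'   the arc end.
#' @export
toyRamusMesh <- function(jointToTipLateralMm = 15.1, tubeRadius = 1.2,
                         nArc = 20L, nTube = 10L) {
  m <- torusArcMesh(arcRadius = jointToTipLateralMm, tubeRadius = tubeRadius,
                    arcDeg = 90, nArc = nArc, nTube = nTube)
  joint <- c(jointToTipLateralMm, 0, 0)
  tip <- c(0, jointToTipLateralMm, 0)
  lm <- RamusLandmarks(jointPoint = joint, anteriorTip = tip)
  list(mesh = m, landmarks = lm)
}
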