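# Mesh file round trips.

test_that("binary PLY round-trips vertices, faces and the isovalue", {
  m <- uvSphereMesh(radius = 1.5, nTheta = 12, nPhi = 8)
  m@isovalue <- 0.37
  f <- tempfile(fileext = ".ply")
  writeMeshPly(m, f)
  back <- readMeshPly(f)
  expect_equal(meshVertices(back), meshVertices(m), tolerance = 1e-6)
  expect_identical(meshFaces(back), meshFaces(m))
  expect_equal(isovalue(back), 0.37, tolerance = 1e-9)
})

test_that("ASCII PLY and OBJ round-trip too", {
  m <- tubeMesh(c(0, 0, 0), c(1, 2, 3), radius = 0.2)
  fa <- tempfile(fileext = ".ply")
  writeMeshPly(m, fa, binary = FALSE)
  backA <- readMeshPly(fa)
  expect_equal(meshVertices(backA), meshVertices(m), tolerance = 1e-6)
  expect_identical(meshFaces(backA), meshFaces(m))
  fo <- tempfile(fileext = ".obj")
  writeMeshObj(m, fo)
  backO <- readMeshObj(fo)
  expect_equal(meshVertices(backO), meshVertices(m), tolerance = 1e-6)
  expect_identical(meshFaces(backO), meshFaces(m))
})

test_that("STL export writes one facet per face", {
  m <- uvSphereMesh(radius = 1, nTheta = 8, nPhi = 5)
  fs <- tempfile(fileext = ".stl")
  writeMesh(m, fs)
  txt <- readLines(fs)
  expect_equal(sum(grepl("^facet", txt)), nFaces(m))
})
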