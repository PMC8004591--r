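test_that("ASCII PLY writing and reading round-trips a mesh exactly", {
  sq <- TriangleMesh(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)),
                     rbind(c(1, 2, 3), c(1, 3, 4)))
  path <- withr::local_tempfile(fileext = ".ply")
  writeMesh(sq, path)
  m <- readMesh(path)
  expect_equal(nVertices(m), 4L)
  expect_equal(nFaces(m), 2L)
  expect_lt(max(abs(vertices(m) - vertices(sq))), 1e-6)
  expect_identical(faces(m), faces(sq))

  # a second round trip with awkward coordinates
  set.seed(1)
  rnd <- TriangleMesh(matrix(rnorm(30) * 1000, 10, 3),
                      rbind(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9),
                            c(1, 5, 9), c(2, 6, 10)))
  writeMesh(rnd, path)
  m2 <- readMesh(path)
  expect_lt(max(abs(vertices(m2) - vertices(rnd))), 1e-6)
  expect_identical(faces(m2), faces(rnd))
})

test_that("binary little-endian PLY with extra vertex properties is parsed", {
  path <- withr::local_tempfile(fileext = ".ply")
  con <- file(path, "wb")
  header <- paste0("ply\nformat binary_little_endian 1.0\n",
                   "element vertex 4\n",
                   "property float x\nproperty float y\nproperty float z\n",
                   "property float confidence\n",
                   "element face 2\n",
                   "property list uchar int vertex_indices\nend_header\n")
  writeChar(header, con, eos = NULL)
  V <- rbind(c(0, 0, 0), c(2, 0, 0), c(2, 1, 0), c(0, 1, 0))
  for (i in 1:4)
    writeBin(c(V[i, ], 0.5), con, size = 4L, endian = "little")
  for (fc in list(c(0L, 1L, 2L), c(0L, 2L, 3L))) {
    writeBin(as.raw(3L), con)
    writeBin(fc, con, size = 4L, endian = "little")
  }
  close(con)
  m <- readMesh(path)
  expect_equal(nVertices(m), 4L)
  expect_equal(faces(m), rbind(c(1L, 2L, 3L), c(1L, 3L, 4L)))
  expect_lt(max(abs(vertices(m) - V)), 1e-6)
})

test_that("OBJ polygonal faces are fan-triangulated and round-trip", {
  path <- withr::local_tempfile(fileext = ".obj")
  writeLines(c("v 0 0 0", "v 1 0 0", "v 1 1 0", "v 0 1 0",
               "f 1 2 3 4"), path)
  m <- readMesh(path)
  expect_equal(nFaces(m), 2L)
  expect_equal(faces(m), rbind(c(1L, 2L, 3L), c(1L, 3L, 4L)))

  path2 <- withr::local_tempfile(fileext = ".obj")
  writeMesh(m, path2)
  m2 <- readMesh(path2)
  expect_lt(max(abs(vertices(m2) - vertices(m))), 1e-6)
  expect_identical(faces(m2), faces(m))
})

test_that("malformed meshes raise format errors naming the problem", {
  path <- withr::local_tempfile(fileext = ".obj")
  writeLines(c("v 0 0 0", "v 1 0 0", "v 1 1 0", "v 0 1 0", "f 1 2 9"), path)
  expect_error(readMesh(path), "references vertex 9")

  empty <- withr::local_tempfile(fileext = ".obj")
  writeLines(c("v 0 0 0", "v 1 0 0", "v 1 1 0"), empty)
  expect_error(readMesh(empty), "no faces")

  expect_error(readMesh(file.path(tempdir(), "missing-file.ply")),
               "file not found")

  junk <- withr::local_tempfile(fileext = ".ply")
  writeLines("not a mesh at all", junk)
  expect_error(readMesh(junk))
})

test_that("TriangleMesh validity rejects bad faces", {
  expect_error(TriangleMesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                            rbind(c(1, 2, 5))), "out of range")
  expect_error(TriangleMesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                            rbind(c(1, 2, 2))), "degenerate")
})
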