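test_that("RANSAC finds a planted table plane", {
  # table at z = 0 (about 40% of vertices) plus an elevated blob
  set.seed(5)
  table <- gridMesh(seq(-100, 100, by = 10), seq(-100, 100, by = 10))
  blob <- transformMesh(icosphereMesh(3L, radius = 40), t = c(0, 0, 200))
  scene <- TriangleMesh(rbind(vertices(table), vertices(blob)),
                        rbind(faces(table), faces(blob) + nVertices(table)))
  plane <- detectTablePlane(scene, PreprocessConfig(rngSeed = 11L))
  expect_gt(abs(plane@normal[3]), cos(1 * pi / 180))   # within 1 degree
  expect_lt(abs(plane@offset * sign(plane@normal[3])), 0.5)
})

test_that("jittered table matches an exhaustive least-squares oracle", {
  set.seed(9)
  table <- gridMesh(seq(-100, 100, by = 10), seq(-100, 100, by = 10))
  tv <- vertices(table)
  tv[, 3] <- tv[, 3] + rnorm(nrow(tv), 0, 0.5)
  blob <- transformMesh(icosphereMesh(3L, radius = 40), t = c(0, 0, 200))
  scene <- TriangleMesh(rbind(tv, vertices(blob)),
                        rbind(faces(table), faces(blob) + nrow(tv)))
  plane <- detectTablePlane(scene, PreprocessConfig(rngSeed = 11L))

  # oracle: least squares on the known table vertices
  ctr <- colMeans(tv)
  ev <- eigen(crossprod(sweep(tv, 2, ctr)), symmetric = TRUE)
  n_ref <- ev$vectors[, 3] * sign(ev$vectors[3, 3])
  off_ref <- sum(n_ref * ctr)
  n_est <- plane@normal * sign(plane@normal[3])
  expect_gt(sum(n_est * n_ref), cos(2 * pi / 180))     # within 2 degrees
  expect_lt(abs(plane@offset * sign(plane@normal[3]) - off_ref), 2)
})

test_that("a sphere-only mesh has no dominant plane", {
  # random points on a sphere: no plane holds more than the ~2% equatorial
  # band within tolerance (an exact icosphere has large coplanar rings)
  set.seed(8)
  P <- matrix(rnorm(3 * 2000), ncol = 3)
  P <- 100 * P / sqrt(rowSums(P^2))
  sph <- TriangleMesh(P, rbind(c(1L, 2L, 3L)))
  expect_error(detectTablePlane(sph, PreprocessConfig(rngSeed = 2L)),
               "no dominant plane")
})

test_that("RANSAC is reproducible for a fixed seed", {
  scene <- generatePlantScene(PlantSceneSpec(nLeaves = 4, rngSeed = 5))$mesh
  p1 <- detectTablePlane(scene, PreprocessConfig(rngSeed = 3L))
  p2 <- detectTablePlane(scene, PreprocessConfig(rngSeed = 3L))
  expect_identical(p1@normal, p2@normal)
  expect_identical(p1@offset, p2@offset)
  expect_identical(p1@inlierCount, p2@inlierCount)
})

test_that("buffer removal keeps exactly the ledger's plant faces", {
  scene <- generatePlantScene(PlantSceneSpec(nLeaves = 5, rngSeed = 13))
  plane <- detectTablePlane(scene$mesh)
  plant <- removeNonPlant(scene$mesh, plane)
  kept <- attr(plant, "keptFaces")
  leaf_faces <- sort(unlist(lapply(scene$ledger$leaves, `[[`, "face_ids")))
  expect_identical(sort(kept), leaf_faces)
  # output faces are a subset of input faces, and vertex provenance holds
  expect_true(all(kept %in% seq_len(nFaces(scene$mesh))))
  expect_identical(nrow(plant@vertices), length(plant@vertexIndex))
})

test_that("as the buffer shrinks to zero only on-table faces are removed", {
  # plant face fully above the plane, clutter face on the plane
  V <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0),
             c(0, 0, 50), c(10, 0, 50), c(0, 10, 55))
  mesh <- TriangleMesh(V, rbind(c(1, 2, 3), c(4, 5, 6)))
  plane <- new("PlaneModel", normal = c(0, 0, 1), offset = 0,
               inlierCount = 3L)
  out <- removeNonPlant(mesh, plane, PreprocessConfig(epsilonMm = 1e-6))
  expect_equal(nFaces(out), 1L)
  expect_equal(out@vertexIndex, 4:6)
})

test_that("a mesh entirely above the buffer passes through unchanged", {
  leaf <- generateLeaf(15, 8, 0, 1.5)$mesh
  lifted <- transformMesh(leaf, t = c(0, 0, 200))
  plane <- new("PlaneModel", normal = c(0, 0, 1), offset = 0,
               inlierCount = 3L)
  out <- removeNonPlant(lifted, plane)
  expect_equal(vertices(out), vertices(lifted))
  expect_equal(faces(out), faces(lifted))
})

test_that("an all-clutter mesh raises a no-plant-geometry error", {
  table <- gridMesh(seq(0, 50, 10), seq(0, 50, 10))
  plane <- new("PlaneModel", normal = c(0, 0, 1), offset = 0,
               inlierCount = 3L)
  expect_error(removeNonPlant(table, plane), "no plant geometry")
})
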