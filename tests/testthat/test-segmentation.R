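# manual vertex field: constant normals per plate, zero curvature
plateField <- function(normals_per_vertex) {
  new("VertexField", normals = normals_per_vertex,
      curvature = rep(0, nrow(normals_per_vertex)),
      smoothness = rep(0, nrow(normals_per_vertex)))
}

test_that("disconnected coplanar patches form separate clusters", {
  p1 <- gridMesh(seq(0, 6), seq(0, 6))
  p2 <- transformMesh(gridMesh(seq(0, 6), seq(0, 6)), t = c(20, 0, 0))
  mesh <- TriangleMesh(rbind(vertices(p1), vertices(p2)),
                       rbind(faces(p1), faces(p2) + nVertices(p1)))
  field <- plateField(matrix(rep(c(0, 0, 1), each = nVertices(mesh)),
                             ncol = 3))
  rg <- regionGrowing(mesh, field, epsA = 10, epsB = 0.1,
                      minClusterVertices = 10L)
  expect_length(rg$clusters, 2L)
  expect_length(rg$small, 0L)
})

test_that("a single flat plate is one cluster containing every vertex", {
  plate <- gridMesh(seq(0, 8), seq(0, 8))
  field <- plateField(matrix(rep(c(0, 0, 1), each = nVertices(plate)),
                             ncol = 3))
  rg <- regionGrowing(plate, field, epsA = 5, epsB = 0.1,
                      minClusterVertices = 10L)
  expect_length(rg$clusters, 1L)
  expect_setequal(rg$clusters[[1]]@vertexIds, seq_len(nVertices(plate)))
})

test_that("the smoothness threshold decides whether a dihedral splits", {
  # two plates joined along a hinge at a 60-degree dihedral angle
  ny <- 7L
  left <- gridMesh(seq(-6, 0), seq(0, 6))
  dihedral <- 60 * pi / 180
  right <- gridMesh(seq(0, 6), seq(0, 6),
                    function(x, y) cbind(x * cos(dihedral), y,
                                         x * sin(dihedral)))
  nL <- nVertices(left)
  hingeL <- which(vertices(left)[, 1] == 0)
  hingeR <- which(vertices(right)[, 1] == 0)
  remap <- seq_len(nVertices(right)) + nL
  remap[hingeR] <- hingeL          # share the hinge row of vertices
  mesh <- TriangleMesh(rbind(vertices(left), vertices(right)),
                       rbind(faces(left),
                             matrix(remap[faces(right)], ncol = 3)))
  # normals: left plate (0,0,1); right plate rotated by the dihedral;
  # hinge vertices carry the left normal
  nrm_left <- c(0, 0, 1)
  nrm_right <- c(-sin(dihedral), 0, cos(dihedral))
  N <- matrix(rep(nrm_left, each = nVertices(mesh)), ncol = 3)
  right_ids <- setdiff(unique(as.vector(remap[faces(right)])), hingeL)
  N[right_ids, ] <- matrix(rep(nrm_right, each = length(right_ids)), ncol = 3)
  field <- plateField(N)
  # the unsigned angle between the plate normals is 60 degrees
  rg30 <- regionGrowing(mesh, field, epsA = 30, epsB = 0.1, 10L)
  expect_length(rg30$clusters, 2L)
  rg90 <- regionGrowing(mesh, field, epsA = 90, epsB = 0.1, 10L)
  expect_length(rg90$clusters, 1L)
})

test_that("multilevel segmentation recovers all leaves of a clean plant", {
  scene <- generatePlantScene(PlantSceneSpec(nLeaves = 6, rngSeed = 7))
  plant <- removeNonPlant(scene$mesh, detectTablePlane(scene$mesh))
  report <- multilevelSegment(plant)
  expect_length(report@typicalLeaves, 6L)
  expect_lte(report@levelsRun, 30L)
  m <- matchLedger(report, plant, scene$ledger, minOverlap = 0.9)
  expect_equal(m$recall, 1)

  # vertex-disjoint typical leaves
  ids <- unlist(lapply(report@typicalLeaves, slot, "vertexIds"))
  expect_identical(anyDuplicated(ids), 0L)

  # threshold schedule decreases strictly
  if (nrow(report@levelLog) > 1) {
    expect_true(all(diff(report@levelLog$eps_a) < 0))
    expect_true(all(diff(report@levelLog$eps_b) < 0))
  }
})

test_that("multilevel segmentation is deterministic", {
  scene <- generatePlantScene(PlantSceneSpec(nLeaves = 4, rngSeed = 19))
  plant <- removeNonPlant(scene$mesh, detectTablePlane(scene$mesh))
  r1 <- multilevelSegment(plant)
  r2 <- multilevelSegment(plant)
  expect_identical(traitTable(r1), traitTable(r2))
  expect_identical(lapply(r1@typicalLeaves, slot, "vertexIds"),
                   lapply(r2@typicalLeaves, slot, "vertexIds"))
  expect_identical(r1@levelsRun, r2@levelsRun)
})

test_that("a persistently atypical cluster terminates within 30 levels", {
  # one normal plate and one much smaller plate: the small one never passes
  # the size band and is re-segmented until the loop floor
  set.seed(2)
  p1 <- gridMesh(seq(0, 20), seq(0, 14))
  p2 <- transformMesh(gridMesh(seq(0, 7), seq(0, 7)), t = c(60, 0, 0))
  V <- rbind(vertices(p1), vertices(p2))
  V <- V + matrix(rnorm(length(V), 0, 0.04), ncol = 3)
  mesh <- TriangleMesh(V, rbind(faces(p1), faces(p2) + nVertices(p1)))
  report <- multilevelSegment(mesh, SegmentationConfig(minClusterVertices = 40L))
  expect_lte(report@levelsRun, 30L)
  expect_gte(report@levelsRun, 2L)
})

test_that("an empty plant mesh is rejected", {
  empty <- TriangleMesh(matrix(numeric(0), 0, 3), matrix(integer(0), 0, 3))
  expect_error(multilevelSegment(empty), "input error")
})
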