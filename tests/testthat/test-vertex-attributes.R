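test_that("a dense planar patch has near-zero curvature and smoothness", {
  plane <- gridMesh(seq(0, 20), seq(0, 20))
  field <- estimateVertexAttributes(plane, 30L)
  inner <- which(plane@vertices[, 1] >= 5 & plane@vertices[, 1] <= 15 &
                 plane@vertices[, 2] >= 5 & plane@vertices[, 2] <= 15)
  expect_lt(max(curvature(field)[inner]), 1e-6)
  expect_lt(max(smoothness(field)[inner]), 0.5)
  expect_lt(max(abs(sqrt(rowSums(normals(field)^2)) - 1)), 1e-6)

  st <- surfaceStats(field)
  expect_lt(st@sigmaSmooth, 0.5)
  expect_lt(st@rhoCurv, 1e-6)
})

test_that("sphere curvature is near-constant and matches a brute-force oracle", {
  sph <- icosphereMesh(4L, radius = 1)        # 2562 vertices
  expect_gte(nVertices(sph), 2000L)
  field <- estimateVertexAttributes(sph, 30L)
  curv <- curvature(field)
  expect_lt(sd(curv) / mean(curv), 0.2)

  # independent oracle: brute-force neighbour scan + eigen-decomposition
  V <- vertices(sph)
  set.seed(7)
  for (i in sample(nrow(V), 25)) {
    d2 <- rowSums(sweep(V, 2, V[i, ])^2)
    nb <- order(d2, seq_len(nrow(V)))[1:30]
    C <- stats::cov(V[nb, , drop = FALSE]) * (29 / 30)  # population covariance
    ev <- eigen(C, symmetric = TRUE)
    expect_equal(curv[i], min(ev$values) / sum(ev$values), tolerance = 1e-8)
    nrm <- ev$vectors[, 3]
    expect_lt(abs(abs(sum(nrm * normals(field)[i, ])) - 1), 1e-8)
  }
})

test_that("curvature and smoothness are invariant under rigid motion", {
  leaf <- generateLeaf(20, 10, bendDeg = 30, resolutionMm = 1.2)$mesh
  # generic position: exact grid meshes have tied nearest-neighbour
  # distances whose resolution order is representation-dependent
  set.seed(6)
  leaf <- TriangleMesh(vertices(leaf) +
                         matrix(rnorm(3 * nVertices(leaf), 0, 0.01), ncol = 3),
                       faces(leaf))
  R <- rotationMatrix(c(1, 2, 3), 0.83)
  moved <- transformMesh(leaf, R, c(100, -50, 30))
  f1 <- estimateVertexAttributes(leaf, 30L)
  f2 <- estimateVertexAttributes(moved, 30L)
  expect_lt(max(abs(curvature(f1) - curvature(f2))), 1e-6)
  expect_lt(max(abs(smoothness(f1) - smoothness(f2))), 1e-6)
})

test_that("surfaceStats is the arithmetic mean and permutation-invariant", {
  N <- matrix(rep(c(0, 0, 1), each = 5), 5, 3)
  f <- new("VertexField", normals = N, curvature = rep(0.1, 5),
           smoothness = rep(10, 5))
  st <- surfaceStats(f)
  expect_equal(st@sigmaSmooth, 10)
  expect_equal(st@rhoCurv, 0.1)

  set.seed(3)
  sm <- runif(5, 0, 20); cv <- runif(5, 0, 0.3)
  perm <- sample(5)
  f1 <- new("VertexField", normals = N, curvature = cv, smoothness = sm)
  f2 <- new("VertexField", normals = N[perm, ], curvature = cv[perm],
            smoothness = sm[perm])
  expect_equal(surfaceStats(f1)@sigmaSmooth, surfaceStats(f2)@sigmaSmooth)
  expect_equal(surfaceStats(f1)@rhoCurv, surfaceStats(f2)@rhoCurv)
})

test_that("too-small meshes and empty fields raise input errors", {
  tri <- TriangleMesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)), rbind(1:3))
  expect_error(estimateVertexAttributes(tri, 30L), "input error")
  empty <- new("VertexField", normals = matrix(numeric(0), 0, 3),
               curvature = numeric(0), smoothness = numeric(0))
  expect_error(surfaceStats(empty), "input error")
})
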