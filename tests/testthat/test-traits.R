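test_that("area and perimeter are exact on the unit square", {
  sq <- TriangleMesh(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)),
                     rbind(c(1, 2, 3), c(1, 3, 4)))
  expect_equal(leafArea(sq), 1.0)
  expect_equal(leafPerimeter(sq), 4.0)
})

test_that("area scales quadratically and perimeter linearly", {
  leaf <- generateLeaf(20, 10, 0, 1.5)$mesh
  big <- TriangleMesh(leaf@vertices * 2, leaf@faces)
  expect_equal(leafArea(big), 4 * leafArea(leaf), tolerance = 1e-9)
  expect_equal(leafPerimeter(big), 2 * leafPerimeter(leaf), tolerance = 1e-9)
})

test_that("disc area and perimeter converge to the analytic values", {
  disc <- discMesh(10, 512, 32)
  expect_lt(abs(leafArea(disc) - pi * 100) / (pi * 100), 0.01)
  expect_lt(abs(leafPerimeter(disc) - 2 * pi * 10) / (2 * pi * 10), 0.01)
  # refinement reduces the area error
  coarse <- discMesh(10, 64, 8)
  expect_gt(abs(leafArea(coarse) - pi * 100),
            abs(leafArea(disc) - pi * 100))
})

test_that("perimeter equals the brute-force boundary-edge sum", {
  set.seed(11)
  base <- gridMesh(seq(0, 8), seq(0, 6))
  for (rep in 1:3) {
    keep <- sort(sample(nFaces(base), 55))
    sub <- TriangleMesh(base@vertices, base@faces[keep, , drop = FALSE])
    bkeys <- bruteBoundaryEdges(sub)
    ab <- do.call(rbind, strsplit(bkeys, " "))
    a <- as.integer(ab[, 1]); b <- as.integer(ab[, 2])
    oracle <- sum(sqrt(rowSums((sub@vertices[a, , drop = FALSE] -
                                sub@vertices[b, , drop = FALSE])^2)))
    expect_equal(leafPerimeter(sub), oracle, tolerance = 1e-12)
  }
})

test_that("closed surfaces raise a no-boundary error", {
  expect_error(leafPerimeter(icosahedronMesh()), "no boundary")
})

test_that("geodesic length of a flat strip is the strip length", {
  rect <- rectangleStrip(50, 10, 1)
  len <- leafLength(rect)
  expect_lte(abs(len - 50), 1.0)   # within one edge length
})

test_that("geodesic length follows the surface of a bent strip", {
  bent <- bentStrip(R = 20, angle = pi, W = 10, h = 1)
  len <- leafLength(bent)
  arc <- pi * 20
  expect_lt(abs(len - arc) / arc, 0.02)
  # a genuine geodesic, not the 3D chord between the ends
  expect_gt(len, 1.5 * sqrt(100 + (2 * 20)^2))
})

test_that("length is at least the Euclidean distance of its endpoints", {
  for (mesh in list(rectangleStrip(30, 8, 1), bentStrip(15, 2, 8, 1),
                    generateLeaf(20, 10, 25, 1.2)$mesh)) {
    det <- leafLength(mesh, detail = TRUE)
    euclid <- sqrt(sum((mesh@vertices[det$endpoints[1], ] -
                        mesh@vertices[det$endpoints[2], ])^2))
    expect_gte(det$length + 1e-9, euclid)
  }
})

test_that("length is monotone in the endpoint-candidate quantile", {
  leaf <- generateLeaf(25, 14, 10, 1.2)$mesh
  l1 <- leafLength(leaf, q = 0.02)
  l2 <- leafLength(leaf, q = 0.05)
  l3 <- leafLength(leaf, q = 0.10)
  expect_lte(l1, l2 + 1e-9)
  expect_lte(l2, l3 + 1e-9)
})

test_that("width recovers the rectangle width and the ellipse minor axis", {
  rect <- rectangleStrip(50, 10, 1)
  det <- leafLength(rect, detail = TRUE)
  expect_lt(abs(leafWidth(rect, det$points) - 10) / 10, 0.02)

  leaf <- generateLeaf(30, 20, 0, 1)$mesh
  det2 <- leafLength(leaf, detail = TRUE)
  expect_lt(abs(leafWidth(leaf, det2$points) - 40) / 40, 0.02)
})

test_that("the full trait vector is computed with consistent ratios", {
  tv <- LeafTraits(100, 50, 10, 5)
  v <- traits(tv)
  expect_equal(unname(v[c("x11", "x12", "x13", "x14", "x15", "x16")]),
               c(2, 10, 20, 5, 10, 2))

  leaf <- generateLeaf(30, 20, 0, 1)$mesh
  mv <- traits(traitVector(leaf))
  expect_lt(abs(mv[["s"]] - pi * 600) / (pi * 600), 0.02)
  expect_lte(mv[["w"]], mv[["l"]])
})

test_that("ratio traits are dimensionless or scale linearly as expected", {
  leaf <- generateLeaf(20, 12, 15, 1.2)$mesh
  tv1 <- traits(traitVector(leaf))
  tv2 <- traits(traitVector(TriangleMesh(leaf@vertices * 2, leaf@faces)))
  expect_equal(tv2[["x16"]], tv1[["x16"]], tolerance = 1e-6)
  expect_equal(tv2[["s"]], 4 * tv1[["s"]], tolerance = 1e-6)
  expect_equal(tv2[["c"]], 2 * tv1[["c"]], tolerance = 1e-4)
  expect_equal(tv2[["l"]], 2 * tv1[["l"]], tolerance = 1e-3)
})

test_that("scale traits are invariant under rigid motion", {
  leaf <- generateLeaf(20, 12, 15, 1.2)$mesh
  moved <- transformMesh(leaf, rotationMatrix(c(2, -1, 4), 1.1),
                         c(-30, 90, 12))
  t1 <- traits(traitVector(leaf))
  t2 <- traits(traitVector(moved))
  for (nm in c("s", "c", "l", "w"))
    expect_equal(t2[[nm]], t1[[nm]], tolerance = 1e-6)
})

test_that("generator leaves are recovered with small per-trait error", {
  set.seed(21)
  for (k in 1:3) {
    a <- runif(1, 22, 32); b <- runif(1, 0.55, 0.68) * a
    leaf <- generateLeaf(a, b, 0, 1)
    mv <- traits(traitVector(leaf$mesh))
    tv <- traits(leaf$traits)
    for (nm in c("s", "c", "l", "w"))
      expect_lt(abs(mv[[nm]] - tv[[nm]]) / tv[[nm]], 0.03)
  }
})

test_that("degenerate inputs raise the documented errors", {
  degen <- TriangleMesh(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)), rbind(1:3))
  expect_error(leafArea(degen), "zero-area")

  two <- TriangleMesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
                            c(10, 10, 0), c(11, 10, 0), c(10, 11, 0)),
                      rbind(c(1, 2, 3), c(4, 5, 6)))
  expect_error(leafLength(two), "disconnected")
})
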