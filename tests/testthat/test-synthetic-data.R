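test_that("flat leaf ground truth matches the analytic ellipse", {
  leaf <- generateLeaf(30, 20, bendDeg = 0, resolutionMm = 1)
  tv <- traits(leaf$traits)
  expect_lt(abs(tv[["s"]] - pi * 600) / (pi * 600), 0.01)
  expect_lt(abs(tv[["l"]] - 60) / 60, 0.01)
  expect_lt(abs(tv[["w"]] - 40) / 40, 0.01)
  # Ramanujan's approximation for the ellipse circumference
  h <- ((30 - 20) / (30 + 20))^2
  circ <- pi * (30 + 20) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
  expect_lt(abs(tv[["c"]] - circ) / circ, 0.01)
})

test_that("bending preserves the midrib arc and exceeds the chord", {
  leaf <- generateLeaf(30, 20, bendDeg = 90, resolutionMm = 1)
  tv <- traits(leaf$traits)
  expect_lt(abs(tv[["l"]] - 60) / 60, 0.01)        # arc length preserved
  mid <- vertices(leaf$mesh)[leaf$midrib, ]
  chord <- sqrt(sum((mid[nrow(mid), ] - mid[1, ])^2))
  expect_gt(tv[["l"]], chord)
})

test_that("too-coarse resolutions are refused", {
  expect_error(generateLeaf(30, 20, 0, resolutionMm = 6), "resolution error")
})

test_that("the same spec yields byte-identical scenes", {
  spec <- PlantSceneSpec(nLeaves = 4, occlusionLevel = "little", rngSeed = 8)
  s1 <- generatePlantScene(spec)
  s2 <- generatePlantScene(spec)
  expect_identical(vertices(s1$mesh), vertices(s2$mesh))
  expect_identical(faces(s1$mesh), faces(s2$mesh))
  p1 <- withr::local_tempfile(fileext = ".ply")
  p2 <- withr::local_tempfile(fileext = ".ply")
  writeMesh(s1$mesh, p1); writeMesh(s2$mesh, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("a non-occluded scene has disjoint leaves and full counts", {
  scene <- generatePlantScene(PlantSceneSpec(nLeaves = 6,
                                             occlusionLevel = "none",
                                             dropoutFraction = 0,
                                             rngSeed = 7))
  expect_equal(scene$ledger$counts$n0, 6L)
  expect_equal(scene$ledger$counts$n1, 6L)
  # pairwise projected bounding boxes do not overlap
  boxes <- lapply(scene$ledger$leaves, function(e) {
    XY <- vertices(scene$mesh)[unlist(e$vertex_ids), 1:2, drop = FALSE]
    apply(XY, 2, range)
  })
  for (i in 1:5) for (j in (i + 1):6) {
    bi <- boxes[[i]]; bj <- boxes[[j]]
    disjoint <- bi[2, 1] < bj[1, 1] || bj[2, 1] < bi[1, 1] ||
      bi[2, 2] < bj[1, 2] || bj[2, 2] < bi[1, 2]
    expect_true(disjoint)
  }
  # ledger face sets are disjoint
  all_faces <- unlist(lapply(scene$ledger$leaves, `[[`, "face_ids"))
  expect_identical(anyDuplicated(all_faces), 0L)
})

test_that("heavier occlusion targets produce more projected overlap", {
  none <- generatePlantScene(PlantSceneSpec(nLeaves = 8,
                                            occlusionLevel = "none",
                                            rngSeed = 5))
  heavy <- generatePlantScene(PlantSceneSpec(nLeaves = 8,
                                             occlusionLevel = "heavy",
                                             rngSeed = 5))
  expect_equal(none$ledger$occlusion$achieved, 0)
  expect_gt(heavy$ledger$occlusion$achieved,
            none$ledger$occlusion$achieved)
  expect_lt(abs(heavy$ledger$occlusion$achieved - 0.30), 0.06)
  # shadowing removes data from covered leaves
  expect_gt(max(vapply(heavy$ledger$leaves, `[[`, 0, "shadow_fraction")), 0)
  expect_lte(heavy$ledger$counts$n2, heavy$ledger$counts$n1)
})

test_that("dropout deletes leaf faces and flags damaged leaves", {
  clean <- generatePlantScene(PlantSceneSpec(nLeaves = 6, rngSeed = 31))
  dropped <- generatePlantScene(PlantSceneSpec(nLeaves = 6,
                                               dropoutFraction = 0.2,
                                               rngSeed = 31))
  nf <- function(s) length(unlist(lapply(s$ledger$leaves, `[[`, "face_ids")))
  removed <- 1 - nf(dropped) / nf(clean)
  expect_gt(removed, 0.1)
  expect_lt(removed, 0.3)
  damaged <- vapply(dropped$ledger$leaves, `[[`, TRUE, "damaged")
  expect_gt(sum(damaged), 0)
  expect_equal(dropped$ledger$counts$n1, sum(!damaged))
})

test_that("table, pot and petiole stubs all stay below the buffer", {
  scene <- generatePlantScene(PlantSceneSpec(nLeaves = 5, rngSeed = 3))
  lab <- scene$ledger$face_labels
  clutter <- lab %in% c("table", "pot", "stem")
  vids <- unique(as.vector(faces(scene$mesh)[clutter, ]))
  expect_lt(max(vertices(scene$mesh)[vids, 3]), 100)
  leaf_v <- unique(as.vector(faces(scene$mesh)[!clutter, ]))
  expect_gt(min(vertices(scene$mesh)[leaf_v, 3]), 100)
})

test_that("ledgers round-trip through JSON", {
  scene <- generatePlantScene(PlantSceneSpec(nLeaves = 3, rngSeed = 2))
  path <- withr::local_tempfile(fileext = ".json")
  writeLedger(scene$ledger, path)
  back <- readLedger(path)
  expect_equal(back$counts$n0, scene$ledger$counts$n0)
  expect_equal(length(back$leaves), length(scene$ledger$leaves))
  expect_equal(unlist(back$leaves[[1]]$traits),
               unname(scene$ledger$leaves[[1]]$traits), tolerance = 1e-12)
})
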