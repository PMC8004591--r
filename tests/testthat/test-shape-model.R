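ratio_names <- c("x11", "x12", "x13", "x14", "x15", "x16")

# random but valid trait tables (ratio columns need not be geometric here;
# the fitting operates on the columns as given)
randomTraitTable <- function(n, seed) {
  set.seed(seed)
  M <- as.data.frame(matrix(runif(n * 10, 1, 100), n, 10))
  names(M) <- c("s", "c", "l", "w", ratio_names)
  M
}

test_that("weights match a brute-force eigen-decomposition oracle", {
  for (seed in c(1, 2, 3)) {
    M <- randomTraitTable(10, seed)
    model <- fitShapeModel(M)
    oracle_a <- sort(eigen(cor(as.matrix(M[, 1:4])))$values, decreasing = TRUE)
    oracle_a <- oracle_a / sum(oracle_a)
    oracle_b <- sort(eigen(cor(as.matrix(M[, 5:10])))$values,
                     decreasing = TRUE)
    oracle_b <- oracle_b / sum(oracle_b)
    expect_equal(model@a, oracle_a, tolerance = 1e-8)
    expect_equal(model@b, oracle_b, tolerance = 1e-8)
    expect_equal(sum(model@a), 1, tolerance = 1e-9)
    expect_equal(sum(model@b), 1, tolerance = 1e-9)
    expect_true(all(model@a >= -1e-12) && all(model@b >= -1e-12))
  }
})

test_that("a 3+1 correlated block yields the (0.75, 0.25, 0, 0) spectrum", {
  set.seed(4)
  x1 <- runif(12, 10, 20)
  z <- runif(12, 5, 15)
  x2 <- resid(lm(z ~ x1)) + 30          # exactly uncorrelated with x1
  M <- data.frame(s = x1, c = x2, l = 2 * x1, w = x1 + 5)
  M[ratio_names] <- replicate(6, runif(12, 1, 2), simplify = FALSE)
  model <- fitShapeModel(M)
  expect_equal(model@a, c(0.75, 0.25, 0, 0), tolerance = 1e-8)
})

test_that("identical rows fall back to equal weights", {
  row <- traitRowsFromScales(rep(1, 6))
  model <- fitShapeModel(row)
  expect_equal(model@a, rep(1 / 4, 4))
  expect_equal(model@b, rep(1 / 6, 6))
  expect_true(model@weightsFallback)
  expect_false(model@degenerate)        # means are defined; bands still apply
})

test_that("fewer than five rows also fall back to equal weights", {
  model <- fitShapeModel(randomTraitTable(4, 9))
  expect_equal(model@a, rep(1 / 4, 4))
  expect_true(model@weightsFallback)
})

test_that("non-positive traits are rejected", {
  M <- randomTraitTable(6, 5)
  M$s[2] <- -1
  expect_error(fitShapeModel(M), "non-positive")
})

test_that("the size score evaluates the weighted relative deviation", {
  model <- new("ShapeModel", a = c(0.5, 0.3, 0.1, 0.1), b = rep(1 / 6, 6),
               meanScale = c(100, 50, 10, 5), meanG = 10,
               band = c(0.25, 1.25), nFit = 10L, degenerate = FALSE,
               weightsFallback = FALSE)
  expect_equal(scoreF(LeafTraits(110, 45, 10, 5), model), 0.02,
               tolerance = 1e-12)
  expect_equal(scoreF(LeafTraits(100, 50, 10, 5), model), 0)
  expect_equal(scoreF(LeafTraits(200, 100, 20, 10), model), 1,
               tolerance = 1e-12)
})

test_that("the size score is invariant under a common change of units", {
  model <- new("ShapeModel", a = c(0.4, 0.3, 0.2, 0.1), b = rep(1 / 6, 6),
               meanScale = c(2000, 170, 65, 41), meanG = 10,
               band = c(0.25, 1.25), nFit = 8L, degenerate = FALSE,
               weightsFallback = FALSE)
  tv <- LeafTraits(2500, 150, 70, 39)
  f1 <- scoreF(tv, model)
  k <- 0.1                               # e.g. mm -> cm on every trait
  model2 <- model
  model2@meanScale <- model@meanScale * k
  tv2 <- LeafTraits(2500 * k, 150 * k, 70 * k, 39 * k)
  expect_equal(scoreF(tv2, model2), f1, tolerance = 1e-12)
})

test_that("the architecture score is the weighted ratio sum", {
  mk <- function(b) new("ShapeModel", a = rep(1 / 4, 4), b = b,
                        meanScale = c(1, 1, 1, 1), meanG = 1,
                        band = c(0.25, 1.25), nFit = 10L,
                        degenerate = FALSE, weightsFallback = FALSE)
  tv <- LeafTraits(12, 6, 2, 1)          # ratios: 2, 6, 12, 3, 6, 2
  expect_equal(scoreG(tv, mk(c(1, 0, 0, 0, 0, 0))), 2)
  b <- c(0.4, 0.3, 0.1, 0.1, 0.05, 0.05)
  tv2 <- LeafTraits(20, 10, 2, 1)
  v <- traits(tv2)[5:10]
  expect_equal(scoreG(tv2, mk(b)), sum(b * v), tolerance = 1e-12)
  # hand-evaluated example with explicit ratios
  expect_equal(sum(b * c(2, 10, 20, 5, 10, 2)), 6.9)
})

test_that("detection accepts the mean leaf and rejects size/shape outliers", {
  rows <- traitRowsFromScales(c(0.97, 0.99, 1, 1, 1.01, 1.03))
  model <- fitShapeModel(rows)
  mean_leaf <- LeafTraits(mean(rows$s), mean(rows$c), mean(rows$l),
                          mean(rows$w))
  det <- detectTypical(mean_leaf, model)
  expect_true(det@isTypical)
  expect_identical(det@reason, "pass")

  small <- LeafTraits(mean(rows$s) * 0.1, mean(rows$c) * 0.1,
                      mean(rows$l) * 0.1, mean(rows$w) * 0.1)
  det2 <- detectTypical(small, model)
  expect_false(det2@isTypical)
  expect_identical(det2@reason, "size_out_of_band")
  expect_lt(1 + det2@fScore, 0.25)

  # same area but a much shorter, narrower outline: the size test still
  # passes (weighted deviation moderate) but G leaves the shape band
  model_eq <- fitShapeModel(traitRowsFromScales(rep(1, 6)))
  distorted <- LeafTraits(2000, 170, 40, 25)
  expect_gt(scoreG(distorted, model_eq), 1.25 * model_eq@meanG)
  res <- detectTypical(distorted, model_eq)
  expect_false(res@isTypical)
  expect_identical(res@reason, "shape_out_of_band")
})

test_that("a single-cluster model is degenerate and accepts everything", {
  model <- fitShapeModel(traitRowsFromScales(1))
  expect_true(model@degenerate)
  det <- detectTypical(LeafTraits(1, 1, 1, 1), model)
  expect_true(det@isTypical)
  expect_identical(det@reason, "degenerate_model")
})

test_that("every fitting row within 20 percent of the means is accepted", {
  set.seed(31)
  for (rep in 1:5) {
    n <- sample(5:12, 1)
    base <- c(2000, 170, 65, 41)
    rows <- lapply(seq_len(n), function(i) {
      sc <- base * (1 + runif(4, -0.08, 0.08))
      LeafTraits(sc[1], sc[2], sc[3], sc[4])
    })
    M <- do.call(rbind, lapply(rows, function(r) r@values))
    # premise: every trait of every row within 20% of the column means
    devs <- abs(sweep(M, 2, colMeans(M), `/`) - 1)
    expect_lt(max(devs), 0.20)
    model <- fitShapeModel(as.data.frame(M))
    for (r in rows) {
      det <- detectTypical(r, model)
      expect_true(det@isTypical)
    }
  }
})

test_that("shape models serialize to JSON and back", {
  model <- fitShapeModel(randomTraitTable(8, 12))
  path <- withr::local_tempfile(fileext = ".json")
  writeShapeModel(model, path)
  back <- readShapeModel(path)
  expect_equal(back@a, model@a, tolerance = 1e-12)
  expect_equal(back@b, model@b, tolerance = 1e-12)
  expect_equal(back@meanScale, unname(model@meanScale), tolerance = 1e-12)
  expect_equal(back@meanG, model@meanG, tolerance = 1e-12)
  expect_identical(back@nFit, model@nFit)
})
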