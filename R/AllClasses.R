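#' @import methods
NULL

#' Triangle mesh in millimetre coordinates
#'
#' The universal geometry carrier of the package: a vertex matrix and a face
#' matrix. Faces index vertices 1-based (the R convention; PLY/OBJ files use
#' their native 0-/1-based indexing and are converted on read/write). The
#' optional \code{vertexIndex} slot records, for meshes derived from a larger
#' mesh (e.g. after non-plant removal), the index of each vertex in the
#' parent mesh; it is empty for meshes read from files.
#'
#' @slot vertices numeric matrix, n x 3, coordinates in mm.
#' @slot faces integer matrix, m x 3, 1-based vertex indices.
#' @slot vertexIndex integer vector of parent-mesh vertex indices, or
#'   \code{integer(0)}.
#' @export
setClass("TriangleMesh",
  representation(vertices = "matrix", faces = "matrix",
                 vertexIndex = "integer"),
  prototype(vertices = matrix(numeric(0), 0, 3),
            faces = matrix(integer(0), 0, 3),
            vertexIndex = integer(0)))

setValidity("TriangleMesh", function(object) {
  v <- object@vertices
  f <- object@faces
  if (ncol(v) != 3L) return("vertices must have 3 columns")
  if (ncol(f) != 3L) return("faces must have 3 columns")
  if (!is.numeric(v)) return("vertices must be numeric")
  if (nrow(f) > 0) {
    if (!is.numeric(f)) return("faces must be integer-valued")
    if (any(f != round(f))) return("face indices must be whole numbers")
    if (min(f) < 1L || max(f) > nrow(v))
      return(sprintf("face index out of range [1, %d]", nrow(v)))
    if (any(f[, 1] == f[, 2] | f[, 1] == f[, 3] | f[, 2] == f[, 3]))
      return("degenerate face (repeated vertex index)")
  }
  if (length(object@vertexIndex) > 0 &&
      length(object@vertexIndex) != nrow(v))
    return("vertexIndex must have one entry per vertex")
  TRUE
})

#' Per-vertex differential attributes
#'
#' Unit normals, surface-variation curvature (lambda_min / sum(lambda) of the
#' local covariance, in [0, 1/3]) and smoothness (mean unsigned angle in
#' degrees between a vertex normal and the normals of its edge-adjacent
#' vertices).
#'
#' @slot normals numeric matrix, n x 3, unit rows.
#' @slot curvature numeric vector, n.
#' @slot smoothness numeric vector, n, degrees.
#' @export
setClass("VertexField",
  representation(normals = "matrix", curvature = "numeric",
                 smoothness = "numeric"))

setValidity("VertexField", function(object) {
  n <- nrow(object@normals)
  if (length(object@curvature) != n || length(object@smoothness) != n)
    return("curvature and smoothness must match the number of normals")
  if (n > 0) {
    len <- sqrt(rowSums(object@normals^2))
    if (any(abs(len - 1) > 1e-6)) return("normals must be unit length")
    if (any(object@curvature < -1e-12 | object@curvature > 1 / 3 + 1e-9))
      return("curvature must lie in [0, 1/3]")
    if (any(object@smoothness < -1e-9 | object@smoothness > 180 + 1e-9))
      return("smoothness must lie in [0, 180] degrees")
  }
  TRUE
})

#' Mesh-level smoothness and curvature averages
#'
#' The two adaptive scale parameters of the segmentation: sigma (mean
#' smoothness, degrees) and rho (mean curvature). Region-growing thresholds
#' are multiples of these.
#'
#' @slot sigmaSmooth numeric, mean smoothness in degrees.
#' @slot rhoCurv numeric, mean surface-variation curvature.
#' @export
setClass("SurfaceStats",
  representation(sigmaSmooth = "numeric", rhoCurv = "numeric"))

setValidity("SurfaceStats", function(object) {
  if (object@sigmaSmooth < 0 || object@sigmaSmooth > 180)
    return("sigmaSmooth must lie in [0, 180]")
  if (object@rhoCurv < 0) return("rhoCurv must be non-negative")
  TRUE
})

#' Fitted table plane
#'
#' @slot normal unit 3-vector.
#' @slot offset scalar (mm); the plane is {p : normal . p = offset}.
#' @slot inlierCount integer, RANSAC consensus size.
#' @export
setClass("PlaneModel",
  representation(normal = "numeric", offset = "numeric",
                 inlierCount = "integer"))

setValidity("PlaneModel", function(object) {
  if (length(object@normal) != 3 || abs(sqrt(sum(object@normal^2)) - 1) > 1e-6)
    return("normal must be a unit 3-vector")
  if (object@inlierCount < 3L) return("inlierCount must be >= 3")
  TRUE
})

#' Non-plant removal configuration
#'
#' @slot epsilonMm buffer above the table plane (mm); faces entirely below it
#'   are removed. Default 100 mm.
#' @slot ransacIterations number of random 3-vertex samples. Default 1000.
#' @slot ransacInlierTolMm inlier distance tolerance (mm). Default 2.
#' @slot minPlaneFraction minimum inlier fraction for a plane to count as
#'   dominant. Default 0.05.
#' @slot rngSeed integer seed for the RANSAC sampling.
#' @export
setClass("PreprocessConfig",
  representation(epsilonMm = "numeric", ransacIterations = "integer",
                 ransacInlierTolMm = "numeric", minPlaneFraction = "numeric",
                 rngSeed = "integer"),
  prototype(epsilonMm = 100, ransacIterations = 1000L,
            ransacInlierTolMm = 2.0, minPlaneFraction = 0.05,
            rngSeed = 1L))

setValidity("PreprocessConfig", function(object) {
  if (object@epsilonMm <= 0) return("epsilonMm must be positive")
  if (object@ransacInlierTolMm <= 0) return("ransacInlierTolMm must be positive")
  if (object@ransacIterations < 1L) return("ransacIterations must be >= 1")
  if (object@minPlaneFraction <= 0 || object@minPlaneFraction > 1)
    return("minPlaneFraction must be in (0, 1]")
  TRUE
})

#' Ten morphological traits of a leaf
#'
#' Four scale-related traits (area s, perimeter c, length l, width w) and the
#' six ratio traits x11 = s/c, x12 = s/l, x13 = s/w, x14 = c/l, x15 = c/w,
#' x16 = l/w. Ratios are always derived from the stored scale traits.
#'
#' @slot values named numeric vector with names
#'   \code{c("s","c","l","w","x11","x12","x13","x14","x15","x16")}.
#' @export
setClass("LeafTraits", representation(values = "numeric"))

.trait_names <- c("s", "c", "l", "w", "x11", "x12", "x13", "x14", "x15", "x16")

setValidity("LeafTraits", function(object) {
  v <- object@values
  if (!identical(names(v), .trait_names))
    return("values must be named s, c, l, w, x11..x16")
  if (any(!is.finite(v)) || any(v <= 0))
    return("all ten traits must be finite and strictly positive")
  ratios <- c(v["s"] / v["c"], v["s"] / v["l"], v["s"] / v["w"],
              v["c"] / v["l"], v["c"] / v["w"], v["l"] / v["w"])
  if (any(abs(v[5:10] - ratios) > 1e-9 * abs(ratios)))
    return("ratio traits must equal their defining quotients")
  TRUE
})

#' A segmented leaf candidate
#'
#' @slot submesh the cluster's \linkS4class{TriangleMesh}.
#' @slot vertexIds indices of the cluster vertices in the parent plant mesh.
#' @slot traits a \linkS4class{LeafTraits}, or NULL if traits could not be
#'   computed.
#' @slot reason character; "pass" for typical leaves, otherwise why the
#'   cluster was set aside.
#' @export
setClass("LeafCluster",
  representation(submesh = "TriangleMesh", vertexIds = "integer",
                 traits = "ANY", reason = "character"),
  prototype(traits = NULL, reason = "pass"))

setValidity("LeafCluster", function(object) {
  if (anyDuplicated(object@vertexIds)) return("vertexIds must be unique")
  TRUE
})

#' PCA-weighted leaf shape models
#'
#' The size model F(X) = sum_i a_i (X0i - mean_i)/mean_i over the four scale
#' traits and the architecture model G(X) = sum_j b_j X1j over the six ratio
#' traits. Weights are the variance contribution rates (normalized eigenvalue
#' spectrum) of a PCA on the correlation-scaled fitting traits; with fewer
#' than 5 fitting clusters, or zero variance, equal weights are used. A model
#' fit on fewer than 2 clusters is degenerate and accepts everything.
#'
#' @slot a numeric length-4 weights for the scale traits, sum 1.
#' @slot b numeric length-6 weights for the ratio traits, sum 1.
#' @slot meanScale named numeric length-4, trait means of the fitting rows.
#' @slot meanG mean of G over the fitting rows.
#' @slot band numeric length-2, the acceptance band (0.25, 1.25).
#' @slot nFit number of fitting clusters.
#' @slot degenerate logical; TRUE when no filtering is possible (fewer than
#'   2 fitting clusters): detection accepts everything.
#' @slot weightsFallback logical; TRUE when equal weights were used instead
#'   of the PCA spectrum (fewer than 5 clusters, or zero trait variance).
#'   The acceptance bands still apply.
#' @export
setClass("ShapeModel",
  representation(a = "numeric", b = "numeric", meanScale = "numeric",
                 meanG = "numeric", band = "numeric", nFit = "integer",
                 degenerate = "logical", weightsFallback = "logical"),
  prototype(band = c(0.25, 1.25), degenerate = FALSE,
            weightsFallback = FALSE))

setValidity("ShapeModel", function(object) {
  if (length(object@a) != 4 || abs(sum(object@a) - 1) > 1e-9)
    return("a must be 4 weights summing to 1")
  if (length(object@b) != 6 || abs(sum(object@b) - 1) > 1e-9)
    return("b must be 6 weights summing to 1")
  if (any(object@a < -1e-12) || any(object@b < -1e-12))
    return("weights must be non-negative")
  if (length(object@meanScale) != 4 || any(object@meanScale <= 0))
    return("meanScale must be 4 strictly positive means")
  if (length(object@band) != 2 || object@band[1] >= object@band[2])
    return("band must be (low, high) with low < high")
  TRUE
})

#' Outcome of the typical-leaf test
#'
#' @slot fScore the size score F(X).
#' @slot gScore the architecture score G(X).
#' @slot isTypical logical.
#' @slot reason one of "pass", "size_out_of_band", "shape_out_of_band",
#'   "degenerate_model".
#' @export
setClass("DetectionResult",
  representation(fScore = "numeric", gScore = "numeric",
                 isTypical = "logical", reason = "character"))

setValidity("DetectionResult", function(object) {
  ok <- c("pass", "size_out_of_band", "shape_out_of_band", "degenerate_model")
  if (!object@reason %in% ok) return("unknown reason")
  if (object@isTypical && !object@reason %in% c("pass", "degenerate_model"))
    return("a typical result must have reason pass or degenerate_model")
  TRUE
})

#' Multi-level segmentation configuration
#'
#' Thresholds at level t are eps_a = m_t * sigma and eps_b = m_t * rho with
#' m_t = initMultiplier - multiplierStep * (t - 1); the loop stops when every
#' cluster passes detection, when either threshold falls to epsilonFloor, or
#' when m_t reaches zero (at most 30 levels with the defaults).
#'
#' @slot nP neighbourhood size for vertex attributes. Default 30.
#' @slot initMultiplier initial threshold multiplier. Default 1.5.
#' @slot multiplierStep per-level decrement. Default 0.05.
#' @slot epsilonFloor lower bound on eps_a and eps_b. Default 1e-4.
#' @slot minClusterVertices clusters below this size are discarded. Default 50.
#' @slot qEndpoint boundary-projection quantile for length endpoints.
#'   Default 0.05.
#' @slot kWidthSlices number of width stations along the length path.
#'   Default 20.
#' @export
setClass("SegmentationConfig",
  representation(nP = "integer", initMultiplier = "numeric",
                 multiplierStep = "numeric", epsilonFloor = "numeric",
                 minClusterVertices = "integer", qEndpoint = "numeric",
                 kWidthSlices = "integer"),
  prototype(nP = 30L, initMultiplier = 1.5, multiplierStep = 0.05,
            epsilonFloor = 1e-4, minClusterVertices = 50L,
            qEndpoint = 0.05, kWidthSlices = 20L))

setValidity("SegmentationConfig", function(object) {
  if (object@initMultiplier <= 0) return("initMultiplier must be positive")
  if (object@multiplierStep <= 0 ||
      object@multiplierStep >= object@initMultiplier)
    return("multiplierStep must lie in (0, initMultiplier)")
  if (object@epsilonFloor <= 0) return("epsilonFloor must be positive")
  if (object@nP < 3L) return("nP must be >= 3")
  if (object@qEndpoint <= 0 || object@qEndpoint >= 0.5)
    return("qEndpoint must be in (0, 0.5)")
  if (object@kWidthSlices < 1L) return("kWidthSlices must be >= 1")
  TRUE
})

#' Result of multi-level segmentation
#'
#' @slot typicalLeaves list of \linkS4class{LeafCluster} that passed the
#'   final shape-model detection.
#' @slot rejected list of \linkS4class{LeafCluster} set aside, with reasons.
#' @slot levelsRun number of region-growing levels executed.
#' @slot finalModel the \linkS4class{ShapeModel} fitted on all accepted
#'   clusters (or NULL when nothing was accepted).
#' @slot levelLog data.frame with one row per level: multiplier, eps_a,
#'   eps_b, clusters, accepted, residual vertex count.
#' @slot surfaceStats the \linkS4class{SurfaceStats} the thresholds scale on.
#' @export
setClass("SegmentationReport",
  representation(typicalLeaves = "list", rejected = "list",
                 levelsRun = "integer", finalModel = "ANY",
                 levelLog = "data.frame", surfaceStats = "ANY"),
  prototype(finalModel = NULL, surfaceStats = NULL))

#' Synthetic plant-scene specification
#'
#' Describes a scanner-like scene: a table plane at z = 0, a pot below the
#' 100 mm preprocessing buffer, short petiole stubs (petioles scan poorly and
#' are generated only below the buffer), and broad elliptical leaves placed
#' on a phyllotactic spiral. Occlusion levels map to target mean projected
#' leaf-overlap fractions none/little/medium/heavy = 0/0.05/0.15/0.30;
#' overlapping leaves that come into contact are welded vertex-to-vertex,
#' emulating the fused surfaces of attached leaves in real scans.
#'
#' @slot nLeaves number of mature leaves.
#' @slot leafSemiAxesMm mean semi-axes (a, b) of the leaf ellipse, mm.
#' @slot leafSizeCv coefficient of variation of leaf size.
#' @slot leafBendDeg total bend of the leaf about its midrib chord, degrees.
#' @slot occlusionLevel one of "none", "little", "medium", "heavy".
#' @slot nNewborn number of small curled newborn leaves (non-typical).
#' @slot newbornScale linear size of a newborn relative to the mean leaf.
#' @slot dropoutFraction fraction of leaf faces deleted as connected shadow
#'   patches (damaged leaves are non-typical). In [0, 0.5].
#' @slot tableSizeMm side length of the square table patch.
#' @slot potHeightMm pot height; must stay below 100 mm.
#' @slot meshResolutionMm target vertex spacing on leaves.
#' @slot vertexNoiseMm sd of isotropic Gaussian scanner jitter applied to
#'   every scene vertex (mm).
#' @slot rngSeed integer seed; the whole scene is a deterministic function
#'   of the spec.
#' @export
setClass("PlantSceneSpec",
  representation(nLeaves = "integer", leafSemiAxesMm = "numeric",
                 leafSizeCv = "numeric", leafBendDeg = "numeric",
                 occlusionLevel = "character", nNewborn = "integer",
                 newbornScale = "numeric", dropoutFraction = "numeric",
                 tableSizeMm = "numeric", potHeightMm = "numeric",
                 meshResolutionMm = "numeric", vertexNoiseMm = "numeric",
                 rngSeed = "integer"),
  prototype(nLeaves = 6L, leafSemiAxesMm = c(32.5, 20.5), leafSizeCv = 0.08,
            leafBendDeg = 20, occlusionLevel = "none", nNewborn = 0L,
            newbornScale = 0.15, dropoutFraction = 0, tableSizeMm = 400,
            potHeightMm = 80, meshResolutionMm = 1.5, vertexNoiseMm = 0.05,
            rngSeed = 1L))

setValidity("PlantSceneSpec", function(object) {
  if (object@nLeaves < 1L) return("nLeaves must be >= 1")
  if (length(object@leafSemiAxesMm) != 2 ||
      object@leafSemiAxesMm[1] < object@leafSemiAxesMm[2] ||
      object@leafSemiAxesMm[2] <= 0)
    return("leafSemiAxesMm must be (a, b) with a >= b > 0")
  if (!object@occlusionLevel %in% c("none", "little", "medium", "heavy"))
    return("occlusionLevel must be none/little/medium/heavy")
  if (object@dropoutFraction < 0 || object@dropoutFraction > 0.5)
    return("dropoutFraction must be in [0, 0.5]")
  if (object@potHeightMm >= 100)
    return("potHeightMm must stay below the 100 mm buffer")
  if (object@meshResolutionMm <= 0) return("meshResolutionMm must be positive")
  if (object@newbornScale <= 0 || object@newbornScale >= 0.25)
    return("newbornScale must be in (0, 0.25)")
  if (object@vertexNoiseMm < 0) return("vertexNoiseMm must be >= 0")
  TRUE
})
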