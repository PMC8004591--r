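#' Accessors for package classes
#'
#' Small accessor generics in the Bioconductor style: \code{vertices} and
#' \code{faces} for meshes, \code{normals}, \code{curvature} and
#' \code{smoothness} for vertex fields, \code{traits} for leaf clusters.
#'
#' @param x an object of the documented class.
#' @return the slot contents.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("vertices", function(x) standardGeneric("vertices"))
#' @rdname accessors
#' @export
setGeneric("faces", function(x) standardGeneric("faces"))
#' @rdname accessors
#' @export
setGeneric("nVertices", function(x) standardGeneric("nVertices"))
#' @rdname accessors
#' @export
setGeneric("nFaces", function(x) standardGeneric("nFaces"))
#' @rdname accessors
#' @export
setGeneric("normals", function(x) standardGeneric("normals"))
#' @rdname accessors
#' @export
setGeneric("curvature", function(x) standardGeneric("curvature"))
#' @rdname accessors
#' @export
setGeneric("smoothness", function(x) standardGeneric("smoothness"))
#' @rdname accessors
#' @export
setGeneric("traits", function(x) standardGeneric("traits"))

#' @rdname accessors
#' @export
setMethod("vertices", "TriangleMesh", function(x) x@vertices)
#' @rdname accessors
#' @export
setMethod("faces", "TriangleMesh", function(x) x@faces)
#' @rdname accessors
#' @export
setMethod("nVertices", "TriangleMesh", function(x) nrow(x@vertices))
#' @rdname accessors
#' @export
setMethod("nFaces", "TriangleMesh", function(x) nrow(x@faces))
#' @rdname accessors
#' @export
setMethod("normals", "VertexField", function(x) x@normals)
#' @rdname accessors
#' @export
setMethod("curvature", "VertexField", function(x) x@curvature)
#' @rdname accessors
#' @export
setMethod("smoothness", "VertexField", function(x) x@smoothness)
#' @rdname accessors
#' @export
setMethod("traits", "LeafCluster", function(x) x@traits)
#' @rdname accessors
#' @export
setMethod("traits", "LeafTraits", function(x) x@values)

setMethod("show", "TriangleMesh", function(object) {
  cat(sprintf("TriangleMesh: %d vertices, %d faces\n",
              nrow(object@vertices), nrow(object@faces)))
  if (nrow(object@vertices) > 0) {
    rng <- apply(object@vertices, 2, range)
    cat(sprintf("  extent (mm): x [%.1f, %.1f], y [%.1f, %.1f], z [%.1f, %.1f]\n",
                rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2], rng[1, 3], rng[2, 3]))
  }
})

setMethod("show", "VertexField", function(object) {
  cat(sprintf("VertexField over %d vertices\n", nrow(object@normals)))
  cat(sprintf("  curvature: mean %.5f  smoothness: mean %.3f deg\n",
              mean(object@curvature), mean(object@smoothness)))
})

setMethod("show", "SurfaceStats", function(object) {
  cat(sprintf("SurfaceStats: sigma = %.4f deg, rho = %.6f\n",
              object@sigmaSmooth, object@rhoCurv))
})

setMethod("show", "PlaneModel", function(object) {
  cat(sprintf("PlaneModel: normal (%.3f, %.3f, %.3f), offset %.2f mm, %d inliers\n",
              object@normal[1], object@normal[2], object@normal[3],
              object@offset, object@inlierCount))
})

setMethod("show", "LeafTraits", function(object) {
  v <- object@values
  cat(sprintf("LeafTraits: s = %.1f mm2, c = %.1f mm, l = %.1f mm, w = %.1f mm\n",
              v["s"], v["c"], v["l"], v["w"]))
  cat(sprintf("  ratios: s/c %.2f, s/l %.2f, s/w %.2f, c/l %.2f, c/w %.2f, l/w %.2f\n",
              v["x11"], v["x12"], v["x13"], v["x14"], v["x15"], v["x16"]))
})

setMethod("show", "ShapeModel", function(object) {
  cat(sprintf("ShapeModel fitted on %d clusters%s\n", object@nFit,
              if (object@degenerate) " (degenerate)" else ""))
  cat("  a:", paste(sprintf("%.3f", object@a), collapse = " "), "\n")
  cat("  b:", paste(sprintf("%.3f", object@b), collapse = " "), "\n")
  cat(sprintf("  mean G: %.3f, band (%.2f, %.2f)\n",
              object@meanG, object@band[1], object@band[2]))
})

setMethod("show", "DetectionResult", function(object) {
  cat(sprintf("DetectionResult: %s (F = %.4f, G = %.4f, %s)\n",
              if (object@isTypical) "typical" else "not typical",
              object@fScore, object@gScore, object@reason))
})

setMethod("show", "LeafCluster", function(object) {
  cat(sprintf("LeafCluster: %d vertices, %d faces, %s\n",
              length(object@vertexIds), nrow(object@submesh@faces),
              if (is.null(object@traits)) "traits not computed"
              else sprintf("area %.1f mm2", object@traits@values["s"])))
})

setMethod("show", "SegmentationReport", function(object) {
  cat(sprintf("SegmentationReport: %d typical leaves, %d rejected, %d levels\n",
              length(object@typicalLeaves), length(object@rejected),
              object@levelsRun))
})

setMethod("show", "PlantSceneSpec", function(object) {
  cat(sprintf("PlantSceneSpec: %d leaves (+%d newborn), occlusion %s, dropout %.2f, seed %d\n",
              object@nLeaves, object@nNewborn, object@occlusionLevel,
              object@dropoutFraction, object@rngSeed))
})
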