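#' Estimate per-vertex normals, curvature and smoothness
#'
#' For each vertex, a local plane is fitted to its \code{nP} nearest vertices
#' (Euclidean, the vertex itself included): the normal is the
#' smallest-eigenvalue eigenvector of the neighbourhood covariance, and the
#' curvature is the surface variation lambda_min / (lambda_1 + lambda_2 +
#' lambda_3), which is 0 on a plane and at most 1/3 for isotropic scatter.
#' Smoothness is the mean unsigned angle (degrees) between the vertex normal
#' and the normals of its edge-adjacent vertices. Normals are oriented away
#' from the mesh centroid; all angle comparisons in the package are unsigned,
#' so the orientation convention does not affect segmentation.
#'
#' @param mesh a \linkS4class{TriangleMesh} with at least \code{nP} vertices.
#' @param nP neighbourhood size (default 30).
#' @return a \linkS4class{VertexField}.
#' @seealso [surfaceStats()], [regionGrowing()]
#' @export
estimateVertexAttributes <- function(mesh, nP = 30L) {
  stopifnot(is(mesh, "TriangleMesh"))
  nP <- as.integer(nP)
  if (nP < 3L) stop("nP must be >= 3", call. = FALSE)
  if (nrow(mesh@vertices) < nP)
    stop(sprintf("input error: mesh has %d vertices but nP = %d",
                 nrow(mesh@vertices), nP), call. = FALSE)
  att <- .cpp_vertex_attributes(mesh@vertices, nP)
  N <- att$normals
  curv <- pmin(pmax(as.numeric(att$curvature), 0), 1 / 3)

  e <- .mesh_edges(mesh)
  sm <- numeric(nrow(N))
  if (nrow(e) > 0) {
    dots <- abs(rowSums(N[e[, 1], , drop = FALSE] * N[e[, 2], , drop = FALSE]))
    ang <- acos(pmin(1, dots)) * 180 / pi
    sums <- rowsum(c(ang, ang), c(e[, 1], e[, 2]))
    cnts <- rowsum(rep(1, 2 * nrow(e)), c(e[, 1], e[, 2]))
    ids <- as.integer(rownames(sums))
    sm[ids] <- sums[, 1] / cnts[, 1]
  }
  new("VertexField", normals = N, curvature = curv, smoothness = sm)
}

#' Mesh-wide smoothness and curvature averages
#'
#' Arithmetic means of the per-vertex smoothness (sigma, degrees) and
#' curvature (rho) over all vertices. The multi-level segmentation scales its
#' thresholds as multiples of these two statistics, which is what makes the
#' segmentation scale adapt to the input data.
#'
#' @param field a \linkS4class{VertexField}.
#' @return a \linkS4class{SurfaceStats}.
#' @export
surfaceStats <- function(field) {
  stopifnot(is(field, "VertexField"))
  if (nrow(field@normals) == 0L)
    stop("input error: empty vertex field", call. = FALSE)
  new("SurfaceStats",
      sigmaSmooth = mean(field@smoothness),
      rhoCurv = mean(field@curvature))
}
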