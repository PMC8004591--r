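#' Preprocessing configuration
#'
#' @param epsilonMm buffer distance above the table (mm), default 100.
#' @param ransacIterations RANSAC sample count, default 1000.
#' @param ransacInlierTolMm inlier tolerance (mm), default 2.
#' @param minPlaneFraction minimum dominant-plane inlier fraction, default 0.05.
#' @param rngSeed seed for the RANSAC sampling, default 1.
#' @return a \linkS4class{PreprocessConfig}.
#' @export
PreprocessConfig <- function(epsilonMm = 100, ransacIterations = 1000L,
                             ransacInlierTolMm = 2.0, minPlaneFraction = 0.05,
                             rngSeed = 1L) {
  new("PreprocessConfig", epsilonMm = epsilonMm,
      ransacIterations = as.integer(ransacIterations),
      ransacInlierTolMm = ransacInlierTolMm,
      minPlaneFraction = minPlaneFraction, rngSeed = as.integer(rngSeed))
}

# run expr with a local RNG state seeded from `seed`, restoring the caller's
.with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# least-squares plane through points: normal = smallest eigenvector of the
# centred covariance, offset = normal . centroid
.fit_plane_ls <- function(P) {
  ctr <- colMeans(P)
  C <- crossprod(sweep(P, 2, ctr))
  ev <- eigen(C, symmetric = TRUE)
  normal <- ev$vectors[, 3]
  normal <- normal / sqrt(sum(normal^2))
  list(normal = normal, offset = sum(normal * ctr))
}

#' Detect the dominant table plane by RANSAC
#'
#' Random 3-vertex samples define candidate planes; the plane with the most
#' inliers (vertices within \code{ransacInlierTolMm}) wins and is refit by
#' least squares on its inliers. The normal is oriented so that the majority
#' of off-plane vertices lie on the positive side (the plant stands on the
#' table). The sampling is driven by \code{rngSeed} only, so results are
#' reproducible.
#'
#' @param mesh a \linkS4class{TriangleMesh} with at least 3 vertices.
#' @param config a \linkS4class{PreprocessConfig}.
#' @return a \linkS4class{PlaneModel}.
#' @seealso [removeNonPlant()]
#' @export
detectTablePlane <- function(mesh, config = PreprocessConfig()) {
  stopifnot(is(mesh, "TriangleMesh"), is(config, "PreprocessConfig"))
  V <- mesh@vertices
  n <- nrow(V)
  if (n < 3L) stop("input error: fewer than 3 vertices", call. = FALSE)
  tol <- config@ransacInlierTolMm

  best <- NULL
  best_count <- -1L
  .with_local_seed(config@rngSeed, {
    for (it in seq_len(config@ransacIterations)) {
      ids <- sample.int(n, 3L)
      p1 <- V[ids[1], ]; p2 <- V[ids[2], ]; p3 <- V[ids[3], ]
      nrm <- c((p2 - p1)[2] * (p3 - p1)[3] - (p2 - p1)[3] * (p3 - p1)[2],
               (p2 - p1)[3] * (p3 - p1)[1] - (p2 - p1)[1] * (p3 - p1)[3],
               (p2 - p1)[1] * (p3 - p1)[2] - (p2 - p1)[2] * (p3 - p1)[1])
      len <- sqrt(sum(nrm^2))
      if (len < 1e-12) next
      nrm <- nrm / len
      d <- abs(V %*% nrm - sum(nrm * p1))
      cnt <- sum(d <= tol)
      if (cnt > best_count) {
        best_count <- cnt
        best <- list(normal = nrm, offset = sum(nrm * p1))
      }
    }
  })
  if (is.null(best) || best_count < config@minPlaneFraction * n)
    stop("no dominant plane: best RANSAC consensus below minPlaneFraction",
         call. = FALSE)

  # refit on inliers
  d <- abs(V %*% best$normal - best$offset)
  inl <- d <= tol
  fit <- .fit_plane_ls(V[inl, , drop = FALSE])

  # orient toward the majority of off-plane vertices
  h <- V %*% fit$normal - fit$offset
  off <- abs(h) > tol
  if (any(off) && sum(h[off] > 0) < sum(h[off] < 0)) {
    fit$normal <- -fit$normal
    fit$offset <- -fit$offset
  }
  new("PlaneModel", normal = as.numeric(fit$normal), offset = fit$offset,
      inlierCount = as.integer(sum(inl)))
}

#' Remove the table, pot and soil below the buffer
#'
#' Removes every face whose three vertices all lie below the signed height
#' \code{epsilonMm} over the table plane (this includes everything on or
#' below the table). A face survives if any of its vertices reaches the
#' buffer height, which is conservative toward keeping leaves that dip close
#' to it. Unreferenced vertices are dropped; the returned mesh records the
#' surviving vertices' original indices in its \code{vertexIndex} slot and
#' the surviving faces' original indices in a \code{keptFaces} attribute.
#'
#' @param mesh the full scene \linkS4class{TriangleMesh}.
#' @param plane a \linkS4class{PlaneModel} from [detectTablePlane()].
#' @param config a \linkS4class{PreprocessConfig}; only \code{epsilonMm} is
#'   used.
#' @return the plant \linkS4class{TriangleMesh}.
#' @export
removeNonPlant <- function(mesh, plane, config = PreprocessConfig()) {
  stopifnot(is(mesh, "TriangleMesh"), is(plane, "PlaneModel"))
  h <- as.numeric(mesh@vertices %*% plane@normal - plane@offset)
  f <- mesh@faces
  below <- h < config@epsilonMm
  drop_face <- below[f[, 1]] & below[f[, 2]] & below[f[, 3]]
  keep <- which(!drop_face)
  if (length(keep) == 0L)
    stop("no plant geometry above buffer", call. = FALSE)
  kept_faces <- f[keep, , drop = FALSE]
  used <- sort(unique(as.vector(kept_faces)))
  remap <- integer(nrow(mesh@vertices))
  remap[used] <- seq_along(used)
  out <- TriangleMesh(mesh@vertices[used, , drop = FALSE],
                      matrix(remap[kept_faces], ncol = 3),
                      vertexIndex = used)
  attr(out, "keptFaces") <- keep
  out
}
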