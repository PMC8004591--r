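#' Segmentation configuration
#'
#' @param nP neighbourhood size for vertex attributes (default 30).
#' @param initMultiplier initial threshold multiplier on sigma and rho
#'   (default 1.5).
#' @param multiplierStep per-level decrement of the multiplier (default 0.05,
#'   i.e. 1.50, 1.45, 1.40, ...).
#' @param epsilonFloor stop when eps_a or eps_b falls to this value
#'   (default 1e-4).
#' @param minClusterVertices discard clusters below this vertex count
#'   (default 50).
#' @param qEndpoint boundary quantile for leaf-length endpoints (default 0.05).
#' @param kWidthSlices width stations (default 20).
#' @return a \linkS4class{SegmentationConfig}.
#' @export
SegmentationConfig <- function(nP = 30L, initMultiplier = 1.5,
                               multiplierStep = 0.05, epsilonFloor = 1e-4,
                               minClusterVertices = 50L, qEndpoint = 0.05,
                               kWidthSlices = 20L) {
  new("SegmentationConfig", nP = as.integer(nP),
      initMultiplier = initMultiplier, multiplierStep = multiplierStep,
      epsilonFloor = epsilonFloor,
      minClusterVertices = as.integer(minClusterVertices),
      qEndpoint = qEndpoint, kWidthSlices = as.integer(kWidthSlices))
}

#' Region growing segmentation
#'
#' Greedy region growing over the vertex adjacency graph: regions are seeded
#' at the unassigned vertex of minimum curvature (ties broken by vertex
#' index); an edge-adjacent unassigned vertex joins the region when the
#' unsigned angle between its normal and the normal of the front vertex that
#' reached it is at most \code{epsA} degrees, and becomes a new growth front
#' only if its curvature is at most \code{epsB}. Clusters smaller than
#' \code{minClusterVertices} are returned separately.
#'
#' @param mesh a \linkS4class{TriangleMesh}.
#' @param field the matching \linkS4class{VertexField}.
#' @param epsA smoothness threshold, degrees.
#' @param epsB curvature threshold.
#' @param minClusterVertices minimum cluster size.
#' @return list with \code{clusters} (list of \linkS4class{LeafCluster}) and
#'   \code{small} (list of \linkS4class{LeafCluster} below the size floor).
#' @export
regionGrowing <- function(mesh, field, epsA, epsB, minClusterVertices = 50L) {
  stopifnot(is(mesh, "TriangleMesh"), is(field, "VertexField"))
  if (nrow(field@normals) != nrow(mesh@vertices))
    stop("input error: field does not match mesh", call. = FALSE)
  if (epsA <= 0 || epsB < 0)
    stop("input error: thresholds must be positive", call. = FALSE)
  csr <- .vertex_adjacency_csr(mesh)
  labels <- .cpp_region_growing(field@normals, field@curvature,
                                csr$ptr, csr$idx, epsA, epsB)
  labels <- .absorb_small_clusters(labels, csr, minClusterVertices)
  ids <- split(seq_len(nrow(mesh@vertices)), labels)
  # order clusters deterministically by their smallest vertex index
  ids <- ids[order(vapply(ids, min, 0L))]
  clusters <- list(); small <- list()
  for (vid in ids) {
    cl <- new("LeafCluster", submesh = .submesh(mesh, vid),
              vertexIds = as.integer(vid), traits = NULL, reason = "pass")
    if (length(vid) >= minClusterVertices)
      clusters[[length(clusters) + 1L]] <- cl
    else {
      cl@reason <- "below_min_cluster_size"
      small[[length(small) + 1L]] <- cl
    }
  }
  list(clusters = clusters, small = small)
}

# Morphological closing of the label field: vertices stranded in clusters
# below the size floor are absorbed into an adjacent large cluster when at
# least two of their neighbours agree on it. Isolated scanner-noise vertices
# otherwise punch holes into leaf clusters and corrupt the perimeter trait.
.absorb_small_clusters <- function(labels, csr, min_size) {
  labels <- as.integer(labels)
  for (pass in seq_len(10L)) {
    sizes <- tabulate(labels)
    small <- which(sizes > 0L & sizes < min_size)
    if (length(small) == 0L) break
    in_small <- labels %in% small
    changed <- FALSE
    for (v in which(in_small)) {
      if (csr$ptr[v + 1L] <= csr$ptr[v]) next
      nb <- csr$idx[(csr$ptr[v] + 1L):csr$ptr[v + 1L]] + 1L
      nl <- labels[nb]
      nl <- nl[!(nl %in% small) & nl != labels[v]]
      if (length(nl) < 2L) next
      tab <- sort(table(nl), decreasing = TRUE)
      if (tab[1] >= 2L) {
        labels[v] <- as.integer(names(tab)[1])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  labels
}

# deterministic cache key for a (sorted) vertex set; several independent
# checksums make collisions within one mesh practically impossible
.cluster_key <- function(vid) {
  v <- as.numeric(vid)
  sprintf("%d_%d_%d_%.0f_%.0f_%.0f", length(v), as.integer(v[1]),
          as.integer(v[length(v)]), sum(v), sum(v * v),
          sum(v * seq_along(v)))
}

# traits with failure capture; cache avoids recomputing identical clusters
# across levels
.cluster_traits <- function(cluster, config, cache) {
  key <- .cluster_key(cluster@vertexIds)
  hit <- cache[[key]]
  if (!is.null(hit)) return(hit)
  res <- tryCatch(
    traitVector(cluster@submesh, q = config@qEndpoint,
                kSlices = config@kWidthSlices),
    error = function(e) conditionMessage(e))
  cache[[key]] <- res
  res
}

#' Multi-level region growing segmentation with evolving shape models
#'
#' Implements the adaptive segmentation loop. Mesh-wide smoothness and
#' curvature averages (sigma, rho) are computed once; at level t the
#' thresholds are eps_a = m_t sigma and eps_b = m_t rho with
#' m_t = 1.5 - 0.05 (t - 1). Each level re-segments only the geometry not yet
#' accepted, computes traits for the resulting clusters, fits the shape
#' models on the accepted clusters together with the current ones, accepts
#' clusters passing [detectTypical()], and re-tests previously accepted
#' clusters against the updated model (late removal is allowed; removed
#' clusters are frozen, not re-segmented). The loop stops when every current
#' cluster passes, when a threshold reaches \code{epsilonFloor}, or when the
#' multiplier reaches zero (at most 30 levels). Finally a model is fitted on
#' all accepted clusters and every accepted cluster is re-detected against
#' it; the survivors are the typical leaf samples.
#'
#' @param plantMesh the preprocessed plant \linkS4class{TriangleMesh}.
#' @param config a \linkS4class{SegmentationConfig}.
#' @param field optionally a precomputed \linkS4class{VertexField}.
#' @return a \linkS4class{SegmentationReport}.
#' @export
multilevelSegment <- function(plantMesh, config = SegmentationConfig(),
                              field = NULL) {
  stopifnot(is(plantMesh, "TriangleMesh"), is(config, "SegmentationConfig"))
  if (nrow(plantMesh@vertices) == 0L || nrow(plantMesh@faces) == 0L)
    stop("input error: empty plant mesh", call. = FALSE)
  if (is.null(field))
    field <- estimateVertexAttributes(plantMesh, nP = config@nP)
  stats <- surfaceStats(field)
  sigma <- stats@sigmaSmooth
  rho <- stats@rhoCurv

  accepted <- list()          # LeafCluster with traits, keyed by cluster key
  accepted_traits <- list()
  rejected <- list()
  residual <- seq_len(nrow(plantMesh@vertices))
  level_rows <- list()
  t <- 0L

  repeat {
    m <- config@initMultiplier - config@multiplierStep * t
    t <- t + 1L
    eps_a <- m * sigma
    eps_b <- m * rho
    # the initial segmentation always runs; the floor terminates later levels
    if (m <= 0 ||
        (t > 1L && (eps_a <= config@epsilonFloor ||
                    eps_b <= config@epsilonFloor))) {
      t <- t - 1L
      break
    }
    if (length(residual) == 0L) { t <- t - 1L; break }

    sub <- .submesh_with_field(plantMesh, field, residual)
    if (nrow(sub$mesh@faces) == 0L) { t <- t - 1L; break }
    rg <- regionGrowing(sub$mesh, sub$field, eps_a, eps_b,
                        config@minClusterVertices)
    # lift cluster vertex ids back into plant-mesh indexing
    lift <- function(cl) {
      cl@vertexIds <- sub$vertex_ids[cl@vertexIds]
      cl@submesh <- .submesh(plantMesh, cl@vertexIds)
      cl
    }
    clusters <- lapply(rg$clusters, lift)
    smalls <- lapply(rg$small, lift)
    for (cl in smalls) rejected[[length(rejected) + 1L]] <- cl
    residual <- setdiff(residual, unlist(lapply(smalls, slot, "vertexIds")))

    # traits for current clusters; failures stay in the residual pool
    cache <- .trait_cache(plantMesh)
    cur_ok <- list(); cur_traits <- list()
    n_trait_fail <- 0L
    for (cl in clusters) {
      tr <- .cluster_traits(cl, config, cache)
      if (is(tr, "LeafTraits")) {
        cl@traits <- tr
        cur_ok[[length(cur_ok) + 1L]] <- cl
        cur_traits[[length(cur_traits) + 1L]] <- tr
      } else n_trait_fail <- n_trait_fail + 1L
    }

    n_accepted_before <- length(accepted)
    all_traits <- c(accepted_traits, cur_traits)
    accepted_now <- 0L
    if (length(all_traits) > 0L) {
      model <- fitShapeModel(all_traits)
      # current clusters
      for (k in seq_along(cur_ok)) {
        det <- detectTypical(cur_traits[[k]], model)
        if (det@isTypical) {
          accepted[[length(accepted) + 1L]] <- cur_ok[[k]]
          accepted_traits[[length(accepted_traits) + 1L]] <- cur_traits[[k]]
          residual <- setdiff(residual, cur_ok[[k]]@vertexIds)
          accepted_now <- accepted_now + 1L
        }
      }
      # re-test previously accepted clusters (frozen geometry, removable)
      if (n_accepted_before > 0L) {
        keep <- logical(length(accepted))
        for (k in seq_along(accepted)) {
          det <- detectTypical(accepted_traits[[k]], model)
          keep[k] <- det@isTypical
          if (!det@isTypical) {
            cl <- accepted[[k]]
            cl@reason <- paste0("removed_at_level_", t, "_", det@reason)
            rejected[[length(rejected) + 1L]] <- cl
          }
        }
        accepted <- accepted[keep]
        accepted_traits <- accepted_traits[keep]
      }
    }

    level_rows[[t]] <- data.frame(
      level = t, multiplier = m, eps_a = eps_a, eps_b = eps_b,
      clusters = length(clusters), trait_failures = n_trait_fail,
      accepted = accepted_now, total_accepted = length(accepted),
      residual_vertices = length(residual))

    all_passed <- length(cur_ok) > 0 &&
      accepted_now == length(cur_ok) && n_trait_fail == 0L
    none_left <- length(clusters) == 0L
    if (all_passed || none_left) break
  }

  # final detection against the model fitted on all accepted clusters
  final_model <- NULL
  typical <- list()
  if (length(accepted) > 0L) {
    final_model <- fitShapeModel(accepted_traits)
    for (k in seq_along(accepted)) {
      det <- detectTypical(accepted_traits[[k]], final_model)
      if (det@isTypical) typical[[length(typical) + 1L]] <- accepted[[k]]
      else {
        cl <- accepted[[k]]
        cl@reason <- paste0("final_detection_", det@reason)
        rejected[[length(rejected) + 1L]] <- cl
      }
    }
  }
  # whatever geometry never got accepted is reported as rejected clusters
  if (length(residual) > 0L) {
    comp_mesh <- .submesh(plantMesh, residual)
    if (nrow(comp_mesh@faces) > 0L) {
      memb <- .mesh_components(comp_mesh)
      orig <- if (length(comp_mesh@vertexIndex) > 0) comp_mesh@vertexIndex
              else seq_len(nrow(comp_mesh@vertices))
      orig <- .plant_ids(plantMesh, orig)
      for (cc in split(seq_along(memb), memb)) {
        vid <- sort(orig[cc])
        rejected[[length(rejected) + 1L]] <-
          new("LeafCluster", submesh = .submesh(plantMesh, vid),
              vertexIds = as.integer(vid), traits = NULL,
              reason = "never_accepted")
      }
    }
  }

  new("SegmentationReport", typicalLeaves = typical, rejected = rejected,
      levelsRun = t, finalModel = final_model,
      levelLog = if (length(level_rows)) do.call(rbind, level_rows)
                 else data.frame(),
      surfaceStats = stats)
}

# submesh over a vertex subset carrying the matching vertex field; returns
# the submesh, its field, and the plant-mesh ids of its vertices
.submesh_with_field <- function(mesh, field, vertex_ids) {
  sm <- .submesh(mesh, vertex_ids)
  orig <- if (length(mesh@vertexIndex) > 0)
    match(sm@vertexIndex, mesh@vertexIndex) else sm@vertexIndex
  f <- new("VertexField",
           normals = field@normals[orig, , drop = FALSE],
           curvature = field@curvature[orig],
           smoothness = field@smoothness[orig])
  list(mesh = sm, field = f, vertex_ids = orig)
}

# vertexIndex of a submesh refers to the ORIGINAL top mesh; map back to the
# immediate plant mesh indexing when the plant mesh itself has provenance
.plant_ids <- function(plantMesh, orig) {
  if (length(plantMesh@vertexIndex) > 0)
    match(orig, plantMesh@vertexIndex)
  else orig
}

# per-plant-mesh trait cache (environment attached via an external registry,
# keyed by mesh identity within one multilevelSegment call)
.trait_cache_registry <- new.env(parent = emptyenv())
.trait_cache <- function(mesh) {
  key <- paste0("m", nrow(mesh@vertices), "_", nrow(mesh@faces), "_",
                format(sum(mesh@vertices), digits = 17))
  cache <- .trait_cache_registry[[key]]
  if (is.null(cache)) {
    cache <- new.env(parent = emptyenv())
    .trait_cache_registry[[key]] <- cache
  }
  cache
}
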