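# Topology utilities shared by perimeter, region growing and geodesics.
# Undirected edges are keyed as (min - 1) * nV + (max - 1) in doubles, which
# is exact well past any mesh size this package sees.

.edge_key <- function(a, b, n) {
  lo <- pmin(a, b); hi <- pmax(a, b)
  (as.numeric(lo) - 1) * n + (as.numeric(hi) - 1)
}

# all face edges (3 per face, directed as stored) with face ids
.face_edges <- function(mesh) {
  f <- mesh@faces
  data.frame(a = c(f[, 1], f[, 2], f[, 3]),
             b = c(f[, 2], f[, 3], f[, 1]),
             face = rep(seq_len(nrow(f)), 3L))
}

# unique undirected edges as a 2-column matrix
.mesh_edges <- function(mesh) {
  fe <- .face_edges(mesh)
  key <- .edge_key(fe$a, fe$b, nrow(mesh@vertices))
  keep <- !duplicated(key)
  cbind(pmin(fe$a, fe$b)[keep], pmax(fe$a, fe$b)[keep])
}

# per-undirected-edge incident-face count; errors identify non-manifold edges
.edge_face_counts <- function(mesh, check_manifold = TRUE) {
  fe <- .face_edges(mesh)
  key <- .edge_key(fe$a, fe$b, nrow(mesh@vertices))
  tab <- table(key)
  if (check_manifold && any(tab >= 3L)) {
    bad <- as.numeric(names(tab)[which(tab >= 3L)[1]])
    n <- nrow(mesh@vertices)
    stop(sprintf(
      "topology error: non-manifold edge (%d, %d) with %d incident faces",
      floor(bad / n) + 1L, (bad %% n) + 1L, max(tab)), call. = FALSE)
  }
  list(fe = fe, key = key, tab = tab)
}

# boundary edges: incident to exactly one face; 2-column vertex matrix
.boundary_edges <- function(mesh, check_manifold = TRUE) {
  efc <- .edge_face_counts(mesh, check_manifold)
  bkey <- as.numeric(names(efc$tab)[efc$tab == 1L])
  if (length(bkey) == 0L) return(matrix(integer(0), 0, 2))
  n <- nrow(mesh@vertices)
  cbind(as.integer(floor(bkey / n) + 1), as.integer((bkey %% n) + 1))
}

#' Boundary loops of a mesh
#'
#' Finds every closed cycle of boundary edges (edges incident to exactly one
#' face). Closed surfaces return an empty list.
#'
#' @param mesh a \linkS4class{TriangleMesh}.
#' @return a list of integer vectors, each a cycle of vertex indices.
#' @examples
#' sq <- TriangleMesh(rbind(c(0,0,0), c(1,0,0), c(1,1,0), c(0,1,0)),
#'                    rbind(c(1,2,3), c(1,3,4)))
#' length(boundaryLoops(sq)[[1]])
#' @export
boundaryLoops <- function(mesh) {
  stopifnot(is(mesh, "TriangleMesh"))
  be <- .boundary_edges(mesh)
  if (nrow(be) == 0L) return(list())
  # adjacency among boundary vertices
  verts <- sort(unique(c(be[, 1], be[, 2])))
  adj <- split(c(be[, 2], be[, 1]), c(be[, 1], be[, 2]))
  used <- new.env(parent = emptyenv())
  ekey <- function(a, b) paste(pmin(a, b), pmax(a, b))
  loops <- list()
  for (start in verts) {
    nbrs <- sort(adj[[as.character(start)]])
    for (first in nbrs) {
      if (!is.null(used[[ekey(start, first)]])) next
      loop <- c(start)
      prev <- start; cur <- first
      used[[ekey(start, first)]] <- TRUE
      ok <- TRUE
      while (cur != start) {
        loop <- c(loop, cur)
        cand <- sort(adj[[as.character(cur)]])
        nxt <- NA_integer_
        for (w in cand) {
          if (w == prev && is.null(used[[ekey(cur, w)]]) && w == start) {
            nxt <- w; break
          }
          if (w != prev && is.null(used[[ekey(cur, w)]])) { nxt <- w; break }
        }
        if (is.na(nxt)) { ok <- FALSE; break }  # open chain (pinched boundary)
        used[[ekey(cur, nxt)]] <- TRUE
        prev <- cur; cur <- nxt
      }
      if (ok) loops[[length(loops) + 1L]] <- loop
    }
  }
  loops
}

# CSR vertex adjacency (0-based, for the C++ region growing)
.vertex_adjacency_csr <- function(mesh) {
  e <- .mesh_edges(mesh)
  n <- nrow(mesh@vertices)
  from <- c(e[, 1], e[, 2]); to <- c(e[, 2], e[, 1])
  o <- order(from, to)
  from <- from[o]; to <- to[o]
  counts <- tabulate(from, nbins = n)
  list(ptr = as.integer(c(0L, cumsum(counts))), idx = as.integer(to - 1L))
}

# igraph over mesh edges weighted by Euclidean length
.mesh_graph <- function(mesh) {
  e <- .mesh_edges(mesh)
  w <- sqrt(rowSums((mesh@vertices[e[, 1], , drop = FALSE] -
                     mesh@vertices[e[, 2], , drop = FALSE])^2))
  g <- igraph::make_empty_graph(n = nrow(mesh@vertices), directed = FALSE)
  g <- igraph::add_edges(g, t(e))
  igraph::E(g)$weight <- w
  g
}

# extract the submesh induced by a vertex subset; keeps faces whose three
# vertices are all selected; drops unreferenced vertices; records provenance
.submesh <- function(mesh, vertex_ids) {
  vertex_ids <- sort(unique(as.integer(vertex_ids)))
  sel <- logical(nrow(mesh@vertices))
  sel[vertex_ids] <- TRUE
  f <- mesh@faces
  keep <- sel[f[, 1]] & sel[f[, 2]] & sel[f[, 3]]
  f <- f[keep, , drop = FALSE]
  used <- sort(unique(as.vector(f)))
  if (length(used) == 0L) {
    return(TriangleMesh(matrix(numeric(0), 0, 3), matrix(integer(0), 0, 3)))
  }
  remap <- integer(nrow(mesh@vertices))
  remap[used] <- seq_along(used)
  parent_index <- if (length(mesh@vertexIndex) > 0) mesh@vertexIndex[used]
                  else used
  TriangleMesh(mesh@vertices[used, , drop = FALSE],
               matrix(remap[f], ncol = 3),
               vertexIndex = as.integer(parent_index))
}

# connected components over mesh edges; returns integer membership
.mesh_components <- function(mesh) {
  g <- igraph::graph_from_edgelist(.mesh_edges(mesh), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, nrow(mesh@vertices) -
                                     igraph::vcount(g)))
  igraph::components(g)$membership
}
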