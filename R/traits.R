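#' Construct a LeafTraits vector from the four scale traits
#'
#' The six ratio traits are always derived from the stored scale traits,
#' never measured independently.
#'
#' @param s area (mm^2).
#' @param c perimeter (mm).
#' @param l length (mm).
#' @param w width (mm).
#' @return a \linkS4class{LeafTraits}.
#' @export
LeafTraits <- function(s, c, l, w) {
  v <- c(s = s, c = c, l = l, w = w,
         x11 = s / c, x12 = s / l, x13 = s / w,
         x14 = c / l, x15 = c / w, x16 = l / w)
  names(v) <- .trait_names
  new("LeafTraits", values = v)
}

#' Leaf area
#'
#' Sum of triangle areas (half cross-product magnitude per face): the leaf
#' surface is represented directly by its triangular mesh.
#'
#' @param submesh a leaf \linkS4class{TriangleMesh} with at least one face.
#' @return area in mm^2.
#' @export
leafArea <- function(submesh) {
  stopifnot(is(submesh, "TriangleMesh"))
  f <- submesh@faces
  if (nrow(f) == 0L) stop("input error: mesh has no faces", call. = FALSE)
  V <- submesh@vertices
  u <- V[f[, 2], , drop = FALSE] - V[f[, 1], , drop = FALSE]
  w <- V[f[, 3], , drop = FALSE] - V[f[, 1], , drop = FALSE]
  cx <- u[, 2] * w[, 3] - u[, 3] * w[, 2]
  cy <- u[, 3] * w[, 1] - u[, 1] * w[, 3]
  cz <- u[, 1] * w[, 2] - u[, 2] * w[, 1]
  area <- 0.5 * sum(sqrt(cx^2 + cy^2 + cz^2))
  if (area <= 0) stop("zero-area error: all faces degenerate", call. = FALSE)
  area
}

#' Leaf perimeter
#'
#' Total length of all boundary edges (edges incident to exactly one face).
#'
#' @param submesh a leaf \linkS4class{TriangleMesh} with a boundary.
#' @return perimeter in mm.
#' @export
leafPerimeter <- function(submesh) {
  stopifnot(is(submesh, "TriangleMesh"))
  be <- .boundary_edges(submesh)
  if (nrow(be) == 0L)
    stop("no boundary: the mesh is a closed surface", call. = FALSE)
  V <- submesh@vertices
  sum(sqrt(rowSums((V[be[, 1], , drop = FALSE] -
                    V[be[, 2], , drop = FALSE])^2)))
}

# ---------------------------------------------------------------------------
# Geodesic machinery: edge-graph Dijkstra seeded paths refined by unfolding
# the corridor of faces around the path into the plane and running a funnel,
# which gives the exact shortest path within the corridor's homotopy class.
# ---------------------------------------------------------------------------

# per-mesh topology tables used by the refinement
.geo_topo <- function(mesh) {
  fe <- .face_edges(mesh)
  n <- nrow(mesh@vertices)
  key <- .edge_key(fe$a, fe$b, n)
  e2f <- list2env(split(fe$face, sprintf("%.0f", key)),
                  hash = TRUE, size = max(16L, length(key)))
  e <- .mesh_edges(mesh)
  adj <- split(c(e[, 2], e[, 1]), c(e[, 1], e[, 2]))
  list(V = mesh@vertices, F = mesh@faces, n = n, e2f = e2f, adj = adj)
}

# greedy surface walk hugging the straight chord between two vertices; gives
# an initial path whose corridor contains the chord-side geodesic (Dijkstra
# paths on regular meshes have many ties and can wander cells away from it).
# Returns NULL when the walk gets stuck (e.g. around boundaries).
.chord_walk <- function(topo, from, to) {
  V <- topo$V
  dirv <- V[to, ] - V[from, ]
  L <- sqrt(sum(dirv^2))
  if (L < 1e-12) return(NULL)
  u <- dirv / L
  cur <- from
  path <- integer(0)
  path[1] <- from
  guard <- 0L
  max_steps <- 4L * nrow(V)
  while (cur != to) {
    guard <- guard + 1L
    if (guard > max_steps) return(NULL)
    nbrs <- topo$adj[[as.character(cur)]]
    if (is.null(nbrs)) return(NULL)
    if (to %in% nbrs) {
      path[length(path) + 1L] <- to
      break
    }
    t_cur <- sum((V[cur, ] - V[from, ]) * u)
    proj <- as.numeric((V[nbrs, , drop = FALSE] -
                        matrix(V[from, ], length(nbrs), 3, byrow = TRUE)) %*% u)
    ok <- proj > t_cur + 1e-9
    if (!any(ok)) return(NULL)
    cand <- nbrs[ok]
    rel <- V[cand, , drop = FALSE] -
      matrix(V[from, ], length(cand), 3, byrow = TRUE)
    lat2 <- rowSums(rel^2) - (rel %*% u)^2
    pick <- cand[order(lat2, -proj[ok], cand)[1]]
    path[length(path) + 1L] <- pick
    cur <- pick
  }
  path
}

.geo_edge_faces <- function(topo, a, b) {
  topo$e2f[[sprintf("%.0f", .edge_key(a, b, topo$n))]]
}

# interior angle of face f at vertex b (radians)
.geo_corner_angle <- function(topo, f, b) {
  vs <- topo$F[f, ]
  others <- vs[vs != b]
  u <- topo$V[others[1], ] - topo$V[b, ]
  w <- topo$V[others[2], ] - topo$V[b, ]
  du <- sqrt(sum(u^2)); dw <- sqrt(sum(w^2))
  if (du == 0 || dw == 0) return(0)
  acos(max(-1, min(1, sum(u * w) / (du * dw))))
}

# fan of faces around pivot b from edge (a, b) to edge (b, c), in one of the
# two rotational directions (chosen by the starting face). Returns the face
# sequence or NULL when the walk hits a boundary first.
.geo_fan_walk <- function(topo, b, a, c, start_face) {
  fan <- integer(0)
  cur <- start_face
  prev_third <- a
  for (guard in seq_len(64L)) {
    fan <- c(fan, cur)
    vs <- topo$F[cur, ]
    if (c %in% vs) return(fan)
    third <- vs[vs != b & vs != prev_third]
    if (length(third) != 1L) return(NULL)
    nxt <- .geo_edge_faces(topo, b, third)
    nxt <- nxt[nxt != cur]
    if (length(nxt) == 0L) return(NULL)     # boundary
    prev_third <- third
    cur <- nxt[1]
  }
  NULL
}

# best fan (smaller total corner angle at b) between the two directions
.geo_fan <- function(topo, b, a, c) {
  starts <- .geo_edge_faces(topo, b, a)
  if (is.null(starts)) return(NULL)
  fans <- list()
  for (sf in starts) {
    fan <- .geo_fan_walk(topo, b, a, c, sf)
    if (!is.null(fan)) fans[[length(fans) + 1L]] <- fan
  }
  if (length(fans) == 0L) return(NULL)
  if (length(fans) == 1L) return(fans[[1]])
  ang <- vapply(fans, function(fan)
    sum(vapply(fan, function(f) .geo_corner_angle(topo, f, b), 0)), 0)
  fans[[which.min(ang)]]
}

# corridor of faces along a vertex path; NULL triggers a waypoint split
.geo_corridor <- function(topo, path) {
  np <- length(path)
  corridor <- integer(0)
  for (i in seq_len(np - 1L)[-1]) {       # interior vertices v2 .. v_{n-1}
    fan <- .geo_fan(topo, path[i], path[i - 1L], path[i + 1L])
    if (is.null(fan)) return(list(ok = FALSE, split_at = i))
    corridor <- c(corridor, fan)
  }
  if (np == 2L) {
    fs <- .geo_edge_faces(topo, path[1], path[2])
    if (is.null(fs)) return(list(ok = FALSE, split_at = NA))
    corridor <- fs[1]
  }
  corridor <- corridor[c(TRUE, diff(corridor) != 0L)]
  list(ok = TRUE, faces = corridor)
}

# unfold the face strip into 2D; returns per-face 2 x 3 coordinate matrices
# aligned with topo$F[f, ] vertex order, plus the portal vertex pairs
.geo_unfold <- function(topo, corridor) {
  m <- length(corridor)
  coords <- vector("list", m)
  f1 <- corridor[1]
  vs <- topo$F[f1, ]
  A <- topo$V[vs[1], ]; B <- topo$V[vs[2], ]; C <- topo$V[vs[3], ]
  ab <- sqrt(sum((B - A)^2))
  p1 <- c(0, 0); p2 <- c(ab, 0)
  # place C by distances
  ac <- sqrt(sum((C - A)^2)); bc <- sqrt(sum((C - B)^2))
  x <- if (ab > 0) (ac^2 - bc^2 + ab^2) / (2 * ab) else 0
  y <- sqrt(max(0, ac^2 - x^2))
  co <- rbind(p1, p2, c(x, y))
  rownames(co) <- NULL
  coords[[1]] <- list(v = vs, xy = co)
  portals <- vector("list", max(0L, m - 1L))
  if (m >= 2L) for (t in seq_len(m - 1L)) {
    fprev <- coords[[t]]
    fnext <- corridor[t + 1L]
    vs2 <- topo$F[fnext, ]
    shared <- intersect(fprev$v, vs2)
    if (length(shared) != 2L)
      stop("internal geodesic error: corridor faces do not share an edge")
    zi <- vs2[!vs2 %in% shared]
    x1 <- fprev$xy[match(shared[1], fprev$v), ]
    x2 <- fprev$xy[match(shared[2], fprev$v), ]
    wv <- fprev$v[!fprev$v %in% shared]
    wxy <- fprev$xy[match(wv, fprev$v), ]
    d1 <- sqrt(sum((topo$V[zi, ] - topo$V[shared[1], ])^2))
    d2 <- sqrt(sum((topo$V[zi, ] - topo$V[shared[2], ])^2))
    e <- x2 - x1
    el <- sqrt(sum(e^2))
    ex <- if (el > 0) e / el else c(1, 0)
    ey <- c(-ex[2], ex[1])
    px <- if (el > 0) (d1^2 - d2^2 + el^2) / (2 * el) else 0
    py2 <- max(0, d1^2 - px^2)
    py <- sqrt(py2)
    # place z on the opposite side of the shared edge from w
    wside <- sum((wxy - x1) * ey)
    if (wside > 0) py <- -py
    zxy <- x1 + px * ex + py * ey
    xy2 <- rbind(x1, x2, zxy)[match(vs2, c(shared, zi)), , drop = FALSE]
    rownames(xy2) <- NULL
    coords[[t + 1L]] <- list(v = vs2, xy = xy2)
    portals[[t]] <- list(v = shared, xy = rbind(x1, x2),
                         ahead = zxy, behind = wxy)
  }
  list(coords = coords, portals = portals)
}

# twice the signed triangle area, positive when c lies LEFT of a->b is
# encoded with the sign convention of the standard funnel formulation:
# tri2 > 0 means c is to the RIGHT of the ray a->b
.geo_tri2 <- function(a, b, c) {
  (c[1] - a[1]) * (b[2] - a[2]) - (b[1] - a[1]) * (c[2] - a[2])
}

.geo_veq <- function(a, b) {
  abs(a[1] - b[1]) < 1e-9 && abs(a[2] - b[2]) < 1e-9
}

# funnel algorithm over oriented portals; returns the polyline of apex points
.geo_funnel <- function(portals, s, e) {
  if (length(portals) == 0L) return(rbind(s, e))
  # orient each portal: the left endpoint lies left of the travel direction
  P <- lapply(portals, function(p) {
    d <- p$ahead - p$behind
    c1 <- d[1] * (p$xy[1, 2] - p$behind[2]) - d[2] * (p$xy[1, 1] - p$behind[1])
    c2 <- d[1] * (p$xy[2, 2] - p$behind[2]) - d[2] * (p$xy[2, 1] - p$behind[1])
    if (c1 >= c2) list(l = p$xy[1, ], r = p$xy[2, ])
    else list(l = p$xy[2, ], r = p$xy[1, ])
  })
  P[[length(P) + 1L]] <- list(l = e, r = e)

  eps <- 1e-9
  pts <- list(s)
  apex <- s; pl <- s; pr <- s
  ai <- 0L; li <- 0L; ri <- 0L
  i <- 1L
  n <- length(P)
  guard <- 0L
  while (i <= n) {
    guard <- guard + 1L
    if (guard > 50000L) break
    l <- P[[i]]$l; r <- P[[i]]$r
    # tighten the right side of the funnel
    if (.geo_tri2(apex, pr, r) <= eps) {
      if (.geo_veq(apex, pr) || .geo_tri2(apex, pl, r) > -eps) {
        pr <- r; ri <- i
      } else {
        # right crossed over left: left endpoint becomes the new apex
        pts[[length(pts) + 1L]] <- pl
        apex <- pl; ai <- li
        pl <- apex; pr <- apex; ri <- ai
        i <- ai + 1L
        next
      }
    }
    # tighten the left side of the funnel
    if (.geo_tri2(apex, pl, l) >= -eps) {
      if (.geo_veq(apex, pl) || .geo_tri2(apex, pr, l) < eps) {
        pl <- l; li <- i
      } else {
        pts[[length(pts) + 1L]] <- pr
        apex <- pr; ai <- ri
        pl <- apex; pr <- apex; li <- ai
        i <- ai + 1L
        next
      }
    }
    i <- i + 1L
  }
  pts[[length(pts) + 1L]] <- e
  do.call(rbind, pts)
}

# map a 2D point in a corridor face back to 3D by barycentric coordinates
.geo_to3d <- function(topo, face_entry, pt2d) {
  xy <- face_entry$xy
  v <- face_entry$v
  T <- cbind(xy[1, ] - xy[3, ], xy[2, ] - xy[3, ])
  det <- T[1, 1] * T[2, 2] - T[1, 2] * T[2, 1]
  if (abs(det) < 1e-14) return(topo$V[v[1], ])
  lam <- solve(T, pt2d - xy[3, ])
  lam <- c(lam, 1 - sum(lam))
  lam[1] * topo$V[v[1], ] + lam[2] * topo$V[v[2], ] + lam[3] * topo$V[v[3], ]
}

# refine one vertex path (consecutive vertices edge-adjacent); returns the
# tightened length, a 3D polyline, and the vertex ids where the path bends
.refine_geodesic <- function(topo, path) {
  path <- as.integer(path)
  np <- length(path)
  if (np < 2L) return(list(length = 0, points = topo$V[path, , drop = FALSE],
                           vids = path))
  graph_poly <- topo$V[path, , drop = FALSE]
  graph_len <- sum(sqrt(rowSums((graph_poly[-1, , drop = FALSE] -
                                 graph_poly[-np, , drop = FALSE])^2)))
  fallback <- list(length = graph_len, points = graph_poly, vids = path)
  cor <- .geo_corridor(topo, path)
  if (!cor$ok) {
    if (is.na(cor$split_at) || np <= 2L) return(fallback)
    a <- .refine_geodesic(topo, path[1:cor$split_at])
    b <- .refine_geodesic(topo, path[cor$split_at:np])
    return(list(length = a$length + b$length,
                points = rbind(a$points, b$points[-1, , drop = FALSE]),
                vids = c(a$vids, b$vids[-1])))
  }
  un <- .geo_unfold(topo, cor$faces)
  sface <- un$coords[[1]]
  eface <- un$coords[[length(un$coords)]]
  s2d <- sface$xy[match(path[1], sface$v), ]
  e2d <- eface$xy[match(path[np], eface$v), ]
  if (anyNA(s2d) || anyNA(e2d)) return(fallback)
  poly2d <- .geo_funnel(un$portals, s2d, e2d)
  len <- sum(sqrt(rowSums((poly2d[-1, , drop = FALSE] -
                           poly2d[-nrow(poly2d), , drop = FALSE])^2)))
  if (!is.finite(len) || len > graph_len + 1e-9) return(fallback)
  # funnel bends happen at portal endpoints, which are mesh vertices; locate
  # each bend by matching 2D coordinates against the portal endpoints
  pts3d <- graph_poly
  vids <- path
  if (nrow(poly2d) >= 2L) {
    mids <- poly2d[-c(1, nrow(poly2d)), , drop = FALSE]
    bend_vid <- integer(nrow(mids))
    bend3d <- matrix(0, nrow(mids), 3)
    if (nrow(mids) > 0) {
      pv <- do.call(rbind, lapply(un$portals, function(p)
        cbind(p$xy, p$v)))
      for (k in seq_len(nrow(mids))) {
        dd <- (pv[, 1] - mids[k, 1])^2 + (pv[, 2] - mids[k, 2])^2
        bend_vid[k] <- as.integer(pv[which.min(dd), 3])
        bend3d[k, ] <- topo$V[bend_vid[k], ]
      }
    }
    pts3d <- rbind(topo$V[path[1], ], bend3d, topo$V[path[np], ])
    vids <- c(path[1], bend_vid, path[np])
  }
  list(length = len, points = pts3d, vids = vids)
}

# among the many tied shortest paths on regular meshes, greedily walk the
# one hugging the straight chord: from `from`, repeatedly step to a
# neighbour on a shortest path to `to` (checked against the distance field
# dvec = distances from `to`) with minimal lateral deviation from the chord
.straightest_path <- function(topo, dvec, from, to) {
  V <- topo$V
  dirv <- V[to, ] - V[from, ]
  L <- sqrt(sum(dirv^2))
  if (L < 1e-12) return(NULL)
  u <- dirv / L
  cur <- from
  path <- from
  guard <- 0L
  while (cur != to) {
    guard <- guard + 1L
    if (guard > 4L * nrow(V)) return(NULL)
    nbrs <- topo$adj[[as.character(cur)]]
    if (is.null(nbrs)) return(NULL)
    Nw <- V[nbrs, , drop = FALSE]
    w <- sqrt(rowSums((Nw - matrix(V[cur, ], length(nbrs), 3,
                                   byrow = TRUE))^2))
    ok <- abs(dvec[nbrs] + w - dvec[cur]) < 1e-6 * (1 + dvec[cur])
    if (!any(ok)) return(NULL)
    cand <- nbrs[ok]
    rel <- V[cand, , drop = FALSE] -
      matrix(V[from, ], length(cand), 3, byrow = TRUE)
    lat2 <- rowSums(rel^2) - (rel %*% u)^2
    pick <- cand[order(lat2, cand)[1]]
    path[length(path) + 1L] <- pick
    cur <- pick
  }
  path
}

# closest points on a set of triangles (rows of A, B, C) to point p;
# Ericson's vertex/edge/face region classification, vectorized over faces
.closest_on_tris <- function(p, A, B, C) {
  ab <- B - A; ac <- C - A
  ap <- -sweep(A, 2, p)
  d1 <- rowSums(ab * ap); d2 <- rowSums(ac * ap)
  bp <- -sweep(B, 2, p)
  d3 <- rowSums(ab * bp); d4 <- rowSums(ac * bp)
  cp <- -sweep(C, 2, p)
  d5 <- rowSums(ab * cp); d6 <- rowSums(ac * cp)
  out <- A                                  # vertex A region default
  doneA <- d1 <= 0 & d2 <= 0
  vB <- d3 >= 0 & d4 <= d3
  out[vB, ] <- B[vB, , drop = FALSE]
  vC <- d6 >= 0 & d5 <= d6
  out[vC, ] <- C[vC, , drop = FALSE]
  vc <- d1 * d4 - d3 * d2
  eAB <- !doneA & !vB & !vC & vc <= 0 & d1 >= 0 & d3 <= 0
  if (any(eAB)) {
    t <- d1[eAB] / (d1[eAB] - d3[eAB])
    out[eAB, ] <- A[eAB, , drop = FALSE] + t * ab[eAB, , drop = FALSE]
  }
  vb <- d5 * d2 - d1 * d6
  eAC <- !doneA & !vB & !vC & !eAB & vb <= 0 & d2 >= 0 & d6 <= 0
  if (any(eAC)) {
    t <- d2[eAC] / (d2[eAC] - d6[eAC])
    out[eAC, ] <- A[eAC, , drop = FALSE] + t * ac[eAC, , drop = FALSE]
  }
  va <- d3 * d6 - d5 * d4
  eBC <- !doneA & !vB & !vC & !eAB & !eAC & va <= 0 &
    (d4 - d3) >= 0 & (d5 - d6) >= 0
  if (any(eBC)) {
    t <- (d4 - d3)[eBC] / ((d4 - d3)[eBC] + (d5 - d6)[eBC])
    out[eBC, ] <- B[eBC, , drop = FALSE] +
      t * (C - B)[eBC, , drop = FALSE]
  }
  inner <- !doneA & !vB & !vC & !eAB & !eAC & !eBC
  if (any(inner)) {
    denom <- va[inner] + vb[inner] + vc[inner]
    v <- vb[inner] / denom; w <- vc[inner] / denom
    out[inner, ] <- A[inner, , drop = FALSE] +
      v * ab[inner, , drop = FALSE] + w * ac[inner, , drop = FALSE]
  }
  out
}

# tighten a funnel polyline by midpoint relaxation constrained to the mesh
# surface: subdivide to roughly edge-length spacing, then repeatedly replace
# interior points by the surface projection of their neighbours' midpoint.
# Removes the small residual slack the corridor leaves on adversarial pairs.
.relax_path <- function(topo, v2f, pts, iters = 40L) {
  if (nrow(pts) < 2L) return(pts)
  h <- mean(sqrt(rowSums((topo$V[topo$F[, 1], , drop = FALSE] -
                          topo$V[topo$F[, 2], , drop = FALSE])^2)))
  A <- topo$V[topo$F[, 1], , drop = FALSE]
  B <- topo$V[topo$F[, 2], , drop = FALSE]
  C <- topo$V[topo$F[, 3], , drop = FALSE]

  resample <- function(P, spacing) {
    seg <- P[-1, , drop = FALSE] - P[-nrow(P), , drop = FALSE]
    slen <- sqrt(rowSums(seg^2))
    keep <- slen > 1e-12
    seg <- seg[keep, , drop = FALSE]; slen <- slen[keep]
    P <- P[c(TRUE, keep), , drop = FALSE]
    L <- sum(slen)
    if (L <= 0) return(P)
    cum <- c(0, cumsum(slen))
    nseg <- max(2L, ceiling(L / spacing))
    t_out <- seq(0, L, length.out = nseg + 1L)
    out <- matrix(0, length(t_out), 3)
    for (q in seq_along(t_out)) {
      si <- min(max(findInterval(t_out[q], cum, rightmost.closed = TRUE), 1L),
                length(slen))
      out[q, ] <- P[si, ] + (t_out[q] - cum[si]) / slen[si] * seg[si, ]
    }
    out
  }

  relax_once <- function(P, iters) {
    n <- nrow(P)
    if (n < 3L) return(P)
    cur_face <- integer(n)
    for (i in seq_len(n)) {
      cl <- .closest_on_tris(P[i, ], A, B, C)
      best <- which.min(rowSums(sweep(cl, 2, P[i, ])^2))
      cur_face[i] <- best
      P[i, ] <- cl[best, ]
    }
    for (it in seq_len(iters)) {
      moved <- 0
      for (i in 2:(n - 1L)) {
        target <- 0.5 * (P[i - 1L, ] + P[i + 1L, ])
        cand <- unique(unlist(v2f[topo$F[cur_face[i], ]]))
        cl <- .closest_on_tris(target, A[cand, , drop = FALSE],
                               B[cand, , drop = FALSE],
                               C[cand, , drop = FALSE])
        d2 <- rowSums(sweep(cl, 2, target)^2)
        b <- which.min(d2)
        moved <- moved + sum((cl[b, ] - P[i, ])^2)
        P[i, ] <- cl[b, ]
        cur_face[i] <- cand[b]
      }
      if (moved < (1e-5 * h)^2 * n) break
    }
    P
  }

  # coarse-to-fine: long-wavelength bowing converges at the coarse levels,
  # the fine level tightens the local zigzag
  P <- pts
  for (spacing in c(8, 4, 2, 1) * h) {
    P <- resample(P, spacing)
    P <- relax_once(P, iters)
  }
  P
}

# iterate the corridor refinement: rebuild a vertex path through the bend
# vertices of the previous refinement (the corridor shifts toward the true
# geodesic each round) until the length stops improving
.refine_iterate <- function(topo, g, path0, max_iter = 3L) {
  best <- .refine_geodesic(topo, path0)
  prev_path <- path0
  for (it in seq_len(max_iter)) {
    vids <- best$vids
    vids <- vids[c(TRUE, diff(vids) != 0L)]
    if (length(vids) < 2L) break
    newpath <- vids[1]
    ok <- TRUE
    for (kk in seq_len(length(vids) - 1L)) {
      u <- vids[kk]; v <- vids[kk + 1L]
      seg <- if (v %in% topo$adj[[as.character(u)]]) c(u, v)
      else {
        cw <- .chord_walk(topo, u, v)
        if (is.null(cw)) {
          sp <- igraph::shortest_paths(g, from = u, to = v,
                                       output = "vpath")$vpath[[1]]
          as.integer(sp)
        } else cw
      }
      if (length(seg) < 2L) { ok <- FALSE; break }
      newpath <- c(newpath, seg[-1])
    }
    if (!ok || identical(newpath, prev_path)) break
    cand <- .refine_geodesic(topo, newpath)
    if (cand$length < best$length - 1e-9) {
      best <- cand
      prev_path <- newpath
    } else break
  }
  best
}

#' Leaf length: longest shortest surface path along the first principal axis
#'
#' Candidate endpoints are boundary vertices whose projection on the first
#' principal axis of the leaf falls in the extreme \code{q} quantiles (at
#' least 3 per side). For each candidate pair the edge-graph shortest path is
#' computed and then refined by unfolding the corridor of faces around it and
#' pulling the path tight (a funnel pass), giving the exact geodesic within
#' that corridor; the leaf length is the maximum refined distance over pairs.
#'
#' @param submesh a connected leaf \linkS4class{TriangleMesh} with at least
#'   two boundary vertices.
#' @param q endpoint quantile (default 0.05).
#' @param detail if TRUE, return a list with the length, the refined 3D
#'   polyline and the endpoint vertices.
#' @return length in mm, or a list when \code{detail = TRUE}.
#' @export
leafLength <- function(submesh, q = 0.05, detail = FALSE) {
  stopifnot(is(submesh, "TriangleMesh"))
  comp <- .mesh_components(submesh)
  if (max(comp) > 1L)
    stop("topology error: leaf submesh is disconnected", call. = FALSE)
  be <- .boundary_edges(submesh)
  bverts <- sort(unique(as.vector(be)))
  if (length(bverts) < 2L)
    stop("input error: fewer than 2 boundary vertices", call. = FALSE)
  V <- submesh@vertices
  ctr <- colMeans(V)
  ev <- eigen(crossprod(sweep(V, 2, ctr)), symmetric = TRUE)
  u <- ev$vectors[, 1]
  anchor <- bverts[which.max(rowSums(V[bverts, , drop = FALSE]))]
  if (sum((V[anchor, ] - ctr) * u) < 0) u <- -u

  proj <- as.numeric(V[bverts, , drop = FALSE] %*% u)
  o <- order(proj, bverts)
  lo_cut <- stats::quantile(proj, q, names = FALSE)
  hi_cut <- stats::quantile(proj, 1 - q, names = FALSE)
  low <- bverts[proj <= lo_cut]
  high <- bverts[proj >= hi_cut]
  if (length(low) < 3L) low <- bverts[o][seq_len(min(3L, length(bverts)))]
  if (length(high) < 3L) high <- bverts[rev(o)][seq_len(min(3L, length(bverts)))]

  g <- .mesh_graph(submesh)
  # distance field from every endpoint candidate on the high side; row j is
  # reused both for the pair distances and for the straightest-path walks
  Dfield <- igraph::distances(g, v = high)
  D <- t(Dfield[, low, drop = FALSE])
  topo <- .geo_topo(submesh)

  # stage 1: corridor-funnel refinement (an upper bound on each pair's
  # geodesic) for every pair whose graph distance could still win the max;
  # the Euclidean pair distance is a lower bound that tightens the pruning
  ord <- order(D, decreasing = TRUE)
  # Euclidean distances are lower bounds on the pair geodesics: no pair with
  # graph distance below the best Euclidean bound can win the max
  E2 <- outer(rowSums(V[low, , drop = FALSE]^2),
              rowSums(V[high, , drop = FALSE]^2), `+`) -
    2 * V[low, , drop = FALSE] %*% t(V[high, , drop = FALSE])
  best_lb <- sqrt(max(0, max(E2)))
  refs <- list()
  path_cache <- list()
  for (k in ord) {
    i <- (k - 1L) %% length(low) + 1L
    j <- (k - 1L) %/% length(low) + 1L
    if (low[i] == high[j]) next
    if (length(refs) > 0L && D[k] <= best_lb + 1e-12) break
    sp <- .straightest_path(topo, Dfield[j, ], low[i], high[j])
    ref <- if (!is.null(sp)) .refine_iterate(topo, g, sp) else NULL
    if (is.null(ref)) {
      ck <- as.character(low[i])
      if (is.null(path_cache[[ck]]))
        path_cache[[ck]] <- igraph::shortest_paths(g, from = low[i],
                                                   to = high,
                                                   output = "vpath")$vpath
      vpath <- as.integer(path_cache[[ck]][[j]])
      if (length(vpath) >= 2L) ref <- .refine_iterate(topo, g, vpath)
    }
    if (is.null(ref)) next
    ref$endpoints <- c(low[i], high[j])
    refs[[length(refs) + 1L]] <- ref
  }
  if (length(refs) == 0L)
    stop("topology error: no geodesic between endpoint candidates",
         call. = FALSE)
  # stage 2: tighten candidate winners by surface-constrained relaxation;
  # relaxation only shortens, so pairs whose funnel bound is already below
  # the best relaxed length cannot win the max
  v2f <- split(rep(seq_len(nrow(submesh@faces)), 3L),
               as.vector(submesh@faces))
  lens <- vapply(refs, function(r) r$length, 0)
  best <- -Inf
  best_out <- NULL
  for (k in order(lens, decreasing = TRUE)) {
    if (lens[k] <= best + 1e-12) break
    pts <- .relax_path(topo, v2f, refs[[k]]$points)
    len <- min(lens[k],
               sum(sqrt(rowSums((pts[-1, , drop = FALSE] -
                                 pts[-nrow(pts), , drop = FALSE])^2))))
    if (len > best) {
      best <- len
      best_out <- list(points = pts, endpoints = refs[[k]]$endpoints)
    }
  }
  if (detail)
    list(length = best, points = best_out$points,
         endpoints = best_out$endpoints)
  else best
}

#' Leaf width: widest surface transect perpendicular to the length path
#'
#' The length path is sampled at \code{k} evenly spaced stations; at each
#' station the mesh is sliced by the plane through the station point with
#' normal along the local path tangent, and the total length of the
#' intersection polyline is taken as that station's transect. The width is
#' the maximum transect over stations.
#'
#' @param submesh the leaf \linkS4class{TriangleMesh}.
#' @param lengthPath 3D polyline (matrix) from \code{leafLength(detail=TRUE)}.
#' @param k number of stations (default 20).
#' @return width in mm.
#' @export
leafWidth <- function(submesh, lengthPath, k = 20L) {
  stopifnot(is(submesh, "TriangleMesh"))
  P <- as.matrix(lengthPath)
  if (nrow(P) < 2L) stop("input error: length path too short", call. = FALSE)
  seg <- P[-1, , drop = FALSE] - P[-nrow(P), , drop = FALSE]
  slen <- sqrt(rowSums(seg^2))
  keep <- slen > 1e-12
  seg <- seg[keep, , drop = FALSE]; slen <- slen[keep]
  P <- P[c(TRUE, keep), , drop = FALSE]
  L <- sum(slen)
  if (L <= 0) stop("input error: degenerate length path", call. = FALSE)
  cum <- c(0, cumsum(slen))
  V <- submesh@vertices
  f <- submesh@faces
  # point on the path at arc position t
  at_arc <- function(target) {
    target <- min(max(target, 0), L)
    si <- findInterval(target, cum, rightmost.closed = TRUE)
    si <- min(max(si, 1L), length(slen))
    t_loc <- (target - cum[si]) / slen[si]
    P[si, ] + t_loc * seg[si, ]
  }
  delta <- max(L / (4 * k), mean(slen))
  width <- 0
  any_hit <- FALSE
  for (i in seq_len(k)) {
    target <- (i - 0.5) / k * L
    p0 <- at_arc(target)
    # central-difference tangent smooths the kinks of the refined polyline
    tangent <- at_arc(target + delta) - at_arc(target - delta)
    tl <- sqrt(sum(tangent^2))
    if (tl < 1e-12) next
    tangent <- tangent / tl
    d <- as.numeric(V %*% tangent) - sum(p0 * tangent)
    d1 <- d[f[, 1]]; d2 <- d[f[, 2]]; d3 <- d[f[, 3]]
    crossing <- (pmin(d1, d2, d3) < 0) & (pmax(d1, d2, d3) > 0)
    if (!any(crossing)) next
    tot <- 0
    for (fi in which(crossing)) {
      vs <- f[fi, ]
      dv <- d[vs]
      pts <- list()
      for (e in list(c(1, 2), c(2, 3), c(3, 1))) {
        da <- dv[e[1]]; db <- dv[e[2]]
        if (da == 0) pts[[length(pts) + 1L]] <- V[vs[e[1]], ]
        if (da * db < 0) {
          tt <- da / (da - db)
          pts[[length(pts) + 1L]] <- V[vs[e[1]], ] +
            tt * (V[vs[e[2]], ] - V[vs[e[1]], ])
        }
      }
      if (length(pts) >= 2L) {
        M <- unique(do.call(rbind, pts))
        if (nrow(M) >= 2L) {
          dd <- as.matrix(stats::dist(M))
          tot <- tot + max(dd)
        }
      }
    }
    if (tot > 0) any_hit <- TRUE
    width <- max(width, tot)
  }
  if (!any_hit)
    stop("geometry error: no station slice intersects the leaf",
         call. = FALSE)
  width
}

#' Compute the full ten-trait vector of a leaf
#'
#' Computes area, perimeter, geodesic length and width, then derives the six
#' ratio traits.
#'
#' @param submesh a leaf \linkS4class{TriangleMesh}.
#' @param q endpoint quantile for [leafLength()].
#' @param kSlices number of width stations for [leafWidth()].
#' @return a \linkS4class{LeafTraits}.
#' @examples
#' leaf <- generateLeaf(30, 20, bendDeg = 0, resolutionMm = 2)
#' traitVector(leaf$mesh)
#' @export
traitVector <- function(submesh, q = 0.05, kSlices = 20L) {
  s <- leafArea(submesh)
  c_ <- leafPerimeter(submesh)
  len <- leafLength(submesh, q = q, detail = TRUE)
  w <- leafWidth(submesh, len$points, k = kSlices)
  LeafTraits(s, c_, len$length, w)
}
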