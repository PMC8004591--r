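# Mesh fixtures built in code. All grids use the same column-strip
# triangulation (quad split by one diagonal), matching scanner-like meshes.

gridMesh <- function(xs, ys, fx = function(x, y) cbind(x, y, 0)) {
  ny <- length(ys)
  V <- NULL
  for (x in xs) V <- rbind(V, fx(rep(x, ny), ys))
  idx <- function(i, j) (i - 1L) * ny + j
  F <- NULL
  for (i in seq_len(length(xs) - 1L)) {
    j <- seq_len(ny - 1L)
    F <- rbind(F,
               cbind(idx(i, j), idx(i + 1L, j), idx(i + 1L, j + 1L)),
               cbind(idx(i, j), idx(i + 1L, j + 1L), idx(i, j + 1L)))
  }
  TriangleMesh(V, F)
}

rectangleStrip <- function(L = 50, W = 10, h = 1) {
  gridMesh(seq(0, L, length.out = round(L / h) + 1L),
           seq(0, W, length.out = round(W / h) + 1L))
}

bentStrip <- function(R = 20, angle = pi, W = 10, h = 1) {
  L <- R * angle
  gridMesh(seq(0, L, length.out = round(L / h) + 1L),
           seq(0, W, length.out = round(W / h) + 1L),
           function(s, y) cbind(R * sin(s / R), y, R * (1 - cos(s / R))))
}

discMesh <- function(r = 10, nb = 512, nr = 32) {
  th <- seq(0, 2 * pi, length.out = nb + 1L)[-(nb + 1L)]
  V <- rbind(c(0, 0, 0))
  for (k in seq_len(nr))
    V <- rbind(V, cbind(r * k / nr * cos(th), r * k / nr * sin(th), 0))
  id <- function(ring, k) 1L + (ring - 1L) * nb + ((k - 1L) %% nb) + 1L
  F <- NULL
  for (k in seq_len(nb)) F <- rbind(F, c(1L, id(1, k), id(1, k + 1)))
  for (ring in seq_len(nr - 1L)) for (k in seq_len(nb))
    F <- rbind(F, c(id(ring, k), id(ring + 1, k), id(ring + 1, k + 1)),
               c(id(ring, k), id(ring + 1, k + 1), id(ring, k + 1)))
  TriangleMesh(V, F)
}

annulusMesh <- function(r1 = 5, r2 = 10, nb = 48) {
  th <- seq(0, 2 * pi, length.out = nb + 1L)[-(nb + 1L)]
  V <- rbind(cbind(r1 * cos(th), r1 * sin(th), 0),
             cbind(r2 * cos(th), r2 * sin(th), 0))
  nxt <- c(seq_len(nb)[-1], 1L)
  F <- rbind(cbind(seq_len(nb), nb + seq_len(nb), nb + nxt),
             cbind(seq_len(nb), nb + nxt, nxt))
  TriangleMesh(V, F)
}

icosahedronMesh <- function() {
  p <- (1 + sqrt(5)) / 2
  V <- rbind(c(-1, p, 0), c(1, p, 0), c(-1, -p, 0), c(1, -p, 0),
             c(0, -1, p), c(0, 1, p), c(0, -1, -p), c(0, 1, -p),
             c(p, 0, -1), c(p, 0, 1), c(-p, 0, -1), c(-p, 0, 1))
  V <- V / sqrt(1 + p^2)
  F <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  TriangleMesh(V, F)
}

icosphereMesh <- function(subdiv = 3L, radius = 1) {
  mesh <- icosahedronMesh()
  for (s in seq_len(subdiv)) {
    V <- mesh@vertices
    F <- mesh@faces
    midmap <- new.env(parent = emptyenv())
    newV <- list()
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      hit <- midmap[[key]]
      if (!is.null(hit)) return(hit)
      m <- (V[a, ] + V[b, ]) / 2
      m <- m / sqrt(sum(m^2))
      newV[[length(newV) + 1L]] <<- m
      id <- nrow(V) + length(newV)
      midmap[[key]] <- id
      id
    }
    newF <- matrix(0L, 0, 3)
    for (f in seq_len(nrow(F))) {
      a <- F[f, 1]; b <- F[f, 2]; c_ <- F[f, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c_); ca <- midpoint(c_, a)
      newF <- rbind(newF, c(a, ab, ca), c(b, bc, ab), c(c_, ca, bc),
                    c(ab, bc, ca))
    }
    mesh <- TriangleMesh(rbind(V, do.call(rbind, newV)), newF)
  }
  TriangleMesh(mesh@vertices * radius, mesh@faces)
}

rotationMatrix <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- rbind(c(0, -axis[3], axis[2]),
             c(axis[3], 0, -axis[1]),
             c(-axis[2], axis[1], 0))
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

transformMesh <- function(mesh, R = diag(3), t = c(0, 0, 0)) {
  TriangleMesh(sweep(mesh@vertices %*% t(R), 2, t, `+`), mesh@faces)
}

# ellipse leaf trait matrix for shape-model tests: n leaves around the given
# linear scale factors, geometrically consistent ratios
traitRowsFromScales <- function(scales, s0 = 2000, c0 = 170, l0 = 65,
                                w0 = 41) {
  do.call(rbind, lapply(scales, function(k) {
    tv <- LeafTraits(s0 * k^2, c0 * k, l0 * k, w0 * k)
    as.data.frame(t(tv@values))
  }))
}

# brute-force boundary edges: an undirected edge is boundary iff it has
# exactly one incident face (independent of the package's topology code)
bruteBoundaryEdges <- function(mesh) {
  f <- faces(mesh)
  e <- rbind(cbind(f[, 1], f[, 2]), cbind(f[, 2], f[, 3]),
             cbind(f[, 3], f[, 1]))
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  tab <- table(key)
  names(tab)[tab == 1L]
}
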