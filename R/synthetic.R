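#' Synthetic plant-scene specification
#'
#' @param nLeaves number of mature leaves (default 6).
#' @param leafSemiAxesMm mean semi-axes (a, b) of the leaf ellipse
#'   (default c(32.5, 20.5), matching a typical pothos leaf of about
#'   2000 mm^2 area, 65 mm length and 41 mm width).
#' @param leafSizeCv linear coefficient of variation of mature-leaf size
#'   (default 0.015, truncated at 2 sd). Measurement targets are the uniform
#'   fully expanded blades of a single plant; atypical foliage is modeled
#'   explicitly through newborn and damaged leaves, not as size-tail draws.
#' @param leafBendDeg total bend of the midrib (default 20 degrees; the leaf
#'   is also cupped transversely with the same radius, as broad live leaves
#'   are).
#' @param occlusionLevel "none", "little", "medium" or "heavy", mapped to
#'   target mean projected leaf-overlap fractions 0 / 0.05 / 0.15 / 0.30.
#' @param nNewborn number of small curled newborn leaves (default 0).
#' @param newbornScale linear size of newborns relative to the mean leaf
#'   (default 0.15).
#' @param dropoutFraction fraction of leaf faces deleted as connected shadow
#'   patches (default 0).
#' @param tableSizeMm table side length (default 400).
#' @param potHeightMm pot height, below the 100 mm buffer (default 80).
#' @param meshResolutionMm target vertex spacing on leaves (default 1.5).
#' @param vertexNoiseMm sd of scanner jitter on every vertex (default 0.05,
#'   the accuracy scale of hand-held laser scanners).
#' @param rngSeed integer seed (default 1).
#' @return a \linkS4class{PlantSceneSpec}.
#' @export
PlantSceneSpec <- function(nLeaves = 6L, leafSemiAxesMm = c(32.5, 20.5),
                           leafSizeCv = 0.015, leafBendDeg = 20,
                           occlusionLevel = "none", nNewborn = 0L,
                           newbornScale = 0.15, dropoutFraction = 0,
                           tableSizeMm = 400, potHeightMm = 80,
                           meshResolutionMm = 1.5, vertexNoiseMm = 0.05,
                           rngSeed = 1L) {
  new("PlantSceneSpec", nLeaves = as.integer(nLeaves),
      leafSemiAxesMm = leafSemiAxesMm, leafSizeCv = leafSizeCv,
      leafBendDeg = leafBendDeg, occlusionLevel = occlusionLevel,
      nNewborn = as.integer(nNewborn), newbornScale = newbornScale,
      dropoutFraction = dropoutFraction, tableSizeMm = tableSizeMm,
      potHeightMm = potHeightMm, meshResolutionMm = meshResolutionMm,
      vertexNoiseMm = vertexNoiseMm, rngSeed = as.integer(rngSeed))
}

# triangulate the strip between two parallel columns of points given their
# 1D positions; returns triangles as (column, index) pairs resolved to the
# provided global ids
.strip_triangulate <- function(idsA, yA, idsB, yB) {
  na <- length(idsA); nb <- length(idsB)
  tris <- matrix(integer(0), 0, 3)
  i <- 1L; j <- 1L
  while (i < na || j < nb) {
    adv_a <- FALSE
    if (i < na && j < nb) {
      # connect by the shorter diagonal
      adv_a <- abs(yA[i + 1L] - yB[j]) <= abs(yB[j + 1L] - yA[i])
    } else if (i < na) adv_a <- TRUE
    if (adv_a) {
      tris <- rbind(tris, c(idsA[i], idsA[i + 1L], idsB[j]))
      i <- i + 1L
    } else {
      tris <- rbind(tris, c(idsA[i], idsB[j + 1L], idsB[j]))
      j <- j + 1L
    }
  }
  tris
}

#' Generate one parametric leaf
#'
#' A broad elliptical leaf surface triangulated at the requested resolution.
#' The ellipse with semi-axes \code{aMm} (along the midrib) and \code{bMm} is
#' optionally bent about the midrib by \code{bendDeg} (arc-length preserving,
#' so the true length stays 2a) and cupped transversely with the same radius.
#' The returned trait vector holds the true traits computed numerically from
#' the construction: mesh surface area, boundary length, midrib arc length,
#' and the longest transverse cross-section arc.
#'
#' @param aMm semi-major axis (mm), along the midrib.
#' @param bMm semi-minor axis (mm); requires \code{aMm >= bMm > 0}.
#' @param bendDeg total midrib bend (degrees).
#' @param resolutionMm target vertex spacing; must be at most \code{bMm / 4}.
#' @param curl apply the transverse cupping (default TRUE when bent).
#' @return list with \code{mesh} (\linkS4class{TriangleMesh}),
#'   \code{traits} (\linkS4class{LeafTraits} ground truth) and
#'   \code{midrib} (vertex ids of the midrib polyline).
#' @export
generateLeaf <- function(aMm, bMm, bendDeg = 0, resolutionMm,
                         curl = bendDeg > 0) {
  if (!(aMm >= bMm && bMm > 0)) stop("need aMm >= bMm > 0", call. = FALSE)
  if (resolutionMm > bMm / 4)
    stop(sprintf("resolution error: %.2f mm is coarser than b/4 = %.2f mm",
                 resolutionMm, bMm / 4), call. = FALSE)
  h <- resolutionMm
  ncol_ <- 2L * ceiling(aMm / h) + 1L
  xs <- seq(-aMm, aMm, length.out = ncol_)
  cols <- vector("list", ncol_)
  V <- NULL
  nv <- 0L
  for (j in seq_len(ncol_)) {
    ymax <- bMm * sqrt(max(0, 1 - (xs[j] / aMm)^2))
    ny <- if (ymax <= 0) 1L else 2L * ceiling(ymax / h) + 1L
    ys <- if (ny == 1L) 0 else seq(-ymax, ymax, length.out = ny)
    ids <- nv + seq_len(ny)
    storage.mode(ids) <- "integer"
    nv <- nv + ny
    cols[[j]] <- list(ids = ids, ys = ys)
    V <- rbind(V, cbind(xs[j], ys, 0))
  }
  F <- NULL
  for (j in seq_len(ncol_ - 1L)) {
    F <- rbind(F, .strip_triangulate(cols[[j]]$ids, cols[[j]]$ys,
                                     cols[[j + 1L]]$ids, cols[[j + 1L]]$ys))
  }
  # bend about the midrib (arc-length preserving) and transverse cupping
  if (bendDeg > 0) {
    theta <- bendDeg * pi / 180
    Rb <- 2 * aMm / theta
    s <- V[, 1]
    V <- cbind(Rb * sin(s / Rb), V[, 2], Rb * (1 - cos(s / Rb)))
    if (curl) {
      # cup across the midrib with the same radius, displacing along the
      # local surface normal (-sin, 0, cos) of the bent sheet
      sag <- Rb * (1 - cos(V[, 2] / Rb))
      V <- cbind(V[, 1] - sag * sin(s / Rb), V[, 2],
                 V[, 3] + sag * cos(s / Rb))
    }
  }
  mesh <- TriangleMesh(V, F)

  # ground truth, numerically from the construction
  mid_ids <- vapply(cols, function(cl) cl$ids[(length(cl$ids) + 1L) %/% 2L], 0L)
  midP <- mesh@vertices[mid_ids, , drop = FALSE]
  l_true <- sum(sqrt(rowSums((midP[-1, , drop = FALSE] -
                              midP[-nrow(midP), , drop = FALSE])^2)))
  w_true <- max(vapply(cols, function(cl) {
    if (length(cl$ids) < 2L) return(0)
    P <- mesh@vertices[cl$ids, , drop = FALSE]
    sum(sqrt(rowSums((P[-1, , drop = FALSE] - P[-nrow(P), , drop = FALSE])^2)))
  }, 0))
  s_true <- leafArea(mesh)
  c_true <- leafPerimeter(mesh)
  list(mesh = mesh, traits = LeafTraits(s_true, c_true, l_true, w_true),
       midrib = mid_ids)
}

# ---------------------------------------------------------------------------
# scene assembly helpers
# ---------------------------------------------------------------------------

.rot_z <- function(phi) rbind(c(cos(phi), -sin(phi), 0),
                              c(sin(phi), cos(phi), 0), c(0, 0, 1))
.rot_y <- function(psi) rbind(c(cos(psi), 0, sin(psi)), c(0, 1, 0),
                              c(-sin(psi), 0, cos(psi)))

.table_mesh <- function(size, step) {
  g <- seq(-size / 2, size / 2, by = step)
  n <- length(g)
  V <- cbind(rep(g, each = n), rep(g, n), 0)
  idx <- function(i, j) (i - 1L) * n + j
  F <- NULL
  for (i in seq_len(n - 1L)) {
    j <- seq_len(n - 1L)
    F <- rbind(F,
               cbind(idx(i, j), idx(i + 1L, j), idx(i + 1L, j + 1L)),
               cbind(idx(i, j), idx(i + 1L, j + 1L), idx(i, j + 1L)))
  }
  TriangleMesh(V, F)
}

.pot_mesh <- function(radius, height, step) {
  nphi <- max(12L, ceiling(2 * pi * radius / step))
  nz <- max(2L, ceiling(height / step) + 1L)
  phis <- seq(0, 2 * pi, length.out = nphi + 1L)[-(nphi + 1L)]
  zs <- seq(0, height, length.out = nz)
  V <- NULL
  for (z in zs) V <- rbind(V, cbind(radius * cos(phis), radius * sin(phis), z))
  F <- NULL
  for (i in seq_len(nz - 1L)) {
    for (j in seq_len(nphi)) {
      j2 <- if (j == nphi) 1L else j + 1L
      a <- (i - 1L) * nphi + j; b <- (i - 1L) * nphi + j2
      c_ <- i * nphi + j; d <- i * nphi + j2
      F <- rbind(F, c(a, b, d), c(a, d, c_))
    }
  }
  # soil disc on top
  ctr <- nrow(V) + 1L
  V <- rbind(V, c(0, 0, height))
  top0 <- (nz - 1L) * nphi
  for (j in seq_len(nphi)) {
    j2 <- if (j == nphi) 1L else j + 1L
    F <- rbind(F, c(top0 + j, top0 + j2, ctr))
  }
  TriangleMesh(V, F)
}

.stem_mesh <- function(phi, r0, z0, z1, width, step) {
  # thin ribbon from the pot rim rising outward; stays below the buffer
  nseg <- max(2L, ceiling((z1 - z0) / step))
  tpar <- seq(0, 1, length.out = nseg + 1L)
  cx <- (r0 + 12 * tpar) * cos(phi)
  cy <- (r0 + 12 * tpar) * sin(phi)
  cz <- z0 + (z1 - z0) * tpar
  # ribbon across the tangential direction
  tx <- -sin(phi) * width / 2; ty <- cos(phi) * width / 2
  V <- rbind(cbind(cx - tx, cy - ty, cz), cbind(cx + tx, cy + ty, cz))
  n <- nseg + 1L
  F <- NULL
  for (i in seq_len(nseg)) {
    F <- rbind(F, c(i, i + 1L, n + i), c(i + 1L, n + i + 1L, n + i))
  }
  TriangleMesh(V, F)
}

# convex hull point-in-polygon test for the projected overlap measure;
# orientation-agnostic (signed-area check)
.in_hull2d <- function(P, hull) {
  if (nrow(hull) < 3L) return(rep(FALSE, nrow(P)))
  nh <- nrow(hull)
  nxt <- c(seq_len(nh)[-1], 1L)
  area2 <- sum(hull[, 1] * hull[nxt, 2] - hull[nxt, 1] * hull[, 2])
  sgn <- if (area2 >= 0) 1 else -1
  inside <- rep(TRUE, nrow(P))
  for (i in seq_len(nh)) {
    a <- hull[i, ]; b <- hull[nxt[i], ]
    cr <- (b[1] - a[1]) * (P[, 2] - a[2]) - (b[2] - a[2]) * (P[, 1] - a[1])
    inside <- inside & (sgn * cr >= 0)
  }
  inside
}

# mean fraction of each mature leaf's vertices lying inside another mature
# leaf's projected hull
.scene_overlap <- function(placed) {
  n <- length(placed)
  if (n < 2L) return(0)
  hulls <- lapply(placed, function(p) {
    XY <- p[, 1:2, drop = FALSE]
    XY[grDevices::chull(XY), , drop = FALSE]
  })
  fr <- vapply(seq_len(n), function(i) {
    XY <- placed[[i]][, 1:2, drop = FALSE]
    covered <- rep(FALSE, nrow(XY))
    for (j in seq_len(n)) {
      if (j == i) next
      covered <- covered | .in_hull2d(XY, hulls[[j]])
    }
    mean(covered)
  }, 0)
  mean(fr)
}

.bbox_overlap_any <- function(placed) {
  n <- length(placed)
  if (n < 2L) return(FALSE)
  boxes <- lapply(placed, function(p) apply(p[, 1:2, drop = FALSE], 2, range))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    bi <- boxes[[i]]; bj <- boxes[[j]]
    if (bi[1, 1] <= bj[2, 1] && bj[1, 1] <= bi[2, 1] &&
        bi[1, 2] <= bj[2, 2] && bj[1, 2] <= bi[2, 2]) return(TRUE)
  }
  FALSE
}

#' Generate a scanner-like plant scene with a ground-truth ledger
#'
#' Builds a complete scene: a table plane at z = 0, a pot with soil below the
#' 100 mm preprocessing buffer, short petiole stubs (also below the buffer:
#' thin petioles scan poorly and are usually missing from hand-held scans),
#' and leaves placed on a phyllotactic spiral. The spiral radius is tuned by
#' bisection until the mean projected leaf-overlap fraction matches the
#' occlusion level's target (none 0, little 0.05, medium 0.15, heavy 0.30);
#' under occlusion, leaf pairs that come into contact are welded vertex to
#' vertex, emulating the fused surfaces of attached leaves. Newborn leaves
#' are small and strongly curled; dropout deletes connected face patches to
#' mimic scan shadowing. Gaussian jitter emulates scanner measurement noise.
#' The same spec always produces the identical scene.
#'
#' @param spec a \linkS4class{PlantSceneSpec}.
#' @return list with \code{mesh} (the scene \linkS4class{TriangleMesh}) and
#'   \code{ledger} (ground truth: per-leaf face/vertex ids in the scene mesh,
#'   typicality flags, true traits; table plane; counts n0/n1; achieved
#'   overlap).
#' @export
generatePlantScene <- function(spec) {
  stopifnot(is(spec, "PlantSceneSpec"))
  .with_local_seed(spec@rngSeed, .generate_scene_impl(spec))
}

.generate_scene_impl <- function(spec) {
  res <- spec@meshResolutionMm
  a0 <- spec@leafSemiAxesMm[1]; b0 <- spec@leafSemiAxesMm[2]
  n <- spec@nLeaves
  nb <- spec@nNewborn
  ntot <- n + nb

  # --- leaf geometry in local coordinates ---
  cv <- spec@leafSizeCv
  scale_k <- 1 + pmin(2 * cv, pmax(-2 * cv, stats::rnorm(ntot, 0, cv)))
  scale_k[n + seq_len(nb)] <- spec@newbornScale *
    pmax(0.6, stats::rnorm(nb, 1, 0.1))
  bend_k <- spec@leafBendDeg * stats::runif(ntot, 0.85, 1.15)
  # newborn curl is kept just-resolvable at the emulated scan resolution so
  # the newborn forms a cluster and is rejected by the size band
  bend_k[n + seq_len(nb)] <- 5
  leaves <- vector("list", ntot)
  for (k in seq_len(ntot)) {
    ak <- a0 * scale_k[k]; bk <- b0 * scale_k[k]
    rk <- min(res, bk / 4)
    leaves[[k]] <- generateLeaf(ak, bk, bend_k[k], rk)
  }

  # --- placement on a phyllotactic spiral ---
  golden <- 137.50776 * pi / 180
  phi_k <- (seq_len(ntot) - 1L) * golden + stats::rnorm(ntot, 0, 0.06)
  pitch_k <- (-10 + stats::rnorm(ntot, 0, 3)) * pi / 180
  dz <- switch(spec@occlusionLevel, none = 22, little = 12, medium = 8,
               heavy = 5)
  zjit <- switch(spec@occlusionLevel, none = 1.5, little = 1.5, medium = 2,
                 heavy = 2.5)
  # shuffled height order: angularly close leaves can also be height
  # neighbours, as on a real plant (a strict spiral would keep overlapping
  # leaves far apart vertically and no canopy contact would ever occur)
  z_k <- 150 + (sample.int(ntot) - 1L) * dz + stats::rnorm(ntot, 0, zjit)
  rad_jit <- stats::runif(ntot, 0.9, 1.1)

  place <- function(s) {
    lapply(seq_len(ntot), function(k) {
      d <- s * 0.9 * a0 * rad_jit[k] * (if (k > n) 0.4 else 1)
      R <- .rot_z(phi_k[k]) %*% .rot_y(-pitch_k[k])
      ctr <- c(d * cos(phi_k[k]), d * sin(phi_k[k]), z_k[k])
      sweep(leaves[[k]]$mesh@vertices %*% t(R), 2, ctr, `+`)
    })
  }

  target <- switch(spec@occlusionLevel, none = 0, little = 0.05,
                   medium = 0.15, heavy = 0.30)
  if (target == 0) {
    s <- 1.0
    ok <- FALSE
    for (it in seq_len(60L)) {
      placed <- place(s)
      if (!.bbox_overlap_any(placed[seq_len(n)])) { ok <- TRUE; break }
      s <- s * 1.12
    }
    if (!ok) stop("generation error: could not separate leaves (bbox overlap persists)",
                  call. = FALSE)
  } else {
    lo <- 0.1; hi <- 2.5
    f_lo <- .scene_overlap(place(lo)[seq_len(n)])
    if (f_lo < target)
      stop(sprintf(
        "generation error: overlap target %.2f infeasible (max achievable %.3f)",
        target, f_lo), call. = FALSE)
    for (it in seq_len(18L)) {
      mid <- (lo + hi) / 2
      f_mid <- .scene_overlap(place(mid)[seq_len(n)])
      if (f_mid > target) lo <- mid else hi <- mid
    }
    s <- (lo + hi) / 2
    placed <- place(s)
    achieved <- .scene_overlap(placed[seq_len(n)])
    if (abs(achieved - target) > 0.06)
      stop(sprintf(
        "generation error: overlap tuning missed target %.2f (achieved %.3f)",
        target, achieved), call. = FALSE)
  }
  placed <- place(s)
  achieved <- .scene_overlap(placed[seq_len(n)])

  # --- scan shadowing: canopy overlap hides the covered part of the lower
  # leaf from the scanner when the vertical gap is tight; those faces are
  # never acquired. This is the dominant occlusion failure mode of
  # hand-held scanning (incomplete data, not merged geometry). ---
  shadow_gap <- 10
  shadow_frac <- numeric(ntot)
  shadowed_v <- vector("list", ntot)
  if (target > 0 && n >= 2L) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      up <- if (z_k[i] >= z_k[j]) i else j
      lo_ <- if (up == i) j else i
      Pu <- placed[[up]]; Pl <- placed[[lo_]]
      hull_u <- Pu[grDevices::chull(Pu[, 1:2]), 1:2, drop = FALSE]
      cand <- which(.in_hull2d(Pl[, 1:2, drop = FALSE], hull_u))
      if (length(cand) == 0L) next
      # vertical gap to the covering surface, via the nearest-in-XY vertex
      D2 <- outer(rowSums(Pl[cand, 1:2, drop = FALSE]^2),
                  rowSums(Pu[, 1:2, drop = FALSE]^2), `+`) -
        2 * Pl[cand, 1:2, drop = FALSE] %*% t(Pu[, 1:2, drop = FALSE])
      nn <- max.col(-D2, ties.method = "first")
      gap <- Pu[nn, 3] - Pl[cand, 3]
      hit <- cand[gap > 0 & gap < shadow_gap]
      if (length(hit) > 0L)
        shadowed_v[[lo_]] <- union(shadowed_v[[lo_]], hit)
    }
  }

  # --- combine leaves into one vertex pool, then weld contacts ---
  offs <- cumsum(c(0L, vapply(placed, nrow, 0L)))
  LV <- do.call(rbind, placed)
  LF <- do.call(rbind, lapply(seq_len(ntot), function(k)
    leaves[[k]]$mesh@faces + offs[k]))
  face_leaf <- rep(seq_len(ntot),
                   vapply(leaves, function(l) nrow(l$mesh@faces), 0L))

  # drop shadowed faces (all three vertices hidden)
  if (any(lengths(shadowed_v) > 0L)) {
    hidden <- logical(nrow(LV))
    for (k in seq_len(ntot))
      if (length(shadowed_v[[k]]) > 0L)
        hidden[offs[k] + shadowed_v[[k]]] <- TRUE
    drop_f <- hidden[LF[, 1]] & hidden[LF[, 2]] & hidden[LF[, 3]]
    for (k in seq_len(ntot)) {
      fk <- face_leaf == k
      shadow_frac[k] <- sum(drop_f & fk) / max(1L, sum(fk))
    }
    LF <- LF[!drop_f, , drop = FALSE]
    face_leaf <- face_leaf[!drop_f]
  }

  remap <- seq_len(nrow(LV))
  if (target > 0) {
    # mild contact welding: where two acquired surfaces nearly touch, the
    # scanner fuses them; the dominant occlusion effect is the shadowing
    # above, so welding stays local
    weld_reach <- 2.5
    weld_cap <- 8L
    for (i in seq_len(max(0, n - 1L))) for (j in (i + 1L):n) {
      Pi <- placed[[i]]; Pj <- placed[[j]]
      hull_j <- Pj[grDevices::chull(Pj[, 1:2]), 1:2, drop = FALSE]
      hull_i <- Pi[grDevices::chull(Pi[, 1:2]), 1:2, drop = FALSE]
      ci <- which(.in_hull2d(Pi[, 1:2, drop = FALSE], hull_j))
      cj <- which(.in_hull2d(Pj[, 1:2, drop = FALSE], hull_i))
      if (length(ci) == 0L || length(cj) == 0L) next
      D2 <- outer(rowSums(Pi[ci, , drop = FALSE]^2),
                  rowSums(Pj[cj, , drop = FALSE]^2), `+`) -
        2 * Pi[ci, , drop = FALSE] %*% t(Pj[cj, , drop = FALSE])
      cand <- which(D2 < weld_reach^2, arr.ind = TRUE)
      if (nrow(cand) == 0L) next
      cand <- cand[order(D2[cand]), , drop = FALSE]
      used_i <- integer(0); used_j <- integer(0)
      nweld <- 0L
      for (r in seq_len(nrow(cand))) {
        ui <- ci[cand[r, 1]]; uj <- cj[cand[r, 2]]
        if (ui %in% used_i || uj %in% used_j) next
        gi <- offs[i] + ui; gj <- offs[j] + uj
        mid <- (LV[gi, ] + LV[gj, ]) / 2
        LV[gi, ] <- mid
        remap[gj] <- gi
        used_i <- c(used_i, ui); used_j <- c(used_j, uj)
        nweld <- nweld + 1L
        if (nweld >= weld_cap) break
      }
    }
  }
  # resolve weld chains (a vertex welded into a vertex welded elsewhere)
  while (any(remap[remap] != remap)) remap <- remap[remap]
  LF <- matrix(remap[LF], ncol = 3)
  good <- LF[, 1] != LF[, 2] & LF[, 1] != LF[, 3] & LF[, 2] != LF[, 3]
  LF <- LF[good, , drop = FALSE]
  face_leaf <- face_leaf[good]

  # --- dropout: connected shadow patches ---
  damaged <- rep(FALSE, ntot)
  if (spec@dropoutFraction > 0 && n > 0) {
    budget <- round(spec@dropoutFraction * sum(face_leaf <= n))
    order_dmg <- sample.int(n)
    drop_face <- rep(FALSE, nrow(LF))
    for (k in order_dmg) {
      if (budget <= 0) break
      fk <- which(face_leaf == k)
      patch_target <- min(budget, round(0.4 * length(fk)))
      if (patch_target < 0.05 * length(fk)) next
      # BFS over face adjacency within the leaf
      sub <- LF[fk, , drop = FALSE]
      key <- function(a, b) paste(pmin(a, b), pmax(a, b))
      ek <- c(key(sub[, 1], sub[, 2]), key(sub[, 2], sub[, 3]),
              key(sub[, 3], sub[, 1]))
      e2f <- split(rep(seq_along(fk), 3L), ek)
      adj <- vector("list", length(fk))
      for (fs in e2f) if (length(fs) == 2L) {
        adj[[fs[1]]] <- c(adj[[fs[1]]], fs[2])
        adj[[fs[2]]] <- c(adj[[fs[2]]], fs[1])
      }
      seedf <- sample.int(length(fk), 1L)
      inpatch <- logical(length(fk))
      queue <- seedf; inpatch[seedf] <- TRUE; cnt <- 1L
      while (length(queue) > 0L && cnt < patch_target) {
        cur <- queue[1]; queue <- queue[-1]
        for (nx in adj[[cur]]) {
          if (!inpatch[nx] && cnt < patch_target) {
            inpatch[nx] <- TRUE; cnt <- cnt + 1L
            queue <- c(queue, nx)
          }
        }
      }
      drop_face[fk[inpatch]] <- TRUE
      damaged[k] <- TRUE
      budget <- budget - cnt
    }
    LF <- LF[!drop_face, , drop = FALSE]
    face_leaf <- face_leaf[!drop_face]
  }

  # --- fixtures: table, pot with soil, petiole stubs (all below buffer) ---
  tab <- .table_mesh(spec@tableSizeMm, max(5, 3 * res))
  pot <- .pot_mesh(40, spec@potHeightMm, 8)
  stems <- lapply(seq_len(ntot), function(k)
    .stem_mesh(phi_k[k], 40, spec@potHeightMm - 2,
               min(95, spec@potHeightMm + 15), 3, 5))
  parts <- c(list(tab, pot), stems)
  part_labels <- c("table", "pot", rep("stem", length(stems)))

  V <- NULL; F <- NULL; flab <- character(0)
  for (p in seq_along(parts)) {
    off <- if (is.null(V)) 0L else nrow(V)
    V <- rbind(V, parts[[p]]@vertices)
    F <- rbind(F, parts[[p]]@faces + off)
    flab <- c(flab, rep(part_labels[p], nrow(parts[[p]]@faces)))
  }
  leaf_off <- nrow(V)
  V <- rbind(V, LV)
  F <- rbind(F, LF + leaf_off)
  flab <- c(flab, paste0("leaf_", face_leaf))

  # scanner jitter
  if (spec@vertexNoiseMm > 0)
    V <- V + matrix(stats::rnorm(length(V), 0, spec@vertexNoiseMm), ncol = 3)

  mesh <- TriangleMesh(V, F)

  leaf_entries <- lapply(seq_len(ntot), function(k) {
    fids <- which(flab == paste0("leaf_", k))
    vids <- sort(unique(as.vector(F[fids, , drop = FALSE])))
    list(id = k,
         newborn = k > n,
         damaged = damaged[k],
         shadow_fraction = shadow_frac[k],
         well_scanned = (k <= n) && !damaged[k] && shadow_frac[k] < 0.1,
         is_typical = (k <= n) && !damaged[k],
         face_ids = fids,
         vertex_ids = vids,
         traits = leaves[[k]]$traits@values)
  })
  n1 <- sum(vapply(leaf_entries, function(e) e$is_typical, TRUE))
  n2 <- sum(vapply(leaf_entries, function(e) e$well_scanned, TRUE))

  ledger <- list(
    leaves = leaf_entries,
    table = list(normal = c(0, 0, 1), offset = 0),
    counts = list(n0 = ntot, n1 = n1, n2 = n2),
    occlusion = list(level = spec@occlusionLevel, target = target,
                     achieved = achieved),
    face_labels = flab)
  list(mesh = mesh, ledger = ledger)
}

#' Write / read a ground-truth ledger as JSON
#'
#' @param ledger a ledger list from [generatePlantScene()].
#' @param path file path.
#' @return the path (write) or the ledger list (read).
#' @export
writeLedger <- function(ledger, path) {
  jsonlite::write_json(ledger, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeLedger
#' @export
readLedger <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
}

#' Match segmented typical leaves against a ground-truth ledger
#'
#' Each typical leaf cluster is mapped back to scene-mesh vertex ids through
#' the plant mesh's provenance and matched greedily (best overlap first) to
#' the ledger leaf with the highest Jaccard vertex overlap. Recall is the
#' fraction of the ledger's typical leaves matched at or above the overlap
#' threshold.
#'
#' @param report a \linkS4class{SegmentationReport}.
#' @param plantMesh the preprocessed plant mesh the report was computed on
#'   (must carry \code{vertexIndex} provenance into the scene mesh).
#' @param ledger the scene ledger.
#' @param minOverlap Jaccard threshold for a match (default 0.9).
#' @return list with \code{recall}, \code{matches} (data.frame cluster ->
#'   ledger leaf with overlap), \code{n_typical_truth}.
#' @export
matchLedger <- function(report, plantMesh, ledger, minOverlap = 0.9) {
  stopifnot(is(report, "SegmentationReport"), is(plantMesh, "TriangleMesh"))
  truth <- Filter(function(e) isTRUE(e$is_typical), ledger$leaves)
  n_truth <- length(truth)
  clusters <- report@typicalLeaves
  if (length(clusters) == 0L || n_truth == 0L)
    return(list(recall = if (n_truth == 0L) NA_real_ else 0,
                matches = data.frame(), n_typical_truth = n_truth))
  prov <- plantMesh@vertexIndex
  rows <- list()
  for (ci in seq_along(clusters)) {
    cvid <- clusters[[ci]]@vertexIds
    orig <- if (length(prov) > 0) prov[cvid] else cvid
    for (ti in seq_len(n_truth)) {
      tv <- unlist(truth[[ti]]$vertex_ids)
      ov <- length(intersect(orig, tv)) / length(union(orig, tv))
      rows[[length(rows) + 1L]] <- data.frame(cluster = ci, leaf = ti,
                                              overlap = ov)
    }
  }
  tab <- do.call(rbind, rows)
  tab <- tab[order(-tab$overlap), ]
  used_c <- integer(0); used_t <- integer(0)
  matches <- tab[0, ]
  for (r in seq_len(nrow(tab))) {
    if (tab$overlap[r] < minOverlap) break
    if (tab$cluster[r] %in% used_c || tab$leaf[r] %in% used_t) next
    matches <- rbind(matches, tab[r, ])
    used_c <- c(used_c, tab$cluster[r]); used_t <- c(used_t, tab$leaf[r])
  }
  list(recall = nrow(matches) / n_truth, matches = matches,
       n_typical_truth = n_truth)
}
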