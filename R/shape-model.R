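# Coerce a list of LeafTraits / named vectors / data.frame into a numeric
# matrix with the ten canonical trait columns.
.trait_matrix <- function(trait_rows) {
  if (is(trait_rows, "LeafTraits")) trait_rows <- list(trait_rows)
  if (is.data.frame(trait_rows) || is.matrix(trait_rows)) {
    M <- as.matrix(trait_rows)
    if (!all(.trait_names %in% colnames(M)))
      stop("trait table must have columns ", paste(.trait_names, collapse = ", "),
           call. = FALSE)
    return(M[, .trait_names, drop = FALSE])
  }
  M <- do.call(rbind, lapply(trait_rows, function(r) {
    if (is(r, "LeafTraits")) r@values else r[.trait_names]
  }))
  colnames(M) <- .trait_names
  M
}

# variance contribution rates: normalized eigenvalue spectrum of the
# correlation matrix, sorted descending; equal weights when PCA is not
# meaningful (fewer than 5 rows, or zero variance in any trait)
.vcr_weights <- function(M) {
  p <- ncol(M)
  if (nrow(M) < 5L) return(rep(1 / p, p))
  sds <- apply(M, 2, stats::sd)
  if (any(sds < 1e-12)) return(rep(1 / p, p))
  lam <- eigen(stats::cor(M), symmetric = TRUE, only.values = TRUE)$values
  lam <- pmax(lam, 0)
  sort(lam / sum(lam), decreasing = TRUE)
}

#' Fit the two PCA-weighted leaf shape models
#'
#' The size model weights a_1..a_4 are the variance contribution rates of a
#' PCA on the correlation-scaled scale traits (area, perimeter, length,
#' width) across the fitting clusters, and the architecture weights b_1..b_6
#' likewise for the six ratio traits; both weight vectors sum to 1. The
#' correlation scaling stops the mm^2-valued area from dominating the
#' mm-valued traits. With fewer than 5 fitting clusters (or zero variance)
#' the spectrum is unstable and equal weights are used instead. A model fit
#' on fewer than 2 clusters is flagged degenerate: no filtering is possible,
#' and [detectTypical()] accepts everything against it.
#'
#' @param traitRows a list of \linkS4class{LeafTraits}, or a data.frame /
#'   matrix with the ten trait columns.
#' @return a \linkS4class{ShapeModel}.
#' @seealso [scoreF()], [scoreG()], [detectTypical()]
#' @export
fitShapeModel <- function(traitRows) {
  M <- .trait_matrix(traitRows)
  if (nrow(M) < 1L) stop("input error: no trait rows", call. = FALSE)
  if (any(!is.finite(M)) || any(M <= 0))
    stop("input error: non-positive trait value", call. = FALSE)
  wa <- .vcr_weights(M[, 1:4, drop = FALSE])
  wb <- .vcr_weights(M[, 5:10, drop = FALSE])
  S <- colMeans(M[, 1:4, drop = FALSE])
  G <- as.numeric(M[, 5:10, drop = FALSE] %*% wb)
  fallback <- nrow(M) < 5L || any(apply(M, 2, stats::sd) < 1e-12)
  new("ShapeModel", a = wa, b = wb, meanScale = S, meanG = mean(G),
      band = c(0.25, 1.25), nFit = nrow(M),
      degenerate = nrow(M) < 2L, weightsFallback = fallback)
}

#' Size score F(X)
#'
#' F(X) = sum_i a_i (X0i - mean_i) / mean_i over the four scale traits: the
#' weighted relative deviation of the leaf's size from the fitting-set mean.
#' F = 0 at the mean and F = 1 when every trait doubles (the weights sum
#' to 1).
#'
#' @param traits a \linkS4class{LeafTraits}.
#' @param model a \linkS4class{ShapeModel}.
#' @return dimensionless scalar.
#' @export
scoreF <- function(traits, model) {
  stopifnot(is(traits, "LeafTraits"), is(model, "ShapeModel"))
  x <- traits@values[1:4]
  if (any(model@meanScale <= 0))
    stop("division error: zero mean trait", call. = FALSE)
  sum(model@a * (x - model@meanScale) / model@meanScale)
}

#' Architecture score G(X)
#'
#' G(X) = sum_j b_j X1j: the weighted sum of the six ratio traits, mixing
#' mm-valued and dimensionless ratios as defined.
#'
#' @inheritParams scoreF
#' @return scalar.
#' @export
scoreG <- function(traits, model) {
  stopifnot(is(traits, "LeafTraits"), is(model, "ShapeModel"))
  sum(model@b * traits@values[5:10])
}

#' Typical-leaf detection H(X)
#'
#' A cluster is a typical leaf sample when both the size test and the shape
#' test pass. The size test requires the shifted size score 1 + F(X) to fall
#' strictly inside (0.25, 1.25) (the fitting-set mean has 1 + F = 1 exactly,
#' since the weights sum to one); the shape test requires G(X) to fall
#' strictly inside (0.25, 1.25) times the fitting-set mean of G. A degenerate
#' model (fewer than 2 fitting clusters) accepts everything, with the reason
#' recorded.
#'
#' @inheritParams scoreF
#' @return a \linkS4class{DetectionResult}.
#' @export
detectTypical <- function(traits, model) {
  stopifnot(is(traits, "LeafTraits"), is(model, "ShapeModel"))
  f <- scoreF(traits, model)
  g <- scoreG(traits, model)
  if (model@degenerate)
    return(new("DetectionResult", fScore = f, gScore = g, isTypical = TRUE,
               reason = "degenerate_model"))
  lo <- model@band[1]; hi <- model@band[2]
  if (!(1 + f > lo && 1 + f < hi))
    return(new("DetectionResult", fScore = f, gScore = g, isTypical = FALSE,
               reason = "size_out_of_band"))
  if (!(g > lo * model@meanG && g < hi * model@meanG))
    return(new("DetectionResult", fScore = f, gScore = g, isTypical = FALSE,
               reason = "shape_out_of_band"))
  new("DetectionResult", fScore = f, gScore = g, isTypical = TRUE,
      reason = "pass")
}

#' Serialize / deserialize a shape model to JSON
#'
#' @param model a \linkS4class{ShapeModel}.
#' @param path file path.
#' @return \code{writeShapeModel}: the path, invisibly.
#'   \code{readShapeModel}: the model.
#' @export
writeShapeModel <- function(model, path) {
  stopifnot(is(model, "ShapeModel"))
  obj <- list(a = model@a, b = model@b,
              mean_scale = as.list(stats::setNames(model@meanScale,
                                                   .trait_names[1:4])),
              mean_g = model@meanG, band = model@band, n_fit = model@nFit,
              degenerate = model@degenerate,
              weights_fallback = model@weightsFallback)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeShapeModel
#' @export
readShapeModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("ShapeModel", a = as.numeric(obj$a), b = as.numeric(obj$b),
      meanScale = as.numeric(unlist(obj$mean_scale)),
      meanG = as.numeric(obj$mean_g), band = as.numeric(obj$band),
      nFit = as.integer(obj$n_fit), degenerate = isTRUE(obj$degenerate),
      weightsFallback = isTRUE(obj$weights_fallback))
}
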