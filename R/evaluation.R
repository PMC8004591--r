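# percentages are reported to 2 decimals, half-up, matching the convention
# of printed accuracy tables
.round2_half_up <- function(x) floor(x * 100 + 0.5) / 100

#' Scanning and segmentation accuracy ratios
#'
#' From the counts of manually selected (\code{n1}), well-scanned
#' (\code{n2}) and automatically selected (\code{n3}) typical leaf samples:
#' R_scan = 100 n2/n1, R_seg1 = 100 n3/n2, R_seg2 = 100 n3/n1, each reported
#' to two decimals (half-up).
#'
#' @param n1 manually selected typical leaves (> 0).
#' @param n2 well-scanned typical leaves (> 0).
#' @param n3 automatically selected typical leaves.
#' @param round report to 2 decimals (default TRUE).
#' @return named numeric: \code{r_scan}, \code{r_seg1}, \code{r_seg2}
#'   (percentages).
#' @examples
#' accuracyRatios(234, 220, 205)
#' @export
accuracyRatios <- function(n1, n2, n3, round = TRUE) {
  if (any(c(n1, n2, n3) < 0) || any(c(n1, n2, n3) != round(c(n1, n2, n3))))
    stop("input error: counts must be non-negative integers", call. = FALSE)
  if (n1 == 0 || n2 == 0)
    stop("input error: zero denominator count", call. = FALSE)
  out <- c(r_scan = 100 * n2 / n1, r_seg1 = 100 * n3 / n2,
           r_seg2 = 100 * n3 / n1)
  if (round) .round2_half_up(out) else out
}

#' Modeling efficiency EF
#'
#' EF = 1 - sum((y - x)^2) / sum((y - mean(y))^2): 1 for perfect agreement,
#' 0 for the mean predictor, negative when the estimates are worse than the
#' mean predictor.
#'
#' @param x estimates.
#' @param y observations (not all equal).
#' @return dimensionless scalar, at most 1.
#' @export
modelingEfficiency <- function(x, y) {
  if (length(x) != length(y)) stop("input error: length mismatch", call. = FALSE)
  if (length(y) < 2L) stop("input error: need n >= 2", call. = FALSE)
  sst <- sum((y - mean(y))^2)
  if (sst <= 0)
    stop("undefined-variance error: observations are constant", call. = FALSE)
  1 - sum((y - x)^2) / sst
}

#' Root-mean-square error
#'
#' @param xm manual (reference) measurements.
#' @param xa automatic measurements.
#' @return RMSE in the units of the trait.
#' @export
rmse <- function(xm, xa) {
  if (length(xm) != length(xa)) stop("input error: length mismatch", call. = FALSE)
  if (length(xm) < 1L) stop("input error: empty input", call. = FALSE)
  sqrt(mean((xm - xa)^2))
}

#' Mean absolute percentage error
#'
#' @param xm manual (reference) measurements, all nonzero.
#' @param xa automatic measurements.
#' @return MAPE as a percentage.
#' @export
mape <- function(xm, xa) {
  if (length(xm) != length(xa)) stop("input error: length mismatch", call. = FALSE)
  if (any(xm == 0)) stop("division error: zero manual value", call. = FALSE)
  100 * mean(abs((xm - xa) / xm))
}

#' Per-trait accuracy table
#'
#' Computes EF, RMSE and MAPE for each shared trait column of an automatic
#' and a reference trait table (as produced by [traitTable()] or read from
#' the trait CSV).
#'
#' @param pred data.frame of automatic traits.
#' @param ref data.frame of reference traits (same leaves, same order).
#' @param columns trait columns to compare (default: the ten traits).
#' @return data.frame with one row per trait: ef, rmse, mape.
#' @export
traitAccuracy <- function(pred, ref, columns = .trait_names) {
  columns <- intersect(columns, intersect(colnames(pred), colnames(ref)))
  if (length(columns) == 0L)
    stop("input error: no shared trait columns", call. = FALSE)
  out <- lapply(columns, function(cl) {
    data.frame(trait = cl,
               ef = modelingEfficiency(pred[[cl]], ref[[cl]]),
               rmse = rmse(ref[[cl]], pred[[cl]]),
               mape = mape(ref[[cl]], pred[[cl]]))
  })
  do.call(rbind, out)
}

#' Example segmentation counts for twelve pothos plants
#'
#' Loads the bundled benchmark table of per-plant leaf counts for four
#' occlusion groups (no / a little / medium / heavy canopy occlusion, three
#' plants each): total leaves (n0), manually selected typical leaves (n1),
#' well-scanned typical leaves (n2), automatically selected typical leaves
#' (n3), and the published accuracy percentages they imply.
#'
#' @return data.frame with columns group, plant, n0, n1, n2, n3, r_scan,
#'   r_seg1, r_seg2.
#' @examples
#' counts <- segmentationCounts()
#' accuracyRatios(sum(counts$n1), sum(counts$n2), sum(counts$n3))
#' @export
segmentationCounts <- function() {
  path <- system.file("extdata", "segmentation_counts.csv",
                      package = "leafMorph", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Group-average accuracy ratios
#'
#' Per-group means of the unrounded per-plant accuracy ratios (rounded to two
#' decimals at the end), the convention used for the published group
#' averages.
#'
#' @param counts data.frame as returned by [segmentationCounts()].
#' @return data.frame with columns group, r1, r2, r3.
#' @export
groupAccuracy <- function(counts) {
  groups <- sort(unique(counts$group))
  out <- lapply(groups, function(g) {
    d <- counts[counts$group == g, ]
    r <- vapply(seq_len(nrow(d)), function(i)
      accuracyRatios(d$n1[i], d$n2[i], d$n3[i], round = FALSE), numeric(3))
    data.frame(group = g, r1 = .round2_half_up(mean(r[1, ])),
               r2 = .round2_half_up(mean(r[2, ])),
               r3 = .round2_half_up(mean(r[3, ])))
  })
  do.call(rbind, out)
}
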