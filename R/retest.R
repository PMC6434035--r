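#' Dice overlap of two activation masks
#'
#' D = 2 |A1 and A2| / (|A1| + |A2|), on thresholded activation masks.
#'
#' @param maskA,maskB logical arrays on the same grid; at least one must
#'   be nonempty
#' @return Dice coefficient in [0, 1]
#' @export
diceCoefficient <- function(maskA, maskB) {
  stopifnot(identical(dim(maskA), dim(maskB)))
  nA <- sum(maskA)
  nB <- sum(maskB)
  if (nA + nB == 0L) .stopf("Dice is undefined for two empty masks")
  2 * sum(maskA & maskB) / (nA + nB)
}

#' Voxelwise repeatability index of two maps
#'
#' Repeatability = 1 - mean over voxels of |x1 - x2| / |x1 + x2|. Voxels
#' where the two values sum to zero (undefined ratio) or where either
#' value is missing are excluded and counted.
#'
#' @param map1,map2 3-D maps on the same grid
#' @param mask logical mask of voxels to include
#' @return list with `repeatability`, `nUsed` and `nExcluded`
#' @export
repeatabilityIndex <- function(map1, map2, mask = NULL) {
  stopifnot(identical(dim(map1), dim(map2)))
  if (is.null(mask)) mask <- array(TRUE, dim(map1))
  x1 <- map1[mask]
  x2 <- map2[mask]
  denom <- x1 + x2
  ok <- is.finite(x1) & is.finite(x2) & denom != 0
  if (!any(ok)) .stopf("all voxels excluded (zero denominators or missing)")
  rep <- 1 - mean(abs((x1[ok] - x2[ok]) / denom[ok]))
  list(repeatability = rep, nUsed = sum(ok),
       nExcluded = as.integer(sum(mask) - sum(ok)))
}

#' ICC(3,1): two-way mixed, single measures
#'
#' From the subject-by-session ANOVA decomposition of a complete balanced
#' table: ICC = (BMS - EMS) / (BMS + (k - 1) EMS), with BMS the
#' between-subject and EMS the residual mean square. Rows with missing
#' cells are dropped (listwise deletion). Zero total variance yields NA.
#'
#' @param values n_subjects x k_sessions numeric matrix
#' @return ICC(3,1) value, or NA if undefined
#' @export
icc31 <- function(values) {
  values <- as.matrix(values)
  values <- values[stats::complete.cases(values), , drop = FALSE]
  n <- nrow(values)
  k <- ncol(values)
  if (n < 2L || k < 2L) .stopf("need at least 2 subjects and 2 sessions")
  grand <- mean(values)
  rowM <- rowMeans(values)
  colM <- colMeans(values)
  ssTot <- sum((values - grand)^2)
  ssB <- k * sum((rowM - grand)^2)
  ssC <- n * sum((colM - grand)^2)
  ssE <- ssTot - ssB - ssC
  if (ssTot <= 0) return(NA_real_)
  bms <- ssB / (n - 1)
  ems <- ssE / ((n - 1) * (k - 1))
  (bms - ems) / (bms + (k - 1) * ems)
}

#' Voxelwise ICC(3,1) map
#'
#' @param values array of dimension (n_subjects, k_sessions, voxels...) --
#'   the trailing dimensions form the voxel grid
#' @return array of ICC values on the voxel grid (NA where undefined)
#' @export
icc31Map <- function(values) {
  d <- dim(values)
  stopifnot(length(d) >= 3L)
  vdim <- d[-(1:2)]
  m <- array(values, c(d[1], d[2], prod(vdim)))
  out <- vapply(seq_len(dim(m)[3]), function(v) {
    tab <- m[, , v]
    if (anyNA(tab)) {
      tab <- tab[stats::complete.cases(tab), , drop = FALSE]
      if (nrow(tab) < 2L) return(NA_real_)
    }
    icc31(tab)
  }, numeric(1))
  array(out, vdim)
}

#' Spatial correlation of two maps with Fisher z transform
#'
#' Pearson correlation over the mask voxels and z = atanh(r). Perfect
#' correlation yields an infinite z (flagged by being Inf, not an error).
#'
#' @param map1,map2 3-D maps on the same grid
#' @param mask logical mask (at least 3 voxels with finite values)
#' @return list with `r` and `z`
#' @export
spatialCorrelation <- function(map1, map2, mask = NULL) {
  stopifnot(identical(dim(map1), dim(map2)))
  if (is.null(mask)) mask <- array(TRUE, dim(map1))
  x <- map1[mask]
  y <- map2[mask]
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3L) .stopf("need at least 3 voxels with finite values")
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
    .stopf("zero variance in one of the maps")
  r <- stats::cor(x[ok], y[ok])
  list(r = r, z = atanh(r))
}

#' Fractions of GM voxels exceeding ICC thresholds
#'
#' @param iccMap voxelwise ICC array
#' @param gmMask nonempty logical mask
#' @param thresholds ICC cutoffs (defaults 0.4 and 0.6, the conventional
#'   fair/good boundaries)
#' @return named numeric vector of fractions (defined-ICC GM voxels with
#'   ICC strictly above each threshold, over all GM voxels with defined
#'   ICC)
#' @export
iccFractions <- function(iccMap, gmMask, thresholds = c(0.4, 0.6)) {
  if (!any(gmMask)) .stopf("the GM mask is empty")
  vals <- iccMap[gmMask]
  vals <- vals[is.finite(vals)]
  out <- vapply(thresholds, function(th) mean(vals > th), numeric(1))
  names(out) <- paste0("gt", thresholds)
  out
}

#' Intersection of two activation masks
#'
#' @param maskA,maskB logical arrays on the same grid
#' @return logical array of voxels active in both
#' @export
overlapMask <- function(maskA, maskB) {
  stopifnot(identical(dim(maskA), dim(maskB)))
  maskA & maskB
}

#' Summary statistics of a map over several masks
#'
#' @param map 3-D map (e.g. a t-score map)
#' @param masks named list of logical masks
#' @return data.frame with one row per mask: n, mean, sd (NA for empty
#'   masks, flagged by n = 0)
#' @export
extractStats <- function(map, masks) {
  stopifnot(is.list(masks), length(names(masks)) == length(masks))
  rows <- lapply(names(masks), function(nm) {
    v <- map[masks[[nm]]]
    v <- v[is.finite(v)]
    data.frame(mask = nm, n = length(v),
               mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) > 1L) stats::sd(v) else NA_real_)
  })
  do.call(rbind, rows)
}

#' Paired-session repeatability report
#'
#' Combines the session-level metrics for one map type: Dice overlap of
#' the two activation masks, the voxelwise repeatability index over the
#' mask, and the spatial correlation with Fisher z.
#'
#' @param active1,active2 thresholded activation masks of the two sessions
#' @param map1,map2 the maps to compare (e.g. CVR or M)
#' @param mask voxel mask for repeatability and correlation (e.g. GM)
#' @return a [RetestReport-class]
#' @export
retestReport <- function(active1, active2, map1, map2, mask) {
  rep <- repeatabilityIndex(map1, map2, mask)
  sc <- spatialCorrelation(map1, map2, mask)
  new("RetestReport", dice = diceCoefficient(active1, active2),
      repeatability = rep$repeatability,
      repeatabilityExcluded = rep$nExcluded,
      pearsonR = sc$r, fisherZ = sc$z,
      overlapMask = overlapMask(active1, active2),
      nActive1 = as.integer(sum(active1)),
      nActive2 = as.integer(sum(active2)))
}
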