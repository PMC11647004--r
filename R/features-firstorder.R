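#' Mean dose over a region
#'
#' @param volume A [dose_volume()].
#' @param region Region name.
#' @return Arithmetic mean of the in-mask voxel doses, in Gy.
#' @export
mean_dose <- function(volume, region = "whole_heart") {
  m <- region_mask(volume, region)
  mean(volume$values[m])
}

dx_grid <- c(2, 5, 10, 20, 30, 40, 50, 60, 70, 80, 90, 98)
vd_grid <- c(1, 2, 5, 10, 15, 20, 25, 30, 35, 40, 45, 50)

# Type-7 (linear interpolation) quantiles from an already-sorted vector;
# identical to stats::quantile(x, probs, type = 7).
quantile7 <- function(sorted, probs) {
  n <- length(sorted)
  h <- (n - 1) * probs + 1
  lo <- floor(h)
  hi <- ceiling(h)
  sorted[lo] + (h - lo) * (sorted[hi] - sorted[lo])
}

dv_from_sorted <- function(sorted) {
  n <- length(sorted)
  dx <- quantile7(sorted, 1 - dx_grid / 100)
  # count of voxels >= d via binary search on the sorted doses
  vd <- vapply(vd_grid, function(d)
    100 * (n - findInterval(d, sorted, left.open = TRUE)) / n, numeric(1))
  setNames(c(dx, vd), c(paste0("D_", dx_grid), paste0("V_", vd_grid)))
}

#' Dose-volume histogram indicators
#'
#' The 24 indicators summarise the cumulative dose-volume histogram of a
#' region: `D_x`, the minimum dose (Gy) received by the hottest x% of the
#' region's volume (so `D_70` is the 30% dose quantile), for
#' x in \{2, 5, 10, 20, 30, 40, 50, 60, 70, 80, 90, 98\}; and `V_d`, the
#' percentage of the region's volume receiving at least d Gy, for
#' d in \{1, 2, 5, 10, 15, 20, 25, 30, 35, 40, 45, 50\}.
#'
#' @inheritParams mean_dose
#' @return Named numeric vector of length 24 (`D_2` ... `D_98`,
#'   `V_1` ... `V_50`).
#' @export
dose_volume_indicators <- function(volume, region = "whole_heart") {
  m <- region_mask(volume, region)
  dv_from_sorted(sort(volume$values[m]))
}

firstorder_from_sorted <- function(sorted, level_counts, voxvol) {
  x <- sorted
  n <- length(x)
  p <- level_counts[level_counts > 0] / n
  mu <- sum(x) / n
  xc <- x - mu
  m2 <- sum(xc^2) / n
  m3 <- sum(xc^3) / n
  m4 <- sum(xc^4) / n
  q <- quantile7(x, c(0.10, 0.25, 0.50, 0.75, 0.90))
  inner <- x[x >= q[1] & x <= q[5]]
  energy <- sum(x^2)
  c(Energy = energy,
    TotalEnergy = voxvol * energy,
    Entropy = -sum(p * log2(p)),
    Minimum = x[1],
    `10Percentile` = q[1],
    `90Percentile` = q[5],
    Maximum = x[n],
    Mean = mu,
    Median = q[3],
    InterquartileRange = q[4] - q[2],
    Range = x[n] - x[1],
    MeanAbsoluteDeviation = sum(abs(xc)) / n,
    RobustMeanAbsoluteDeviation =
      if (length(inner)) mean(abs(inner - mean(inner))) else 0,
    RootMeanSquared = sqrt(energy / n),
    Skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    Kurtosis = if (m2 > 0) m4 / m2^2 else 0,
    Variance = m2,
    Uniformity = sum(p^2))
}

#' First-order dose-distribution statistics
#'
#' The 18 standard first-order radiomics features of the in-mask dose
#' distribution. Histogram-based features (entropy, uniformity) are computed
#' on the fixed-bin-width discretization of [discretize()]; energy uses raw
#' Gy values (total energy additionally scales by the voxel volume in mm^3).
#' Degenerate constant regions have entropy 0, uniformity 1, and zero
#' skewness/kurtosis.
#'
#' @inheritParams mean_dose
#' @param disc Optional precomputed [discretize()] result for the region.
#' @param bin_width Bin width in Gy used if `disc` is not supplied.
#' @return Named numeric vector of length 18.
#' @export
first_order_features <- function(volume, region = "whole_heart",
                                 disc = NULL, bin_width = 0.5) {
  m <- region_mask(volume, region)
  if (is.null(disc)) disc <- discretize(volume, region, bin_width)
  counts <- tabulate(disc$levels[!is.na(disc$levels)],
                     nbins = disc$n_levels)
  firstorder_from_sorted(sort(volume$values[m]), counts,
                         prod(volume$spacing))
}
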