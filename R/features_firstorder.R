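# First-order (histogram) features, IBSI-style definitions.

FIRSTORDER_NAMES <- c(
  "Energy", "TotalEnergy", "Entropy", "Minimum", "Percentile10", "Percentile90",
  "Maximum", "Mean", "Median", "InterquartileRange", "Range",
  "MeanAbsoluteDeviation", "RobustMeanAbsoluteDeviation", "RootMeanSquared",
  "Skewness", "Kurtosis", "Variance", "Uniformity")

#' First-order statistical features of a region
#'
#' The 18 first-order features: energy, total energy (energy times voxel
#' volume), histogram entropy and uniformity (computed from the discretized
#' levels), location statistics (min, percentiles, max, mean, median),
#' dispersion statistics (IQR, range, mean absolute deviation, robust MAD
#' restricted to the 10th-90th percentile band, RMS, population variance) and
#' the population skewness and (non-excess) kurtosis. Degenerate moments on a
#' constant region are 0 by convention (kurtosis included).
#'
#' @param values numeric vector of in-region (continuous) intensities.
#' @param discretized integer vector of in-region gray levels (for entropy
#'   and uniformity).
#' @param voxel_volume_mm3 voxel volume used for TotalEnergy.
#' @return named numeric vector of length 18.
#' @export
first_order_features <- function(values, discretized, voxel_volume_mm3 = 1) {
  if (length(values) < 1) stop("empty region")
  stopifnot(length(values) == length(discretized))
  n <- length(values)
  p <- tabulate(discretized)
  p <- p[p > 0] / n
  mu <- mean(values)
  m2 <- mean((values - mu)^2)
  m3 <- mean((values - mu)^3)
  m4 <- mean((values - mu)^4)
  q <- stats::quantile(values, c(0.10, 0.25, 0.5, 0.75, 0.90), names = FALSE, type = 7)
  band <- values[values >= q[1] & values <= q[5]]
  out <- c(
    Energy = sum(values^2),
    TotalEnergy = voxel_volume_mm3 * sum(values^2),
    Entropy = -sum(p * log2(p)),
    Minimum = min(values),
    Percentile10 = q[1],
    Percentile90 = q[5],
    Maximum = max(values),
    Mean = mu,
    Median = q[3],
    InterquartileRange = q[4] - q[2],
    Range = max(values) - min(values),
    MeanAbsoluteDeviation = mean(abs(values - mu)),
    RobustMeanAbsoluteDeviation = if (length(band)) mean(abs(band - mean(band))) else 0,
    RootMeanSquared = sqrt(mean(values^2)),
    Skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    Kurtosis = if (m2 > 0) m4 / m2^2 else 0,
    Variance = m2,
    Uniformity = sum(p^2)
  )
  out[FIRSTORDER_NAMES]
}
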