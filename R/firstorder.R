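# First-order (intensity-statistics) radiomic features, IBSI family.
# All moments use population (1/n) normalisation; percentiles use the
# linear-interpolation convention of stats::quantile(type = 7); uniformity
# and entropy discretise intensities with a fixed bin width from 0 (the
# recommended fixed-bin-size scheme for SUV-calibrated PET).

firstOrderNames <- c(
  "F_stat.mean", "F_stat.var", "F_stat.skew", "F_stat.kurt",
  "F_stat.median", "F_stat.min", "F_stat.10thpercentile",
  "F_stat.90thpercentile", "F_stat.max", "F_stat.iqr", "F_stat.range",
  "F_stat.mad", "F_stat.rmad", "F_stat.energy", "F_stat.rms",
  "F_stat.uniformity", "F_stat.entropy")

#' First-order intensity statistics of a voxel value set
#'
#' Computes the 17 first-order features used throughout the pipeline:
#' mean, population variance, Fisher skewness, excess kurtosis, median,
#' minimum, 10th / 90th percentile, maximum, interquartile range, range,
#' mean absolute deviation, robust mean absolute deviation (over values
#' within the closed \[P10, P90\] band, about that band's own mean), energy
#' (sum of squared values), root mean square, and discretised uniformity
#' (sum of squared bin probabilities) and entropy (bits).
#'
#' Skewness and excess kurtosis of a constant value set are defined as 0,
#' so degenerate regions do not inject NaN into downstream models.
#'
#' @param values numeric vector of SUVs (nonempty, finite).
#' @param binWidth discretisation bin width in SUV for uniformity/entropy;
#'   bins are `[k*binWidth, (k+1)*binWidth)` anchored at 0. Default 0.25.
#' @return named numeric vector of length 17.
#' @examples
#' firstOrderFeatures(c(1, 2, 3))[c("F_stat.mean", "F_stat.var")]
#' @export
firstOrderFeatures <- function(values, binWidth = 0.25) {
  if (!length(values)) stop("empty value set", call. = FALSE)
  if (!all(is.finite(values))) stop("values must be finite", call. = FALSE)
  n <- length(values)
  mu <- mean(values)
  dev <- values - mu
  m2 <- mean(dev^2)
  skew <- if (m2 > 0) mean(dev^3) / m2^1.5 else 0
  kurt <- if (m2 > 0) mean(dev^4) / m2^2 - 3 else 0
  q <- quantile(values, c(0.1, 0.25, 0.5, 0.75, 0.9), names = FALSE, type = 7)
  inBand <- values >= q[1] & values <= q[5]
  rmad <- mean(abs(values[inBand] - mean(values[inBand])))
  bins <- floor(values / binWidth)
  p <- tabulate(match(bins, unique(bins)))
  p <- p / sum(p)
  c(setNames(
    c(mu, m2, skew, kurt, q[3], min(values), q[1], q[5], max(values),
      q[4] - q[2], max(values) - min(values), mean(abs(dev)), rmad,
      sum(values^2), sqrt(mean(values^2)), sum(p^2), -sum(p * log2(p))),
    firstOrderNames))
}
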