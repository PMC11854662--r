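# Brute-force oracles coded directly from the feature definitions,
# independent of the package implementation, plus small fixture builders.

# type-7 quantile, written out from the interpolation formula
oracleQuantile <- function(x, p) {
  xs <- sort(x)
  n <- length(xs)
  h <- (n - 1) * p
  lo <- floor(h) + 1
  if (lo >= n) return(xs[n])
  xs[lo] + (h - floor(h)) * (xs[lo + 1] - xs[lo])
}

# 17 first-order features from their formulas, one by one
oracleFirstOrder <- function(x, binWidth = 0.25) {
  n <- length(x)
  mu <- sum(x) / n
  m2 <- sum((x - mu)^2) / n
  m3 <- sum((x - mu)^3) / n
  m4 <- sum((x - mu)^4) / n
  p10 <- oracleQuantile(x, 0.10); p25 <- oracleQuantile(x, 0.25)
  p50 <- oracleQuantile(x, 0.50); p75 <- oracleQuantile(x, 0.75)
  p90 <- oracleQuantile(x, 0.90)
  band <- x[x >= p10 & x <= p90]
  counts <- table(floor(x / binWidth))
  pr <- as.numeric(counts) / n
  c(mean = mu,
    var = m2,
    skew = if (m2 > 0) m3 / m2^(3 / 2) else 0,
    kurt = if (m2 > 0) m4 / m2^2 - 3 else 0,
    median = p50,
    min = min(x),
    p10 = p10,
    p90 = p90,
    max = max(x),
    iqr = p75 - p25,
    range = max(x) - min(x),
    mad = sum(abs(x - mu)) / n,
    rmad = sum(abs(band - mean(band))) / length(band),
    energy = sum(x^2),
    rms = sqrt(sum(x^2) / n),
    uniformity = sum(pr^2),
    entropy = -sum(pr * log2(pr)))
}

# rasterized ball mask: voxel centres within r (mm) of a continuous centre
ballMask <- function(radiusMm, spacing = c(1, 1, 1), offset = c(0, 0, 0),
                     marginVox = 4) {
  n <- 2 * ceiling(radiusMm / spacing) + 2 * marginVox + 1
  ctr <- (floor(n / 2)) * spacing + offset
  idx <- as.matrix(expand.grid(x = 0:(n[1] - 1), y = 0:(n[2] - 1),
                               z = 0:(n[3] - 1)))
  pos <- sweep(idx, 2, spacing, "*")
  array(rowSums(sweep(pos, 2, ctr, "-")^2) <= radiusMm^2, n)
}

# number of integer-offset voxel centres inside a sphere (enumeration)
countBallVoxels <- function(radiusMm, spacing, offset = c(0, 0, 0)) {
  r <- ceiling(radiusMm / min(spacing)) + 2
  g <- expand.grid(dx = -r:r, dy = -r:r, dz = -r:r)
  pos <- sweep(as.matrix(g), 2, spacing, "*")
  sum(rowSums(sweep(pos, 2, offset, "-")^2) <= radiusMm^2)
}

# compact phantom spec for fast tests
smallPhantomSpec <- function(seed = 1L, nLesions = 3L, ...) {
  phantomSpec(gridShape = c(44L, 44L, 36L), voxelSpacing = c(3, 3, 3),
              nLesions = nLesions, lesionRadiusRange = c(8, 13),
              liverCenter = c(11, 29, 17), liverAxes = c(24, 18, 18),
              seed = seed, ...)
}

smallCohortSpec <- function(seed = 1L, nSubjects = 8L, ...) {
  cohortSpec(nSubjects = nSubjects, seed = seed, ...)
}

# Dice coefficient between two logical masks
dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))
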