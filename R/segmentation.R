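# Liver-referenced PERCIST segmentation: a 2 cm spherical reference VOI on
# the healthy liver defines the background threshold
#   threshold = 1.5 * liver mean + 2 * liver SD,
# and the hypermetabolic lesions are the connected components of the
# supra-threshold voxels outside the liver VOI (and outside any caller-
# supplied exclusion masks, the programmatic stand-in for physician
# rejection of physiological uptake).

#' Place the 2 cm spherical healthy-liver reference VOI
#'
#' The mask contains exactly the voxels whose centres lie within
#' `diameterMm / 2` of `centerMm` (world coordinates). The reference VOI
#' must fit entirely inside the grid: a clipped liver sphere would bias the
#' background statistics, so clipping is an error.
#'
#' @param vol a [SuvVolume-class].
#' @param centerMm sphere centre in world mm (length 3).
#' @param diameterMm sphere diameter in mm; default the conventional 20 mm.
#' @return logical 3D mask.
#' @export
placeLiverVoi <- function(vol, centerMm, diameterMm = 20) {
  stopifnot(is(vol, "SuvVolume"), length(centerMm) == 3L)
  r <- diameterMm / 2
  d <- dim(vol@values)
  sp <- vol@spacing
  lo <- (centerMm - r - vol@origin) / sp   # 0-based fractional indices
  hi <- (centerMm + r - vol@origin) / sp
  if (any(lo < -0.5) || any(hi > d - 0.5))
    stop("liver reference VOI (diameter ", diameterMm,
         " mm) is clipped by the grid boundary", call. = FALSE)
  mask <- array(FALSE, dim = d)
  ilo <- pmax(0L, floor(lo)); ihi <- pmin(d - 1L, ceiling(hi))
  idx <- as.matrix(expand.grid(x = ilo[1]:ihi[1], y = ilo[2]:ihi[2],
                               z = ilo[3]:ihi[3]))
  ctr <- voxelCenters(idx, sp, vol@origin)
  keep <- rowSums(sweep(ctr, 2, centerMm, "-")^2) <= r^2
  mask[idx[keep, , drop = FALSE] + 1] <- TRUE
  if (!any(mask)) stop("liver reference VOI contains no voxel centres",
                       call. = FALSE)
  mask
}

#' Summary statistics of the liver reference VOI
#'
#' @param vol a [SuvVolume-class].
#' @param mask logical liver VOI mask on the same grid.
#' @return a [LiverStats-class] with mean, SD (sample), min and voxel count.
#' @export
liverStats <- function(vol, mask) {
  mask <- checkMask(mask, dim(vol@values), "liver VOI")
  v <- vol@values[mask]
  if (!length(v)) stop("liver VOI is empty", call. = FALSE)
  new("LiverStats", mean = mean(v), sd = if (length(v) > 1) sd(v) else 0,
      min = min(v), voxelCount = length(v))
}

setMethod("show", "LiverStats", function(object) {
  cat(sprintf("LiverStats: mean %.3f, sd %.3f, min %.3f over %d voxels\n",
              object@mean, object@sd, object@min, object@voxelCount))
})

#' PERCIST background threshold
#'
#' The liver-based background cut-off above which voxels count as tumour:
#' `1.5 * liver mean + 2 * liver SD`, an exact affine map with no tolerance.
#'
#' @param stats a [LiverStats-class] (or any object with `@mean` and `@sd`).
#' @return threshold in SUV.
#' @examples
#' percistThreshold(new("LiverStats", mean = 2, sd = 0.25,
#'                      min = 1.4, voxelCount = 10L))  # 3.5
#' @export
percistThreshold <- function(stats) {
  1.5 * stats@mean + 2 * stats@sd
}

#' Extract hypermetabolic lesions above a threshold
#'
#' Connected components (26-neighbourhood by default) of the voxels with
#' SUV >= `threshold` (ties included: the closed-threshold convention of the
#' PERCIST literature), excluding the liver reference VOI and any exclusion
#' masks. Components with fewer than `minLesionVoxels` voxels are dropped as
#' noise. Per-lesion MTV is voxel count times voxel volume (cm^3); TMTV is
#' the sum of the per-lesion MTVs.
#'
#' @param vol a [SuvVolume-class].
#' @param threshold SUV cut-off (> 0).
#' @param liverVoi logical liver reference mask.
#' @param exclusionMasks list of logical masks to remove before labelling
#'   (physiological uptake, contamination, lymphoma-unrelated uptake).
#' @param minLesionVoxels minimum component size kept; default 3.
#' @param connectivity 26 (default) or 6.
#' @return a [LesionSet-class]. If nothing survives, an empty set with
#'   TMTV 0 is returned with a warning (a positive baseline scan is expected
#'   upstream; the caller decides how to treat a negative one).
#' @export
extractLesions <- function(vol, threshold, liverVoi,
                           exclusionMasks = list(), minLesionVoxels = 3L,
                           connectivity = 26L) {
  stopifnot(is(vol, "SuvVolume"))
  if (!is.numeric(threshold) || threshold <= 0)
    stop("'threshold' must be a positive SUV", call. = FALSE)
  d <- dim(vol@values)
  liverVoi <- checkMask(liverVoi, d, "liver VOI")
  fg <- vol@values >= threshold
  fg[liverVoi] <- FALSE
  for (m in exclusionMasks) fg[checkMask(m, d, "exclusion mask")] <- FALSE
  cc <- labelComponents(fg, connectivity)
  lab <- cc$labels
  if (cc$n > 0L) {
    sizes <- tabulate(lab[lab > 0], nbins = cc$n)
    keep <- which(sizes >= minLesionVoxels)
    relabel <- integer(cc$n)
    relabel[keep] <- seq_along(keep)
    lab[lab > 0] <- relabel[lab[lab > 0]]
  } else keep <- integer()
  vv <- prod(vol@spacing) / 1000          # cm^3 per voxel
  if (length(keep)) {
    vals <- vol@values[lab > 0]
    labs <- factor(lab[lab > 0], levels = seq_along(keep))
    st <- data.frame(
      label = seq_along(keep),
      voxels = as.integer(tabulate(as.integer(labs), nbins = length(keep))),
      suvmax = as.numeric(tapply(vals, labs, max)),
      suvmean = as.numeric(tapply(vals, labs, mean))
    )
    st$mtv_cm3 <- st$voxels * vv
    st <- st[, c("label", "voxels", "mtv_cm3", "suvmax", "suvmean")]
  } else {
    warning("no lesion above threshold ", format(threshold, digits = 4),
            " survived filtering; returning an empty LesionSet", call. = FALSE)
    st <- data.frame(label = integer(), voxels = integer(),
                     mtv_cm3 = numeric(), suvmax = numeric(),
                     suvmean = numeric())
  }
  new("LesionSet", labelMap = lab, liverMask = liverVoi,
      spacing = vol@spacing, threshold = threshold, stats = st,
      tmtvCm3 = sum(st$mtv_cm3))
}

#' Segment a volume end-to-end from a liver centre
#'
#' Convenience wrapper: place the liver VOI, compute its statistics, derive
#' the PERCIST threshold and extract the lesions.
#'
#' @inheritParams extractLesions
#' @param liverCenterMm liver VOI centre, world mm.
#' @param ... passed on to [extractLesions()].
#' @return a [LesionSet-class].
#' @export
segmentVolume <- function(vol, liverCenterMm, ...) {
  voi <- placeLiverVoi(vol, liverCenterMm)
  thr <- percistThreshold(liverStats(vol, voi))
  extractLesions(vol, thr, voi, ...)
}

#' Accessors for LesionSet
#'
#' @param x a [LesionSet-class].
#' @return `lesionStats()`: the per-lesion metrics data.frame; `tmtv()`: the
#'   total metabolic tumour volume in cm^3; `nLesions()`: the lesion count;
#'   `lesionMask()`: the logical mask of one lesion.
#' @export
lesionStats <- function(x) x@stats

#' @rdname lesionStats
#' @export
tmtv <- function(x) x@tmtvCm3

#' @rdname lesionStats
#' @export
nLesions <- function(x) nrow(x@stats)

#' @rdname lesionStats
#' @param label lesion label (1..n).
#' @export
lesionMask <- function(x, label) x@labelMap == label

setMethod("show", "LesionSet", function(object) {
  cat(sprintf("LesionSet: %d lesion(s), TMTV %.3f cm^3, threshold SUV %.3f\n",
              nrow(object@stats), object@tmtvCm3, object@threshold))
  if (nrow(object@stats)) print(head(object@stats, 10))
})
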