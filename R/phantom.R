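# Synthetic PET phantom cohorts.
#
# A phantom volume emulates the imaging setting the pipeline assumes:
# quasi-spherical FDG-avid lesions (continuous-space spheres rasterized to
# the grid, so sphericity ground truth is analytic) on a low-uptake
# background, a homogeneous ellipsoidal liver, a Gaussian point-spread blur
# and additive voxel noise. A cohort adds two-scanner gain/offset batch
# effects applied in image space (so they propagate through the full
# extraction path the way real scanner differences would) and a
# time-to-treatment outcome generated from designated ground-truth feature
# values -- computed on the noiseless masks, which separates outcome-model
# recovery from segmentation error.

#' Build a PhantomSpec
#'
#' Defaults mirror the clinical setting of a low tumour burden follicular
#' lymphoma cohort: about 7 lesions per subject with radii 5-12 mm (median
#' total burden around 20 cm^3), nominal lesion peak SUV 6-13 over a
#' background of 1 (median per-subject SUVmax around 11 after the
#' point-spread blur), a liver at SUV mean 2.0 / SD 0.25 (PERCIST
#' threshold 3.5), 3 mm voxels and a 2.5 mm point-spread sigma.
#'
#' @param gridShape,voxelSpacing grid geometry (voxels, mm).
#' @param nLesions number of lesions (>= 1).
#' @param lesionRadiusRange,lesionPeakSuvRange per-lesion radius (mm) and
#'   nominal (pre-blur) peak SUV ranges.
#' @param backgroundSuv,backgroundNoiseSd background mean SUV and noise SD.
#' @param liverCenter liver centre, 0-based voxel coordinates.
#' @param liverAxes liver ellipsoid semi-axes, mm.
#' @param liverMeanSuv,liverSdSuv liver SUV mean and noise SD.
#' @param psfSigmaMm Gaussian point-spread sigma, mm.
#' @param seed integer seed.
#' @return a [PhantomSpec-class].
#' @export
phantomSpec <- function(gridShape = c(64L, 64L, 48L),
                        voxelSpacing = c(3, 3, 3),
                        nLesions = 7L,
                        lesionRadiusRange = c(5, 12),
                        lesionPeakSuvRange = c(6, 13),
                        backgroundSuv = 1.0,
                        backgroundNoiseSd = 0.15,
                        liverCenter = c(16, 42, 24),
                        liverAxes = c(32, 24, 24),
                        liverMeanSuv = 2.0,
                        liverSdSuv = 0.25,
                        psfSigmaMm = 2.5,
                        seed = 1L) {
  new("PhantomSpec", gridShape = as.integer(gridShape),
      voxelSpacing = as.numeric(voxelSpacing),
      nLesions = as.integer(nLesions),
      lesionRadiusRange = as.numeric(lesionRadiusRange),
      lesionPeakSuvRange = as.numeric(lesionPeakSuvRange),
      backgroundSuv = backgroundSuv, backgroundNoiseSd = backgroundNoiseSd,
      liverCenter = as.numeric(liverCenter), liverAxes = as.numeric(liverAxes),
      liverMeanSuv = liverMeanSuv, liverSdSuv = liverSdSuv,
      psfSigmaMm = psfSigmaMm, seed = as.integer(seed))
}

# Rasterize an ellipsoid: voxel centres inside the continuous surface.
.rasterEllipsoid <- function(gridShape, spacing, centerVox, axesMm) {
  idx <- as.matrix(expand.grid(x = 0:(gridShape[1] - 1L),
                               y = 0:(gridShape[2] - 1L),
                               z = 0:(gridShape[3] - 1L)))
  rel <- sweep(sweep(idx, 2, centerVox, "-"), 2, spacing, "*")
  q <- rowSums(sweep(rel, 2, axesMm, "/")^2)
  array(q <= 1, dim = gridShape)
}

#' Generate one phantom volume with ground truth
#'
#' Lesion centres are drawn uniformly, subject to staying inside the grid
#' with margin, clearing the liver, and clearing other lesions by at least
#' `minSeparationMm`; placement is retried a bounded number of times and a
#' grid too small to host the requested lesions is an explicit error. The
#' noiseless structure (background + lesions + liver) is blurred by the
#' point-spread Gaussian; Gaussian voxel noise is then added (liver SD
#' inside the liver, background SD elsewhere) and the volume is clipped at
#' 0 so all SUVs are nonnegative.
#'
#' @param spec a [PhantomSpec-class].
#' @param minSeparationMm minimum surface-to-surface lesion separation, mm.
#' @return a list with elements `volume` (the noisy [SuvVolume-class]),
#'   `noiseless` (the blurred noise-free volume) and `truth`: ground-truth
#'   lesion `labelMap`, `liverMask`, `liverCenterMm` (for the 2 cm
#'   reference VOI), and a per-lesion data.frame `lesions` with centre,
#'   radius and nominal peak.
#' @export
generatePhantom <- function(spec, minSeparationMm = 12) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  d <- spec@gridShape
  sp <- spec@voxelSpacing
  withSeed(spec@seed, {
    liverMask <- .rasterEllipsoid(d, sp, spec@liverCenter, spec@liverAxes)
    liverCenterMm <- spec@liverCenter * sp
    fieldMm <- d * sp
    centers <- matrix(0, 0, 3); radii <- numeric(); peaks <- numeric()
    tries <- 0L
    while (length(radii) < spec@nLesions) {
      if (tries >= 200L * spec@nLesions)
        stop("could not place ", spec@nLesions, " lesions of radius ",
             spec@lesionRadiusRange[1], "-", spec@lesionRadiusRange[2],
             " mm with ", minSeparationMm, " mm separation in a ",
             paste(round(fieldMm), collapse = "x"),
             " mm field: grid too small", call. = FALSE)
      tries <- tries + 1L
      r <- runif(1, spec@lesionRadiusRange[1], spec@lesionRadiusRange[2])
      margin <- r + 2 * spec@psfSigmaMm + max(sp)
      if (any(fieldMm - margin <= margin)) next  # lesion cannot fit at all
      ctr <- runif(3, margin, fieldMm - margin)
      # keep clear of the liver (ellipsoid test with radius allowance)
      rel <- (ctr - liverCenterMm) / (spec@liverAxes + r + minSeparationMm)
      if (sum(rel^2) <= 1) next
      if (nrow(centers)) {
        gap <- sqrt(rowSums(sweep(centers, 2, ctr, "-")^2)) - radii - r
        if (any(gap < minSeparationMm)) next
      }
      centers <- rbind(centers, ctr)
      radii <- c(radii, r)
      peaks <- c(peaks, runif(1, spec@lesionPeakSuvRange[1],
                              spec@lesionPeakSuvRange[2]))
    }
    vol <- array(spec@backgroundSuv, dim = d)
    vol[liverMask] <- spec@liverMeanSuv
    labelMap <- array(0L, dim = d)
    idx <- as.matrix(expand.grid(x = 0:(d[1] - 1L), y = 0:(d[2] - 1L),
                                 z = 0:(d[3] - 1L)))
    pos <- sweep(idx, 2, sp, "*")
    for (i in seq_along(radii)) {
      inside <- rowSums(sweep(pos, 2, centers[i, ], "-")^2) <= radii[i]^2
      labelMap[array(inside, dim = d)] <- i
      vol[array(inside, dim = d)] <- peaks[i]
    }
    noiseless <- gaussianSmooth(vol, spec@psfSigmaMm, sp)
    noiseSd <- array(spec@backgroundNoiseSd, dim = d)
    noiseSd[liverMask] <- spec@liverSdSuv
    noisy <- pmax(noiseless + rnorm(length(vol)) * noiseSd, 0)
    list(volume = suvVolume(array(noisy, d), sp),
         noiseless = suvVolume(noiseless, sp),
         truth = list(labelMap = labelMap, liverMask = liverMask,
                      liverCenterMm = liverCenterMm,
                      lesions = data.frame(label = seq_along(radii),
                                           x_mm = centers[, 1],
                                           y_mm = centers[, 2],
                                           z_mm = centers[, 3],
                                           radius_mm = radii,
                                           peak_suv = peaks)))
  })
}

# LesionSet built from ground-truth masks (not from a threshold): used to
# compute noiseless feature values for outcome generation and for
# segmentation benchmarking.
truthLesionSet <- function(vol, labelMap, liverVoi) {
  vv <- prod(vol@spacing) / 1000
  labs <- sort(unique(labelMap[labelMap > 0]))
  st <- do.call(rbind, lapply(labs, function(lb) {
    v <- vol@values[labelMap == lb]
    data.frame(label = lb, voxels = length(v), mtv_cm3 = length(v) * vv,
               suvmax = max(v), suvmean = mean(v))
  }))
  st$label <- seq_len(nrow(st))
  lm2 <- labelMap
  lm2[lm2 > 0] <- match(labelMap[labelMap > 0], labs)
  new("LesionSet", labelMap = lm2, liverMask = liverVoi,
      spacing = vol@spacing, threshold = 0, stats = st,
      tmtvCm3 = sum(st$mtv_cm3))
}

#' Build a CohortSpec
#'
#' Defaults reproduce the study conditions the pipeline targets: 38
#' subjects, 16 on scanner A and 22 on scanner B, 12/38 never treated, a
#' median time-to-treatment around 40 months driven by tumour burden (TMTV)
#' and hottest-lesion SUVmax with a 15-month residual SD, and a modest
#' scanner B gain/offset perturbation applied to the images.
#'
#' @param nSubjects cohort size.
#' @param scannerAssignment fraction on scanner A.
#' @param batchLocationEffect,batchScaleEffect per-scanner additive SUV
#'   offset and multiplicative gain, length 2 (scanner A, scanner B).
#' @param informativeFeatures,outcomeCoefficients the ground-truth features
#'   driving TTT (names from [featureRegistry()]) and their slopes
#'   (months per feature unit).
#' @param outcomeIntercept baseline TTT, months.
#' @param outcomeNoiseSd residual SD, months.
#' @param censorFraction fraction of subjects who never start treatment.
#' @param seed integer seed.
#' @return a [CohortSpec-class].
#' @export
cohortSpec <- function(nSubjects = 38L,
                       scannerAssignment = 16 / 38,
                       batchLocationEffect = c(0, 0.3),
                       batchScaleEffect = c(1, 1.1),
                       informativeFeatures = c("tmtv_cm3",
                                               "F_stat.max.SUVmax"),
                       outcomeCoefficients = c(-0.8, -1.8),
                       outcomeIntercept = 75,
                       outcomeNoiseSd = 15,
                       censorFraction = 12 / 38,
                       seed = 1L) {
  new("CohortSpec", nSubjects = as.integer(nSubjects),
      scannerAssignment = scannerAssignment,
      batchLocationEffect = as.numeric(batchLocationEffect),
      batchScaleEffect = as.numeric(batchScaleEffect),
      informativeFeatures = as.character(informativeFeatures),
      outcomeCoefficients = as.numeric(outcomeCoefficients),
      outcomeIntercept = outcomeIntercept,
      outcomeNoiseSd = outcomeNoiseSd,
      censorFraction = censorFraction, seed = as.integer(seed))
}

#' Generate a two-scanner phantom cohort
#'
#' Per subject: a phantom is generated from the template spec (with a
#' subject-specific seed and a lesion count drawn uniformly within +/- 4 of
#' the template's, clamped to >= 1), the designated ground-truth features
#' are computed on the noiseless volume with the ground-truth masks, and
#'
#' `TTT = intercept + sum(coefficients * features) + N(0, noiseSd)`,
#'
#' clamped to at least 1 month (time-to-treatment is strictly positive).
#' A `censorFraction` subset of subjects never starts treatment; their
#' recorded time is a follow-up time drawn uniformly on 24-134 months and
#' `event` is FALSE. Scanner batch effects are applied to the noisy images
#' as `gain * SUV + offset` (clipped at 0).
#'
#' @param cspec a [CohortSpec-class].
#' @param pspec a [PhantomSpec-class] template.
#' @return a list: `volumes` (list of [SuvVolume-class]), `scanner`
#'   (character vector, levels `"A"`/`"B"`), `outcome` (data.frame
#'   `subject_id`, `ttt_months`, `event`), `liverCenters` (subjects x 3
#'   matrix, mm), `truthFeatures` (81 x subjects matrix of noiseless
#'   ground-truth feature values) and `truth` (per-subject ground truth).
#' @export
generateCohort <- function(cspec, pspec = phantomSpec()) {
  stopifnot(is(cspec, "CohortSpec"), is(pspec, "PhantomSpec"))
  validObject(cspec)
  n <- cspec@nSubjects
  withSeed(cspec@seed, {
    nA <- min(max(round(cspec@scannerAssignment * n), 1L), n - 1L)
    scanner <- rep("B", n)
    scanner[sample.int(n, nA)] <- "A"
    nles <- pmax(1L, pspec@nLesions +
                   sample(-4:4, n, replace = TRUE))
    censored <- rep(FALSE, n)
    nc <- round(cspec@censorFraction * n)
    if (nc > 0) censored[sample.int(n, nc)] <- TRUE
    followUp <- runif(n, 24, 134)
    noise <- rnorm(n, 0, cspec@outcomeNoiseSd)
    subjectSeeds <- childSeed(cspec@seed, seq_len(n))

    volumes <- vector("list", n)
    liverCenters <- matrix(0, n, 3)
    truth <- vector("list", n)
    reg <- featureRegistry()
    truthFeatures <- matrix(NA_real_, length(reg), n,
                            dimnames = list(reg, paste0("S", seq_len(n))))
    for (i in seq_len(n)) {
      ps <- pspec
      ps@nLesions <- nles[i]
      ps@seed <- subjectSeeds[i]
      ph <- generatePhantom(ps)
      voi <- placeLiverVoi(ph$noiseless, ph$truth$liverCenterMm)
      tls <- truthLesionSet(ph$noiseless, ph$truth$labelMap, voi)
      truthFeatures[, i] <- assembleFeatureVector(tls, ph$noiseless)
      g <- cspec@batchScaleEffect[if (scanner[i] == "A") 1L else 2L]
      o <- cspec@batchLocationEffect[if (scanner[i] == "A") 1L else 2L]
      v <- pmax(g * ph$volume@values + o, 0)
      volumes[[i]] <- suvVolume(array(v, dim(ph$volume@values)),
                                ph$volume@spacing, ph$volume@origin)
      liverCenters[i, ] <- ph$truth$liverCenterMm
      truth[[i]] <- ph$truth
    }
    lin <- drop(cspec@outcomeCoefficients %*%
                  truthFeatures[cspec@informativeFeatures, , drop = FALSE])
    tttTrue <- pmax(cspec@outcomeIntercept + lin + noise, 1)
    ttt <- ifelse(censored, followUp, tttTrue)
    outcome <- data.frame(subject_id = paste0("S", seq_len(n)),
                          ttt_months = ttt, event = !censored)
    list(volumes = volumes, scanner = scanner, outcome = outcome,
         liverCenters = liverCenters, truthFeatures = truthFeatures,
         truth = truth)
  })
}

#' Write a cohort to disk
#'
#' Volumes go to `<dir>/S<i>.nii.gz`; the manifest CSV records subject id,
#' scanner, outcome and the liver VOI centre (mm); the generating specs are
#' serialized to JSON alongside.
#'
#' @param cohort result of [generateCohort()].
#' @param dir output directory (created if needed).
#' @param cspec,pspec optional specs to serialize next to the data.
#' @return the manifest path, invisibly.
#' @export
writeCohort <- function(cohort, dir, cspec = NULL, pspec = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- length(cohort$volumes)
  paths <- file.path(dir, paste0("S", seq_len(n), ".nii.gz"))
  for (i in seq_len(n)) writeSuvVolume(cohort$volumes[[i]], paths[i])
  manifest <- data.frame(subject_id = cohort$outcome$subject_id,
                         volume = basename(paths),
                         scanner = cohort$scanner,
                         ttt_months = cohort$outcome$ttt_months,
                         event = cohort$outcome$event,
                         liver_center_x = cohort$liverCenters[, 1],
                         liver_center_y = cohort$liverCenters[, 2],
                         liver_center_z = cohort$liverCenters[, 3])
  mp <- file.path(dir, "manifest.csv")
  write.csv(manifest, mp, row.names = FALSE)
  specs <- list()
  if (!is.null(cspec)) specs$cohort <- .specToList(cspec)
  if (!is.null(pspec)) specs$phantom <- .specToList(pspec)
  if (length(specs))
    jsonlite::write_json(specs, file.path(dir, "specs.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(mp)
}

.specToList <- function(s) {
  out <- lapply(slotNames(s), function(nm) methods::slot(s, nm))
  names(out) <- slotNames(s)
  out
}
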