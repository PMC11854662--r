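#' SuvVolume: a 3D SUV-calibrated PET volume
#'
#' Holds a 3D grid of standardized uptake values (SUV) together with its
#' voxel spacing and world origin. The package-wide grid convention is:
#' 0-based voxel indices, axis order (x, y, z) as stored, and world
#' coordinate = origin + index * spacing (mm).
#'
#' @slot values 3D numeric array of SUVs; all values finite.
#' @slot spacing numeric(3), voxel edge length per axis in mm; all > 0.
#' @slot origin numeric(3), world coordinate (mm) of voxel (0, 0, 0).
#'
#' @seealso [suvVolume()], [readSuvVolume()], [writeSuvVolume()]
#' @export
setClass("SuvVolume",
  representation(values = "array", spacing = "numeric", origin = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@values)) != 3L)
      msg <- c(msg, "'values' must be a 3D array")
    if (!all(is.finite(object@values)))
      msg <- c(msg, "'values' must be finite everywhere")
    if (length(object@spacing) != 3L || !all(is.finite(object@spacing)) ||
        any(object@spacing <= 0))
      msg <- c(msg, "'spacing' must be 3 positive finite numbers (mm)")
    if (length(object@origin) != 3L || !all(is.finite(object@origin)))
      msg <- c(msg, "'origin' must be 3 finite numbers (mm)")
    if (length(msg)) msg else TRUE
  }
)

#' LiverStats: summary statistics of the healthy-liver reference VOI
#'
#' First-order summary of the SUVs inside the 2 cm spherical liver reference
#' VOI, the inputs of the PERCIST background threshold.
#'
#' @slot mean,sd,min liver SUV mean, standard deviation and minimum.
#' @slot voxelCount number of voxels in the VOI (> 0).
#' @export
setClass("LiverStats",
  representation(mean = "numeric", sd = "numeric", min = "numeric",
                 voxelCount = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@voxelCount <= 0L) msg <- c(msg, "'voxelCount' must be > 0")
    if (!is.finite(object@sd) || object@sd < 0)
      msg <- c(msg, "'sd' must be finite and >= 0")
    if (length(msg)) msg else TRUE
  }
)

#' LesionSet: segmented hypermetabolic lesions plus the liver reference VOI
#'
#' The result of PERCIST-threshold segmentation: a label map of pairwise
#' disjoint lesion masks (labels 1..n, 0 = background), the liver reference
#' mask, the threshold that produced them, and per-lesion metabolic metrics.
#' TMTV (total metabolic tumour volume) is the sum of the per-lesion MTVs.
#'
#' @slot labelMap 3D integer array; 0 background, 1..n lesion labels.
#' @slot liverMask 3D logical array, same grid as `labelMap`.
#' @slot spacing numeric(3) voxel spacing in mm.
#' @slot threshold SUV threshold used for segmentation.
#' @slot stats data.frame with one row per lesion: `label`, `voxels`,
#'   `mtv_cm3`, `suvmax`, `suvmean`.
#' @slot tmtvCm3 total metabolic tumour volume in cm^3.
#' @export
setClass("LesionSet",
  representation(labelMap = "array", liverMask = "array", spacing = "numeric",
                 threshold = "numeric", stats = "data.frame",
                 tmtvCm3 = "numeric"),
  validity = function(object) {
    msg <- character()
    st <- object@stats
    need <- c("label", "voxels", "mtv_cm3", "suvmax", "suvmean")
    if (!all(need %in% names(st)))
      msg <- c(msg, "'stats' must have columns label/voxels/mtv_cm3/suvmax/suvmean")
    else {
      if (nrow(st) && abs(object@tmtvCm3 - sum(st$mtv_cm3)) > 1e-9)
        msg <- c(msg, "tmtvCm3 must equal the sum of per-lesion MTVs")
      if (nrow(st) && any(st$suvmean > st$suvmax + 1e-12))
        msg <- c(msg, "per-lesion suvmean must not exceed suvmax")
    }
    if (!identical(dim(object@labelMap), dim(object@liverMask)))
      msg <- c(msg, "labelMap and liverMask must share the grid")
    if (length(msg)) msg else TRUE
  }
)

#' RadiomicFeatureSet: subjects x features container
#'
#' A [SummarizedExperiment::SummarizedExperiment] with features in rows
#' (the fixed 81-name registry layout, see [featureRegistry()]) and subjects
#' in columns. `colData` carries the scanner label and the outcome
#' (`ttt_months`, time from diagnosis to start of systemic therapy, and
#' `event`, whether treatment started during follow-up).
#'
#' @seealso [radiomicFeatureSet()], [featureMatrix()], [scannerLabels()],
#'   [outcomeTable()]
#' @export
setClass("RadiomicFeatureSet", contains = "SummarizedExperiment",
  validity = function(object) {
    msg <- character()
    if (!"features" %in% names(assays(object)))
      msg <- c(msg, "assay 'features' is required")
    if (!"scanner" %in% names(colData(object)))
      msg <- c(msg, "colData column 'scanner' is required")
    if (anyDuplicated(colnames(object)))
      msg <- c(msg, "subject ids (colnames) must be unique")
    if (length(msg)) msg else TRUE
  }
)

#' CombatModel: fitted ComBat location/scale harmonization model
#'
#' Empirical-Bayes location/scale batch model with a single batch factor
#' (the scanner). Per feature: grand mean `alphaHat` and pooled variance
#' `sigma2Hat`; per batch and feature: shrunken location `gammaStar` and
#' scale `delta2Star`. Features with zero pooled variance are passed through
#' untouched and listed in `flagged`.
#'
#' @slot alphaHat,sigma2Hat numeric vectors, one entry per feature.
#' @slot gammaStar,delta2Star matrices, batches x features.
#' @slot batchLevels character(2) scanner labels.
#' @slot features character vector of feature names in model order.
#' @slot flagged character vector of zero-variance features passed through.
#' @export
setClass("CombatModel",
  representation(alphaHat = "numeric", sigma2Hat = "numeric",
                 gammaStar = "matrix", delta2Star = "matrix",
                 batchLevels = "character", features = "character",
                 flagged = "character"))

#' CvReport: leave-one-out cross-validation report for one model family
#'
#' For each feature-count k = 1..maxK: the (nested) selected feature names,
#' training metrics averaged over the K folds, testing metrics pooled over
#' the K held-out predictions, and the per-fold predictions themselves.
#'
#' @slot modelKind "LR" or "SVM".
#' @slot results named list, one element per k, each a list with elements
#'   `features`, `training`, `testing`, `predictions`.
#' @export
setClass("CvReport",
  representation(modelKind = "character", results = "list"),
  validity = function(object) {
    if (!object@modelKind %in% c("LR", "SVM"))
      "modelKind must be 'LR' or 'SVM'" else TRUE
  }
)

#' PhantomSpec: parameters of one synthetic PET phantom volume
#'
#' Describes a single-subject phantom: grid geometry, quasi-spherical
#' FDG-avid lesions on a low-uptake background, an ellipsoidal healthy-liver
#' region, a Gaussian point-spread blur and additive background noise.
#'
#' @slot gridShape integer(3) voxels per axis.
#' @slot voxelSpacing numeric(3) mm per axis.
#' @slot nLesions number of lesions (>= 1).
#' @slot lesionRadiusRange numeric(2) lesion radius range, mm.
#' @slot lesionPeakSuvRange numeric(2) lesion peak SUV range.
#' @slot backgroundSuv,backgroundNoiseSd background mean SUV and noise SD.
#' @slot liverCenter numeric(3) liver centre, voxel coordinates (0-based).
#' @slot liverAxes numeric(3) liver ellipsoid semi-axes, mm.
#' @slot liverMeanSuv,liverSdSuv liver SUV mean and SD.
#' @slot psfSigmaMm Gaussian point-spread sigma, mm.
#' @slot seed integer random seed.
#' @export
setClass("PhantomSpec",
  representation(gridShape = "integer", voxelSpacing = "numeric",
                 nLesions = "integer", lesionRadiusRange = "numeric",
                 lesionPeakSuvRange = "numeric", backgroundSuv = "numeric",
                 backgroundNoiseSd = "numeric", liverCenter = "numeric",
                 liverAxes = "numeric", liverMeanSuv = "numeric",
                 liverSdSuv = "numeric", psfSigmaMm = "numeric",
                 seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@nLesions < 1L) msg <- c(msg, "'nLesions' must be >= 1")
    if (length(object@gridShape) != 3L || any(object@gridShape < 8L))
      msg <- c(msg, "'gridShape' must be 3 axis sizes >= 8")
    if (any(object@voxelSpacing <= 0)) msg <- c(msg, "'voxelSpacing' must be > 0")
    if (diff(object@lesionRadiusRange) < 0 || object@lesionRadiusRange[1] <= 0)
      msg <- c(msg, "'lesionRadiusRange' must be increasing and positive")
    if (object@lesionPeakSuvRange[1] <= object@backgroundSuv)
      msg <- c(msg, "lesion peak SUV must exceed the background SUV")
    if (object@backgroundNoiseSd < 0 || object@liverSdSuv < 0)
      msg <- c(msg, "noise SDs must be >= 0")
    if (object@psfSigmaMm < 0) msg <- c(msg, "'psfSigmaMm' must be >= 0")
    if (length(msg)) msg else TRUE
  }
)

#' CohortSpec: parameters of a synthetic two-scanner phantom cohort
#'
#' Describes a cohort of phantom subjects split across two scanners, the
#' scanner batch effects applied in image space (multiplicative gain and
#' additive offset on SUVs), and a time-to-treatment outcome generated as a
#' linear model on designated ground-truth features plus Gaussian noise.
#'
#' @slot nSubjects number of subjects.
#' @slot scannerAssignment fraction of subjects on scanner A (0 < f < 1).
#' @slot batchLocationEffect numeric(2), additive SUV shift per scanner.
#' @slot batchScaleEffect numeric(2), multiplicative gain per scanner.
#' @slot informativeFeatures names of features driving the outcome; must be
#'   in the adopted 81-feature layout.
#' @slot outcomeCoefficients months per feature unit, same length.
#' @slot outcomeIntercept baseline TTT, months.
#' @slot outcomeNoiseSd residual SD, months (> 0).
#' @slot censorFraction fraction of subjects never starting treatment.
#' @slot seed integer random seed.
#' @export
setClass("CohortSpec",
  representation(nSubjects = "integer", scannerAssignment = "numeric",
                 batchLocationEffect = "numeric", batchScaleEffect = "numeric",
                 informativeFeatures = "character",
                 outcomeCoefficients = "numeric", outcomeIntercept = "numeric",
                 outcomeNoiseSd = "numeric", censorFraction = "numeric",
                 seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@nSubjects < 1L) msg <- c(msg, "'nSubjects' must be >= 1")
    if (object@scannerAssignment <= 0 || object@scannerAssignment >= 1)
      msg <- c(msg, "'scannerAssignment' must lie strictly between 0 and 1")
    if (object@outcomeNoiseSd <= 0) msg <- c(msg, "'outcomeNoiseSd' must be > 0")
    if (length(object@informativeFeatures) !=
        length(object@outcomeCoefficients))
      msg <- c(msg, "coefficients and informative features must align")
    bad <- setdiff(object@informativeFeatures, featureRegistry())
    if (length(bad))
      msg <- c(msg, paste0("unknown informative feature(s): ",
                           paste(bad, collapse = ", "),
                           "; valid names are given by featureRegistry()"))
    if (object@censorFraction < 0 || object@censorFraction >= 1)
      msg <- c(msg, "'censorFraction' must be in [0, 1)")
    if (length(msg)) msg else TRUE
  }
)
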