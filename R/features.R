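# The fixed 81-feature layout of the pipeline, three regions plus extras:
#   * 17 first-order features on the pooled tumour burden (all lesion voxels
#     of the subject treated as one multiset),
#   * 14 morphological features averaged over the individual lesions
#     (shape descriptors such as sphericity are undefined on a union of
#     disconnected regions, so they are computed per lesion and averaged),
#   * 17 + 14 features on the single lesion containing the global SUVmax
#     (suffix ".SUVmax"),
#   * 17 first-order features on the healthy-liver reference VOI (suffix
#     ".liver"; morphology of a fixed-geometry sphere is meaningless and is
#     dropped),
#   * the lesion count and the TMTV in cm^3.

#' The canonical 81-name feature registry
#'
#' Returns the fixed, ordered feature name layout used by every feature
#' table in the package: `F_stat.*` (pooled burden), `F_morph.*`
#' (lesion-averaged), the same with suffix `.SUVmax` (hottest lesion),
#' `F_stat.*.liver` (liver reference VOI), `n_lesions` and `tmtv_cm3`.
#' The registry order also defines the deterministic tie-break order used
#' by forward feature selection.
#'
#' @return character vector of length 81.
#' @examples
#' length(featureRegistry())
#' @export
featureRegistry <- function() {
  c(firstOrderNames, morphNames,
    paste0(firstOrderNames, ".SUVmax"), paste0(morphNames, ".SUVmax"),
    paste0(firstOrderNames, ".liver"),
    "n_lesions", "tmtv_cm3")
}

#' Assemble the 81-feature radiomic vector of one subject
#'
#' Applies the three-region scheme to a segmented volume: first-order
#' features on the pooled multiset of all lesion voxels; morphology as the
#' unweighted mean of the per-lesion morphology vectors; both families on
#' the lesion containing the overall SUVmax; first-order only on the liver
#' reference VOI; plus lesion count and TMTV. If the global SUVmax is
#' attained in several lesions, the lesion with the larger MTV wins, then
#' the lowest label id (a deterministic tie-break).
#'
#' @param lesions a [LesionSet-class] with at least one lesion and a
#'   nonempty liver VOI.
#' @param vol the [SuvVolume-class] the lesions were segmented from.
#' @param binWidth intensity bin width for uniformity/entropy (SUV).
#' @param areaMethod surface-area estimator, see [morphologicalFeatures()].
#' @return named numeric vector of length 81 in registry order.
#' @export
assembleFeatureVector <- function(lesions, vol, binWidth = 0.25,
                                  areaMethod = "mesh") {
  stopifnot(is(lesions, "LesionSet"), is(vol, "SuvVolume"))
  st <- lesionStats(lesions)
  if (!nrow(st)) stop("no lesions: cannot assemble a feature vector",
                      call. = FALSE)
  if (!any(lesions@liverMask)) stop("liver reference VOI is missing",
                                    call. = FALSE)
  vals <- vol@values
  sp <- vol@spacing

  burdenVox <- vals[lesions@labelMap > 0]
  foBurden <- firstOrderFeatures(burdenVox, binWidth)
  morphPer <- vapply(st$label, function(lb)
    morphologicalFeatures(lesions@labelMap == lb, sp, vals,
                          method = areaMethod),
    numeric(length(morphNames)))
  moBurden <- rowMeans(morphPer)

  # the lesion containing the overall SUVmax (ties: larger MTV, then label)
  gmax <- max(st$suvmax)
  cand <- st[st$suvmax == gmax, ]
  cand <- cand[order(-cand$mtv_cm3, cand$label), ]
  hot <- cand$label[1]
  hotMask <- lesions@labelMap == hot
  foHot <- firstOrderFeatures(vals[hotMask], binWidth)
  moHot <- morphPer[, match(hot, st$label)]

  foLiver <- firstOrderFeatures(vals[lesions@liverMask], binWidth)

  out <- c(foBurden, moBurden,
           setNames(foHot, paste0(names(foHot), ".SUVmax")),
           setNames(moHot, paste0(morphNames, ".SUVmax")),
           setNames(foLiver, paste0(names(foLiver), ".liver")),
           n_lesions = nrow(st), tmtv_cm3 = tmtv(lesions))
  stopifnot(identical(names(out), featureRegistry()))
  out
}

#' Segment and extract features for a list of volumes
#'
#' Runs [segmentVolume()] and [assembleFeatureVector()] per subject and
#' binds the results into a [RadiomicFeatureSet-class].
#'
#' @param volumes list of [SuvVolume-class] objects.
#' @param liverCentersMm matrix (subjects x 3) of liver VOI centres, mm.
#' @param scanner character/factor of scanner labels, one per subject.
#' @param outcome optional data.frame with columns `ttt_months` and `event`.
#' @param subjectIds subject identifiers; default `S1..Sn`.
#' @param ... passed to [segmentVolume()] / [assembleFeatureVector()].
#' @param binWidth intensity bin width (SUV) for uniformity/entropy.
#' @return a [RadiomicFeatureSet-class] (features x subjects).
#' @export
extractCohortFeatures <- function(volumes, liverCentersMm, scanner,
                                  outcome = NULL,
                                  subjectIds = paste0("S", seq_along(volumes)),
                                  binWidth = 0.25, ...) {
  stopifnot(length(volumes) >= 1L,
            nrow(liverCentersMm) == length(volumes),
            length(scanner) == length(volumes))
  feats <- vapply(seq_along(volumes), function(i) {
    les <- segmentVolume(volumes[[i]], liverCentersMm[i, ], ...)
    assembleFeatureVector(les, volumes[[i]], binWidth = binWidth)
  }, numeric(length(featureRegistry())))
  colnames(feats) <- subjectIds
  radiomicFeatureSet(feats, scanner = scanner, outcome = outcome)
}
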