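# End-to-end pipeline. Stage order is fixed and each stage consumes only
# prior-stage outputs:
#   input (phantom simulation or manifest) -> segmentation + extraction ->
#   scanner audit + ComBat harmonization (+ exclusion of resistant
#   features) -> LR/SVM modelling with LOOCV -> median-split KM screen.

#' Run the full radiomics pipeline
#'
#' `config` is a named list (or a path to a JSON file with the same
#' structure). Either `config$phantom` describes a synthetic cohort
#' (fields are passed to [cohortSpec()] / [phantomSpec()]) or
#' `config$manifest` names a cohort manifest CSV as written by
#' [writeCohort()]. Remaining options: `seed` (overrides the cohort spec
#' seed), `outDir` (artifacts are written when set), `alpha` (FDR level,
#' default 0.05), `maxK` (selection depth, default 4), `treatedOnly`
#' (modelling restriction, default FALSE), `nestedSelection` (default
#' FALSE), `binWidth` (SUV discretisation, default 0.25).
#'
#' @param config list or JSON path.
#' @param verbose log each stage with counts via `message()`.
#' @return a report list: `features` (raw [RadiomicFeatureSet-class]),
#'   `harmonization` (see [harmonizeFeatures()]), `modelFeatures` (the
#'   table modelling ran on), `tttScanner`, `cv` (CvReports), `kmScreen`,
#'   and `files` (paths written, if `outDir` was set).
#' @export
runPipeline <- function(config, verbose = TRUE) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  stopifnot(is.list(config))
  log <- function(...) if (verbose) message("[flradiomics] ", ...)
  alpha <- config$alpha %||% 0.05
  maxK <- as.integer(config$maxK %||% 4L)
  binWidth <- config$binWidth %||% 0.25
  treatedOnly <- isTRUE(config$treatedOnly)
  nested <- isTRUE(config$nestedSelection)
  outDir <- config$outDir
  if (!is.character(outDir) || !length(outDir)) outDir <- NULL
  files <- list()
  emit <- function(name, writer) {
    if (is.null(outDir)) return(invisible(NULL))
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    path <- file.path(outDir, name)
    writer(path)
    files[[name]] <<- path
  }

  # ---- stage 0: inputs -----------------------------------------------------
  if (!is.null(config$phantom)) {
    pargs <- config$phantom
    n <- pargs$nSubjects %||% 38L
    if (n < 1L) stop("pipeline config requests zero subjects", call. = FALSE)
    csArgs <- pargs[intersect(names(pargs), names(formals(cohortSpec)))]
    if (!is.null(config$seed)) csArgs$seed <- as.integer(config$seed)
    cspec <- do.call(cohortSpec, csArgs)
    psArgs <- (pargs$phantomSpec %||% list())
    psArgs <- psArgs[intersect(names(psArgs), names(formals(phantomSpec)))]
    pspec <- do.call(phantomSpec, psArgs)
    log("simulating phantom cohort: n = ", cspec@nSubjects)
    cohort <- generateCohort(cspec, pspec)
    volumes <- cohort$volumes
    liverCenters <- cohort$liverCenters
    scanner <- cohort$scanner
    outcome <- cohort$outcome
    subjectIds <- outcome$subject_id
  } else if (!is.null(config$manifest)) {
    man <- read.csv(config$manifest, stringsAsFactors = FALSE)
    if (!nrow(man)) stop("pipeline config requests zero subjects",
                         call. = FALSE)
    log("reading ", nrow(man), " volumes from manifest")
    base <- dirname(config$manifest)
    volumes <- lapply(file.path(base, man$volume), readSuvVolume)
    liverCenters <- as.matrix(man[, c("liver_center_x", "liver_center_y",
                                      "liver_center_z")])
    scanner <- man$scanner
    outcome <- data.frame(subject_id = man$subject_id,
                          ttt_months = man$ttt_months, event = man$event)
    subjectIds <- man$subject_id
  } else stop("config needs either 'phantom' or 'manifest'", call. = FALSE)

  # ---- stage 1: segmentation + feature extraction --------------------------
  log("segmenting and extracting features for ", length(volumes),
      " subjects")
  fs <- extractCohortFeatures(volumes, liverCenters, scanner,
                              outcome = outcome, subjectIds = subjectIds,
                              binWidth = binWidth)
  emit("features_raw.csv", function(p) writeFeatureTable(fs, p))

  # ---- stage 2: scanner audit + harmonization ------------------------------
  harm <- harmonizeFeatures(fs, alpha = alpha)
  log("scanner audit: ", harm$nSignificantPre, " -> ",
      harm$nSignificantPost, " FDR-significant features after ComBat")
  ttsc <- tttScannerTest(fs)
  log("TTT vs scanner rank-sum p = ", format(ttsc$p_value, digits = 3))
  modelFs <- dropUnharmonized(harm$harmonized, harm$auditPost,
                              extra = harm$model@flagged)
  # constant features cannot be z-scored; drop them before modelling
  sds <- apply(featureMatrix(modelFs), 1, sd)
  if (any(sds == 0)) {
    log("dropping ", sum(sds == 0), " constant feature(s)")
    modelFs <- replaceFeatures(modelFs,
                               featureMatrix(modelFs)[sds > 0, ,
                                                      drop = FALSE])
  }
  emit("features_harmonized.csv",
       function(p) writeFeatureTable(harm$harmonized, p))
  emit("scanner_audit.csv", function(p) {
    aud <- merge(harm$auditPre, harm$auditPost, by = "feature",
                 suffixes = c("_pre", "_post"), sort = FALSE)
    aud$excluded <- aud$feature %in% harm$excluded
    write.csv(aud, p, row.names = FALSE)
  })

  # ---- stage 3: modelling --------------------------------------------------
  log("modelling: forward selection + LOOCV, k = 1..", maxK)
  cv <- runModelling(modelFs, maxK = maxK, treatedOnly = treatedOnly,
                     nestedSelection = nested)
  cvTab <- rbind(cvReportTable(cv$LR), cvReportTable(cv$SVM))
  emit("cv_report.csv", function(p) write.csv(cvTab, p, row.names = FALSE))
  emit("cv_report.json", function(p)
    jsonlite::write_json(cvTab, p, auto_unbox = TRUE, digits = NA))

  # ---- stage 4: survival screen --------------------------------------------
  km <- suppressWarnings(medianSplitScreen(modelFs, treatedOnly = TRUE,
                                           alpha = alpha))
  log("KM screen: ", sum(km$significant), " significant feature(s) of ",
      sum(!km$skipped), " screened")
  emit("km_screen.csv", function(p) write.csv(km, p, row.names = FALSE))

  list(features = fs, harmonization = harm, modelFeatures = modelFs,
       tttScanner = ttsc, cv = cv, kmScreen = km, files = files)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
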