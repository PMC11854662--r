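#' Construct a RadiomicFeatureSet
#'
#' @param features numeric matrix, features x subjects, with feature names
#'   as rownames (typically the [featureRegistry()] layout) and unique
#'   subject ids as colnames.
#' @param scanner scanner label per subject (character or factor).
#' @param outcome optional data.frame with columns `ttt_months` (months,
#'   > 0) and `event` (logical: treatment started); row order = subjects.
#' @return a [RadiomicFeatureSet-class].
#' @examples
#' m <- matrix(rnorm(10), 5, 2, dimnames = list(paste0("f", 1:5), c("a", "b")))
#' fs <- radiomicFeatureSet(m, scanner = c("A", "B"))
#' @export
radiomicFeatureSet <- function(features, scanner, outcome = NULL) {
  features <- as.matrix(features)
  if (is.null(rownames(features)))
    stop("feature matrix needs feature names as rownames", call. = FALSE)
  if (is.null(colnames(features)))
    colnames(features) <- paste0("S", seq_len(ncol(features)))
  cd <- DataFrame(scanner = as.character(scanner),
                  row.names = colnames(features))
  if (!is.null(outcome)) {
    if (!all(c("ttt_months", "event") %in% names(outcome)))
      stop("'outcome' needs columns ttt_months and event", call. = FALSE)
    cd$ttt_months <- as.numeric(outcome$ttt_months)
    cd$event <- as.logical(outcome$event)
  }
  new("RadiomicFeatureSet",
      SummarizedExperiment(assays = list(features = features), colData = cd))
}

#' Accessors for RadiomicFeatureSet
#'
#' `featureMatrix()` returns the features x subjects matrix,
#' `scannerLabels()` the per-subject scanner labels, and `outcomeTable()`
#' a data.frame with `subject_id`, `ttt_months`, `event` and the binary
#' class label `early` (TTT at or below the cohort median; subjects exactly
#' at the median count as early).
#'
#' @param x a [RadiomicFeatureSet-class].
#' @return see above.
#' @export
featureMatrix <- function(x) assay(x, "features")

#' @rdname featureMatrix
#' @export
scannerLabels <- function(x) as.character(colData(x)$scanner)

#' @rdname featureMatrix
#' @export
outcomeTable <- function(x) {
  cd <- colData(x)
  if (is.null(cd$ttt_months))
    stop("no outcome recorded in this feature set", call. = FALSE)
  ttt <- as.numeric(cd$ttt_months)
  data.frame(subject_id = colnames(x), ttt_months = ttt,
             event = as.logical(cd$event),
             early = ttt <= median(ttt), row.names = NULL)
}

setMethod("show", "RadiomicFeatureSet", function(object) {
  cat(sprintf("RadiomicFeatureSet: %d features x %d subjects\n",
              nrow(object), ncol(object)))
  tab <- table(scannerLabels(object))
  cat("  scanners:", paste(sprintf("%s (n=%d)", names(tab), tab),
                           collapse = ", "), "\n")
  if (!is.null(colData(object)$ttt_months))
    cat(sprintf("  TTT: median %.1f months, %d/%d treated\n",
                median(colData(object)$ttt_months),
                sum(colData(object)$event), ncol(object)))
})

#' Read / write feature tables as CSV
#'
#' One row per subject: `subject_id`, `scanner`, optionally `ttt_months`
#' and `event`, then one column per feature. Numeric values are written
#' with 17 significant digits, so the round trip is lossless to double
#' precision. On read, an unknown column or a duplicated subject id is an
#' error; when `requireRegistry = TRUE` (default) the feature columns must
#' be exactly the 81-name registry layout.
#'
#' @param x a [RadiomicFeatureSet-class].
#' @param path CSV path.
#' @param requireRegistry enforce the [featureRegistry()] column layout.
#' @return `readFeatureTable()` returns a [RadiomicFeatureSet-class];
#'   `writeFeatureTable()` returns `path` invisibly.
#' @export
writeFeatureTable <- function(x, path) {
  stopifnot(is(x, "RadiomicFeatureSet"))
  fm <- featureMatrix(x)
  df <- data.frame(subject_id = colnames(x), scanner = scannerLabels(x),
                   stringsAsFactors = FALSE)
  cd <- colData(x)
  if (!is.null(cd$ttt_months)) {
    df$ttt_months <- sprintf("%.17g", as.numeric(cd$ttt_months))
    df$event <- as.logical(cd$event)
  }
  for (f in rownames(fm)) df[[f]] <- sprintf("%.17g", fm[f, ])
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(path, requireRegistry = TRUE) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"subject_id" %in% names(df)) stop("missing 'subject_id' column")
  if (!"scanner" %in% names(df)) stop("missing 'scanner' column")
  if (anyDuplicated(df$subject_id))
    stop("duplicate subject id(s): ",
         paste(unique(df$subject_id[duplicated(df$subject_id)]),
               collapse = ", "))
  meta <- intersect(c("subject_id", "scanner", "ttt_months", "event"),
                    names(df))
  featCols <- setdiff(names(df), meta)
  if (requireRegistry) {
    reg <- featureRegistry()
    unknown <- setdiff(featCols, reg)
    if (length(unknown))
      stop("unknown feature column(s): ", paste(unknown, collapse = ", "))
    missing <- setdiff(reg, featCols)
    if (length(missing))
      stop("missing feature column(s): ", paste(missing, collapse = ", "))
    featCols <- reg
  }
  fm <- t(as.matrix(vapply(df[featCols], as.numeric, numeric(nrow(df)))))
  if (nrow(df) == 1L) fm <- matrix(fm, ncol = 1L,
                                   dimnames = list(featCols, NULL))
  colnames(fm) <- df$subject_id
  outcome <- if ("ttt_months" %in% names(df))
    data.frame(ttt_months = as.numeric(df$ttt_months),
               event = as.logical(df$event)) else NULL
  radiomicFeatureSet(fm, scanner = df$scanner, outcome = outcome)
}

# Rebuild a feature set around a new (possibly feature-subset) matrix,
# carrying over the per-subject metadata.
replaceFeatures <- function(x, newMatrix) {
  cd <- colData(x)
  stopifnot(identical(colnames(newMatrix), colnames(x)))
  outcome <- if (!is.null(cd$ttt_months))
    data.frame(ttt_months = cd$ttt_months, event = cd$event) else NULL
  radiomicFeatureSet(newMatrix, scanner = cd$scanner, outcome = outcome)
}
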