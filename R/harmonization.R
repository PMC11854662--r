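# Scanner-difference audit and ComBat harmonization.
#
# The audit runs a two-sided Wilcoxon-Mann-Whitney rank-sum test per
# feature between the two scanner groups (exact enumeration when both
# groups have at most 8 subjects and no ties; otherwise the normal
# approximation with tie and continuity correction) and adjusts the
# p-values across features by the Benjamini-Hochberg step-up rule.
#
# Harmonization is the parametric empirical-Bayes location/scale model with
# the scanner as the single batch factor and no biological covariates:
# standardize each feature by its grand mean (weighted batch means) and
# pooled variance, estimate per-batch location/scale on the standardized
# scale, shrink them towards batch-level normal / inverse-gamma priors by
# the iterative EB scheme, and map each value back through
#   adjusted = sigma / delta* x (z - gamma*) + alpha.

#' Benjamini-Hochberg FDR adjustment
#'
#' Thin wrapper over `stats::p.adjust(method = "BH")`, shared by the
#' scanner audit and the survival screen so both use bit-identical
#' adjustment.
#'
#' @param p numeric vector of raw p-values.
#' @return adjusted p-values, same order.
#' @export
adjustFdr <- function(p) p.adjust(p, method = "BH")

# Rank-sum p-value with the sample-size policy stated above.
.ranksumP <- function(a, b) {
  exact <- length(a) <= 8 && length(b) <= 8 && !anyDuplicated(c(a, b))
  suppressWarnings(wilcox.test(a, b, exact = exact, correct = TRUE)$p.value)
}

#' Per-feature Wilcoxon scanner audit
#'
#' @param fs a [RadiomicFeatureSet-class] with exactly two scanner groups.
#' @param alpha significance level on the FDR-adjusted p-values.
#' @return a data.frame with one row per feature: `feature`, `p_raw`,
#'   `p_adj`, `significant`; the significant count is
#'   `sum(p_adj < alpha)`. Constant features (no variation at all) get
#'   p = 1.
#' @export
wilcoxonScannerTest <- function(fs, alpha = 0.05) {
  stopifnot(is(fs, "RadiomicFeatureSet"))
  lab <- scannerLabels(fs)
  lv <- unique(lab)
  if (length(lv) != 2L)
    stop("exactly two scanner groups are required, got ",
         length(lv), call. = FALSE)
  X <- featureMatrix(fs)
  ga <- lab == lv[1]
  if (!any(ga) || all(ga))
    stop("each scanner group must be nonempty", call. = FALSE)
  p <- apply(X, 1, function(v) {
    if (length(unique(v)) == 1L) return(1)
    .ranksumP(v[ga], v[!ga])
  })
  padj <- adjustFdr(as.numeric(p))
  data.frame(feature = rownames(X), p_raw = as.numeric(p), p_adj = padj,
             significant = padj < alpha, row.names = NULL)
}

#' Rank-sum check of the outcome against the scanner
#'
#' The same two-sided rank-sum test applied to the TTT column: a sanity
#' check that the outcome itself is not confounded with the scanner. The
#' result is reported, not acted on.
#'
#' @param fs a [RadiomicFeatureSet-class] with outcome.
#' @return a list with `p_value` and the group medians.
#' @export
tttScannerTest <- function(fs) {
  lab <- scannerLabels(fs)
  lv <- unique(lab)
  stopifnot(length(lv) == 2L)
  ttt <- outcomeTable(fs)$ttt_months
  list(p_value = .ranksumP(ttt[lab == lv[1]], ttt[lab == lv[2]]),
       medians = tapply(ttt, lab, median))
}

# Method-of-moments inverse-gamma hyperparameters for the scale prior.
.aprior <- function(d2) { m <- mean(d2); s2 <- var(d2); (2 * s2 + m^2) / s2 }
.bprior <- function(d2) { m <- mean(d2); s2 <- var(d2); (m * s2 + m^3) / s2 }

#' Fit the ComBat scanner-harmonization model
#'
#' @param fs a [RadiomicFeatureSet-class] with exactly two scanner batches,
#'   each with at least two subjects.
#' @param tol,maxIter convergence of the EB iteration: stop when the
#'   relative change of the shrunken estimates drops below `tol` (default
#'   1e-4) or after `maxIter` iterations.
#' @return a [CombatModel-class]. Features with zero pooled variance are
#'   flagged and passed through untouched by [combatApply()].
#' @export
combatFit <- function(fs, tol = 1e-4, maxIter = 100L) {
  stopifnot(is(fs, "RadiomicFeatureSet"))
  X <- featureMatrix(fs)
  lab <- scannerLabels(fs)
  lv <- sort(unique(lab))
  if (length(lv) < 2L)
    stop("single-batch input: nothing to harmonize", call. = FALSE)
  if (length(lv) > 2L)
    stop("more than two scanner batches are not supported", call. = FALSE)
  nb <- table(factor(lab, levels = lv))
  if (any(nb < 2L))
    stop("each scanner batch needs at least 2 subjects", call. = FALSE)
  n <- ncol(X)
  batchMeans <- vapply(lv, function(b)
    rowMeans(X[, lab == b, drop = FALSE]), numeric(nrow(X)))
  alphaHat <- drop(batchMeans %*% (as.numeric(nb) / n))
  resid <- X - batchMeans[, match(lab, lv), drop = FALSE]
  sigma2Hat <- rowMeans(resid^2)
  flagged <- rownames(X)[sigma2Hat <= .Machine$double.eps]
  ok <- sigma2Hat > .Machine$double.eps

  gammaStar <- matrix(0, length(lv), nrow(X),
                      dimnames = list(lv, rownames(X)))
  delta2Star <- matrix(1, length(lv), nrow(X),
                       dimnames = list(lv, rownames(X)))
  Z <- (X[ok, , drop = FALSE] - alphaHat[ok]) / sqrt(sigma2Hat[ok])
  for (b in lv) {
    Zb <- Z[, lab == b, drop = FALSE]
    nbk <- ncol(Zb)
    gammaHat <- rowMeans(Zb)
    delta2Hat <- apply(Zb, 1, var)
    gbar <- mean(gammaHat); t2 <- var(gammaHat)
    a <- .aprior(delta2Hat); bb <- .bprior(delta2Hat)
    g <- gammaHat; d2 <- delta2Hat
    for (it in seq_len(maxIter)) {
      gNew <- (nbk * t2 * gammaHat + d2 * gbar) / (nbk * t2 + d2)
      ss <- rowSums((Zb - gNew)^2)
      d2New <- (bb + 0.5 * ss) / (nbk / 2 + a - 1)
      change <- max(abs(gNew - g) / pmax(abs(g), 1e-12),
                    abs(d2New - d2) / pmax(abs(d2), 1e-12))
      g <- gNew; d2 <- d2New
      if (change < tol) break
    }
    gammaStar[b, ok] <- g
    delta2Star[b, ok] <- d2
  }
  new("CombatModel", alphaHat = alphaHat, sigma2Hat = sigma2Hat,
      gammaStar = gammaStar, delta2Star = delta2Star,
      batchLevels = as.character(lv), features = rownames(X),
      flagged = flagged)
}

#' Apply a fitted ComBat model
#'
#' @param model a [CombatModel-class].
#' @param fs a [RadiomicFeatureSet-class] with the model's features and
#'   batch labels.
#' @return a [RadiomicFeatureSet-class] of identical shape with harmonized
#'   values; flagged (zero-variance) features pass through untouched.
#' @export
combatApply <- function(model, fs) {
  stopifnot(is(model, "CombatModel"), is(fs, "RadiomicFeatureSet"))
  X <- featureMatrix(fs)
  if (!identical(rownames(X), model@features))
    stop("feature layout differs from the fitted model", call. = FALSE)
  lab <- scannerLabels(fs)
  if (!all(lab %in% model@batchLevels))
    stop("unknown scanner label(s): ",
         paste(setdiff(lab, model@batchLevels), collapse = ", "),
         call. = FALSE)
  ok <- !(rownames(X) %in% model@flagged)
  out <- X
  sig <- sqrt(model@sigma2Hat[ok])
  Z <- (X[ok, , drop = FALSE] - model@alphaHat[ok]) / sig
  for (b in model@batchLevels) {
    cols <- lab == b
    if (!any(cols)) next
    Zb <- (Z[, cols, drop = FALSE] - model@gammaStar[b, ok]) /
      sqrt(model@delta2Star[b, ok])
    out[ok, cols] <- Zb * sig + model@alphaHat[ok]
  }
  replaceFeatures(fs, out)
}

#' One-step harmonization with pre/post audit
#'
#' Audits the raw table, fits and applies ComBat, re-audits, and reports
#' which features remained significantly scanner-dependent.
#'
#' @param fs a [RadiomicFeatureSet-class].
#' @param alpha FDR significance level.
#' @return a list: `harmonized` (feature set), `model`, `auditPre`,
#'   `auditPost`, `nSignificantPre`, `nSignificantPost`, `excluded`
#'   (features still significant after harmonization, plus flagged
#'   zero-variance features).
#' @export
harmonizeFeatures <- function(fs, alpha = 0.05) {
  auditPre <- wilcoxonScannerTest(fs, alpha)
  model <- combatFit(fs)
  harm <- combatApply(model, fs)
  auditPost <- wilcoxonScannerTest(harm, alpha)
  excluded <- union(auditPost$feature[auditPost$significant], model@flagged)
  list(harmonized = harm, model = model, auditPre = auditPre,
       auditPost = auditPost,
       nSignificantPre = sum(auditPre$significant),
       nSignificantPost = sum(auditPost$significant),
       excluded = excluded)
}

#' Drop features that resisted harmonization
#'
#' Features still FDR-significant in the post-harmonization audit are
#' discarded from the table before modelling.
#'
#' @param fs the harmonized [RadiomicFeatureSet-class].
#' @param auditPost audit computed on `fs` (see [wilcoxonScannerTest()]).
#' @param extra additional feature names to drop (e.g. flagged
#'   zero-variance features).
#' @return the reduced [RadiomicFeatureSet-class].
#' @export
dropUnharmonized <- function(fs, auditPost, extra = character()) {
  drop <- union(auditPost$feature[auditPost$significant], extra)
  keep <- setdiff(rownames(fs), drop)
  if (!length(keep))
    stop("all features remain scanner-dependent: modelling cannot proceed",
         call. = FALSE)
  if (length(drop))
    message("dropping ", length(drop), " feature(s): ",
            paste(drop, collapse = ", "))
  replaceFeatures(fs, featureMatrix(fs)[keep, , drop = FALSE])
}

setMethod("show", "CombatModel", function(object) {
  cat(sprintf("CombatModel: %d features, batches %s%s\n",
              length(object@features),
              paste(object@batchLevels, collapse = "/"),
              if (length(object@flagged))
                sprintf(" (%d flagged zero-variance)",
                        length(object@flagged)) else ""))
})
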