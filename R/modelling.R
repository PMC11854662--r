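# TTT models: linear regression on the continuous time-to-treatment and a
# radial-kernel SVM classifying TTT at or below versus above the cohort
# median. Features are z-scored (sample SD); forward selection is greedy on
# a full-cohort criterion (R^2 for LR, accuracy for SVM), deliberately
# reproducing the two-step select-then-validate procedure (selection on the
# whole cohort, then LOOCV of the fixed subsets). That procedure leaks
# selection information into the validation estimates; `nestedSelection`
# re-selects inside every training fold for honest estimates.

#' z-score the features of a table
#'
#' Each feature (row) is centred and scaled to unit sample SD (n - 1
#' denominator). A zero-SD feature is an error naming the column: constant
#' features must be excluded before modelling.
#'
#' @param fs a [RadiomicFeatureSet-class] or a features x subjects matrix.
#' @return same type as the input.
#' @export
zscoreFeatures <- function(fs) {
  X <- if (is(fs, "RadiomicFeatureSet")) featureMatrix(fs) else fs
  s <- apply(X, 1, sd)
  bad <- rownames(X)[s == 0 | !is.finite(s)]
  if (length(bad))
    stop("zero-SD feature(s): ", paste(bad, collapse = ", "), call. = FALSE)
  Z <- (X - rowMeans(X)) / s
  if (is(fs, "RadiomicFeatureSet")) replaceFeatures(fs, Z) else Z
}

# --- metric helpers ---------------------------------------------------------

rmse <- function(pred, obs) sqrt(mean((pred - obs)^2))

# R^2 as 1 - SSE/SST about the mean of `obs`; can be negative when the
# predictions do worse than the observed mean (documented contract).
rsquared <- function(pred, obs) {
  sst <- sum((obs - mean(obs))^2)
  1 - sum((obs - pred)^2) / sst
}

#' Rank-based ROC AUC
#'
#' Mann-Whitney formulation: the probability that a random positive scores
#' above a random negative, ties counting one half.
#'
#' @param scores numeric decision scores, larger = more positive.
#' @param positive logical vector, TRUE for the positive class.
#' @return AUC in \[0, 1\].
#' @export
aucRank <- function(scores, positive) {
  positive <- as.logical(positive)
  nP <- sum(positive); nN <- sum(!positive)
  if (nP == 0 || nN == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[positive]) - nP * (nP + 1) / 2) / (nP * nN)
}

.classMetrics <- function(predPos, obsPos, scores = NULL) {
  tp <- sum(predPos & obsPos); fp <- sum(predPos & !obsPos)
  fn <- sum(!predPos & obsPos)
  out <- c(accuracy = mean(predPos == obsPos),
           precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
           sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_)
  if (!is.null(scores)) out <- c(out, auc = aucRank(scores, obsPos))
  out
}

# --- SVM --------------------------------------------------------------------

#' Fit a radial-kernel SVM with decision scores
#'
#' Soft-margin SVM with RBF kernel `k(u, v) = exp(-gamma ||u - v||^2)`.
#' Hyperparameters default to `cost = 1` and
#' `gamma = 1 / (n_features * variance of the pooled feature values)`;
#' both are exposed. Decision scores are oriented so that larger scores
#' favour the positive (early-treatment) class.
#'
#' @param x subjects x features numeric matrix.
#' @param positive logical class labels, TRUE = positive/early.
#' @param cost soft-margin cost.
#' @param gamma RBF width; `NULL` for the default above.
#' @return a list with the fitted `svm` object, `predict(newdata)`
#'   returning logical labels and `scores(newdata)` returning oriented
#'   decision values.
#' @export
svmFit <- function(x, positive, cost = 1, gamma = NULL) {
  x <- as.matrix(x)
  positive <- as.logical(positive)
  if (length(unique(positive)) < 2L)
    stop("both classes must be present to fit an SVM", call. = FALSE)
  if (is.null(gamma)) {
    v <- var(as.vector(x))
    gamma <- if (v > 0) 1 / (ncol(x) * v) else 1 / ncol(x)
  }
  y <- factor(ifelse(positive, "early", "late"), levels = c("early", "late"))
  fit <- e1071::svm(x, y, kernel = "radial", cost = cost, gamma = gamma,
                    scale = FALSE)
  score <- function(newx) {
    newx <- matrix(newx, ncol = ncol(x))
    dv <- attr(predict(fit, newx, decision.values = TRUE),
               "decision.values")
    s <- as.numeric(dv[, 1])
    if (colnames(dv)[1] == "late/early") s <- -s
    s
  }
  list(fit = fit,
       predict = function(newx) {
         newx <- matrix(newx, ncol = ncol(x))
         predict(fit, newx) == "early"
       },
       scores = score)
}

# --- forward selection ------------------------------------------------------

# Full-cohort criterion for a candidate feature set: R^2 of the LR fit, or
# training accuracy of the SVM fit.
.cohortCriterion <- function(Z, y, cols, modelKind, cost, gamma) {
  x <- Z[, cols, drop = FALSE]
  if (modelKind == "LR") {
    fit <- stats::.lm.fit(cbind(1, x), y)
    1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  } else {
    m <- svmFit(x, y, cost = cost, gamma = gamma)
    mean(m$predict(x) == y)
  }
}

#' Greedy forward feature selection on the full cohort
#'
#' Builds a nested feature sequence: the best single feature by the
#' full-cohort criterion (R^2 for `"LR"`, accuracy for `"SVM"`), then the
#' best partner holding prior picks fixed, up to `maxK`. Ties are broken
#' by table order (the registry order for extracted tables).
#'
#' @param fs a [RadiomicFeatureSet-class] with outcome.
#' @param modelKind `"LR"` or `"SVM"`.
#' @param maxK selection depth; default 4.
#' @param cost,gamma SVM hyperparameters, see [svmFit()].
#' @param treatedOnly restrict to subjects who started treatment.
#' @return a list: `features` (selected names in order), `criterion`
#'   (cumulative full-cohort score after each pick), `modelKind`.
#' @export
forwardSelect <- function(fs, modelKind = c("LR", "SVM"), maxK = 4L,
                          cost = 1, gamma = NULL, treatedOnly = FALSE) {
  modelKind <- match.arg(modelKind)
  dat <- .modelData(fs, modelKind, treatedOnly)
  Z <- dat$Z; y <- dat$y
  p <- ncol(Z)
  if (p < maxK) stop("need at least ", maxK, " features", call. = FALSE)
  if (nrow(Z) < maxK + 1L)
    stop("need more subjects than maxK to select ", maxK, " features",
         call. = FALSE)
  sel <- integer(); path <- numeric()
  for (k in seq_len(maxK)) {
    best <- -Inf; bestJ <- NA_integer_
    for (j in setdiff(seq_len(p), sel)) {
      sc <- .cohortCriterion(Z, y, c(sel, j), modelKind, cost, gamma)
      if (sc > best + 1e-12) { best <- sc; bestJ <- j }
    }
    sel <- c(sel, bestJ); path <- c(path, best)
  }
  list(features = colnames(Z)[sel], criterion = path, modelKind = modelKind)
}

# Shared preparation: subjects x features z-scored matrix plus the model
# target (continuous TTT for LR, logical early-class for SVM).
.modelData <- function(fs, modelKind, treatedOnly) {
  stopifnot(is(fs, "RadiomicFeatureSet"))
  oc <- outcomeTable(fs)
  keep <- if (treatedOnly) oc$event else rep(TRUE, nrow(oc))
  X <- t(featureMatrix(fs))[keep, , drop = FALSE]
  oc <- oc[keep, , drop = FALSE]
  # class label vs the median of the analyzed subjects (ties -> early)
  early <- oc$ttt_months <= median(oc$ttt_months)
  Z <- t(zscoreFeatures(t(X)))
  y <- if (modelKind == "LR") oc$ttt_months else early
  list(Z = Z, y = y, X = X, outcome = oc,
       scanner = scannerLabels(fs)[keep])
}

# --- LOOCV ------------------------------------------------------------------

#' Leave-one-out cross-validation of a fixed feature subset
#'
#' K fits on K - 1 subjects each (z-scoring refit inside every training
#' fold and applied to the held-out subject), one held-out prediction per
#' fold. LR reports pooled RMSE and R^2 over the K held-out predictions;
#' SVM reports pooled accuracy / precision / sensitivity and the ROC AUC of
#' the pooled decision scores. Training metrics are computed per fold and
#' averaged. An SVM training fold containing a single class is skipped
#' with a warning and reported.
#'
#' @inheritParams forwardSelect
#' @param features character vector of feature names to use.
#' @param nestedSelection re-run forward selection inside each training
#'   fold (honest validation) instead of using `features` as fixed.
#' @return a list: `testing` (pooled held-out metrics), `training`
#'   (fold-averaged metrics), `predictions` (per-fold data.frame),
#'   `skippedFolds`.
#' @export
loocv <- function(fs, features, modelKind = c("LR", "SVM"), cost = 1,
                  gamma = NULL, treatedOnly = FALSE,
                  nestedSelection = FALSE) {
  modelKind <- match.arg(modelKind)
  dat <- .modelData(fs, modelKind, treatedOnly)
  X <- dat$X; y <- dat$y
  K <- nrow(X)
  if (K < 3L) stop("need at least 3 subjects for LOOCV", call. = FALSE)
  kSel <- length(features)
  preds <- data.frame(subject = rownames(X), observed = y,
                      predicted = NA_real_, score = NA_real_)
  trainMetrics <- list(); skipped <- integer()
  for (i in seq_len(K)) {
    tr <- setdiff(seq_len(K), i)
    mu <- colMeans(X[tr, , drop = FALSE])
    s <- apply(X[tr, , drop = FALSE], 2, sd)
    usable <- s > 0
    Ztr <- sweep(sweep(X[tr, usable, drop = FALSE], 2, mu[usable]), 2,
                 s[usable], "/")
    Zte <- (X[i, usable] - mu[usable]) / s[usable]
    feats <- features
    if (nestedSelection) {
      sub <- radiomicFeatureSet(
        t(X[tr, , drop = FALSE]), scanner = dat$scanner[tr],
        outcome = dat$outcome[tr, c("ttt_months", "event")])
      feats <- forwardSelect(sub, modelKind, maxK = kSel, cost = cost,
                             gamma = gamma)$features
    }
    feats <- intersect(feats, colnames(Ztr))
    xt <- Ztr[, feats, drop = FALSE]
    xe <- matrix(Zte[feats], nrow = 1)
    if (modelKind == "LR") {
      fit <- stats::.lm.fit(cbind(1, xt), y[tr])
      beta <- fit$coefficients
      preds$predicted[i] <- drop(cbind(1, xe) %*% beta)
      fitted <- drop(cbind(1, xt) %*% beta)
      trainMetrics[[length(trainMetrics) + 1L]] <-
        c(rmse = rmse(fitted, y[tr]), r2 = rsquared(fitted, y[tr]))
    } else {
      if (length(unique(y[tr])) < 2L) {
        warning("fold ", i, " skipped: single-class training set")
        skipped <- c(skipped, i)
        next
      }
      m <- svmFit(xt, y[tr], cost = cost, gamma = gamma)
      preds$predicted[i] <- as.numeric(m$predict(xe))
      preds$score[i] <- m$scores(xe)
      trainMetrics[[length(trainMetrics) + 1L]] <-
        .classMetrics(m$predict(xt), y[tr], m$scores(xt))
    }
  }
  done <- !is.na(preds$predicted)
  if (!any(done))
    stop("every fold was skipped (single-class training sets); ",
         "the cohort is too unbalanced for LOOCV", call. = FALSE)
  testing <- if (modelKind == "LR") {
    c(rmse = rmse(preds$predicted[done], preds$observed[done]),
      r2 = rsquared(preds$predicted[done], preds$observed[done]))
  } else {
    .classMetrics(preds$predicted[done] > 0.5,
                  as.logical(preds$observed[done]),
                  preds$score[done])
  }
  training <- colMeans(do.call(rbind, trainMetrics))
  list(testing = testing, training = training, predictions = preds,
       skippedFolds = skipped)
}

#' Forward-selected LR and SVM models with LOOCV, k = 1..maxK
#'
#' The full modelling stage: per model family, forward-select up to `maxK`
#' features on the whole cohort, then LOOCV-validate each nested prefix.
#'
#' @inheritParams forwardSelect
#' @param models which families to run.
#' @return named list of [CvReport-class] objects (`LR`, `SVM`).
#' @export
runModelling <- function(fs, maxK = 4L, models = c("LR", "SVM"), cost = 1,
                         gamma = NULL, treatedOnly = FALSE,
                         nestedSelection = FALSE) {
  out <- list()
  for (mk in models) {
    selAll <- forwardSelect(fs, mk, maxK = maxK, cost = cost, gamma = gamma,
                            treatedOnly = treatedOnly)
    res <- list()
    for (k in seq_len(maxK)) {
      feats <- selAll$features[seq_len(k)]
      cv <- loocv(fs, feats, mk, cost = cost, gamma = gamma,
                  treatedOnly = treatedOnly,
                  nestedSelection = nestedSelection)
      res[[as.character(k)]] <- list(features = feats,
                                     training = cv$training,
                                     testing = cv$testing,
                                     predictions = cv$predictions,
                                     skippedFolds = cv$skippedFolds)
    }
    out[[mk]] <- new("CvReport", modelKind = mk, results = res)
  }
  out
}

#' Flatten a CvReport to a long data.frame
#'
#' One row per (k, split, metric), mirroring the usual performance table
#' layout (model, number of features, training/testing, metric, value).
#'
#' @param report a [CvReport-class].
#' @return data.frame with columns `model`, `k`, `features`, `split`,
#'   `metric`, `value`.
#' @export
cvReportTable <- function(report) {
  stopifnot(is(report, "CvReport"))
  rows <- list()
  for (k in names(report@results)) {
    r <- report@results[[k]]
    for (split in c("training", "testing")) {
      m <- r[[split]]
      rows[[length(rows) + 1L]] <-
        data.frame(model = report@modelKind, k = as.integer(k),
                   features = paste(r$features, collapse = "+"),
                   split = split, metric = names(m),
                   value = as.numeric(m))
    }
  }
  do.call(rbind, rows)
}

setMethod("show", "CvReport", function(object) {
  cat("CvReport (", object@modelKind, "), k = 1..",
      length(object@results), "\n", sep = "")
  tab <- cvReportTable(object)
  tab <- tab[tab$split == "testing", c("k", "features", "metric", "value")]
  print(utils::head(reshape(tab, direction = "wide",
                            idvar = c("k", "features"),
                            timevar = "metric"), 8))
})
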