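# Feature-space cohort simulators: the statistical structure of an
# extracted radiomic table (correlated features, scanner batch effects,
# outcome driven by designated features) without the imaging path. Used to
# exercise harmonization, modelling and the survival screen at scale.

#' Simulate a radiomic feature table directly in feature space
#'
#' Features are standard-normal with a common latent factor: every pair of
#' features correlates at `latentCor` (radiomic features of one subject are
#' strongly inter-correlated in practice; 0 gives independent features).
#' Scanner B columns then receive a location shift of `batchLocation`
#' feature-SDs and a scale factor `batchScale` about the feature mean --
#' feature-space analogues of scanner calibration differences.
#' Time-to-treatment is `intercept + sum(coefficients * features) + noise`
#' (on the batch-free values, clamped to >= 1 month); `censorFraction`
#' subjects are flagged never-treated with a follow-up time on 24-134
#' months recorded instead.
#'
#' @param nSubjects cohort size.
#' @param seed integer seed.
#' @param featureNames feature layout; default [featureRegistry()].
#' @param scannerFraction fraction of subjects on scanner A.
#' @param latentCor common between-feature correlation in \[0, 1).
#' @param batchLocation,batchScale scanner-B location shift (SD units) and
#'   scale factor.
#' @param informativeFeatures,coefficients features driving TTT and slopes.
#' @param intercept,noiseSd outcome baseline and residual SD, months.
#' @param censorFraction fraction never treated.
#' @return a [RadiomicFeatureSet-class].
#' @export
simulateFeatureTable <- function(nSubjects, seed = 1L,
                                 featureNames = featureRegistry(),
                                 scannerFraction = 0.5,
                                 latentCor = 0,
                                 batchLocation = 0, batchScale = 1,
                                 informativeFeatures = character(),
                                 coefficients = numeric(),
                                 intercept = 60, noiseSd = 15,
                                 censorFraction = 0) {
  stopifnot(length(informativeFeatures) == length(coefficients),
            all(informativeFeatures %in% featureNames),
            latentCor >= 0, latentCor < 1)
  p <- length(featureNames)
  withSeed(seed, {
    latent <- rnorm(nSubjects)
    X <- sqrt(latentCor) * matrix(latent, p, nSubjects, byrow = TRUE) +
      sqrt(1 - latentCor) * matrix(rnorm(p * nSubjects), p, nSubjects)
    dimnames(X) <- list(featureNames, paste0("S", seq_len(nSubjects)))
    nA <- min(max(round(scannerFraction * nSubjects), 1L), nSubjects - 1L)
    scanner <- rep("B", nSubjects)
    scanner[sample.int(nSubjects, nA)] <- "A"
    lin <- if (length(coefficients))
      drop(coefficients %*% X[informativeFeatures, , drop = FALSE]) else 0
    ttt <- pmax(intercept + lin + rnorm(nSubjects, 0, noiseSd), 1)
    event <- rep(TRUE, nSubjects)
    nc <- round(censorFraction * nSubjects)
    if (nc > 0) {
      idx <- sample.int(nSubjects, nc)
      event[idx] <- FALSE
      ttt[idx] <- runif(nc, 24, 134)
    }
    isB <- scanner == "B"
    X[, isB] <- batchScale * X[, isB] + batchLocation
    radiomicFeatureSet(X, scanner = scanner,
                       outcome = data.frame(ttt_months = ttt, event = event))
  })
}

#' Simulate an all-event survival cohort keyed to one feature
#'
#' Features share a latent factor as in [simulateFeatureTable()]. Subjects
#' above the informative feature's median have their event hazard
#' multiplied by `hazardRatio`; all subjects experience the event
#' (treatment start), mirroring a screen restricted to treated patients.
#'
#' @param nSubjects cohort size (even sizes give a clean median split).
#' @param seed integer seed.
#' @param informativeFeature name of the feature defining the risk groups.
#' @param hazardRatio hazard multiplier for the above-median group.
#' @param baselineMedianMonths median event time of the low-risk group.
#' @param latentCor common between-feature correlation.
#' @param featureNames feature layout; default [featureRegistry()].
#' @return a [RadiomicFeatureSet-class] with all-event outcomes.
#' @export
simulateSurvivalTable <- function(nSubjects = 26L, seed = 1L,
                                  informativeFeature = "F_stat.mean.SUVmax",
                                  hazardRatio = 3,
                                  baselineMedianMonths = 60,
                                  latentCor = 0,
                                  featureNames = featureRegistry()) {
  stopifnot(informativeFeature %in% featureNames)
  p <- length(featureNames)
  withSeed(seed, {
    latent <- rnorm(nSubjects)
    X <- sqrt(latentCor) * matrix(latent, p, nSubjects, byrow = TRUE) +
      sqrt(1 - latentCor) * matrix(rnorm(p * nSubjects), p, nSubjects)
    dimnames(X) <- list(featureNames, paste0("S", seq_len(nSubjects)))
    f <- X[informativeFeature, ]
    high <- f > median(f)
    rate0 <- log(2) / baselineMedianMonths
    rate <- rate0 * ifelse(high, hazardRatio, 1)
    ttt <- pmax(rexp(nSubjects, rate), 0.1)
    radiomicFeatureSet(X, scanner = rep(c("A", "B"),
                                        length.out = nSubjects),
                       outcome = data.frame(ttt_months = ttt, event = TRUE))
  })
}
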