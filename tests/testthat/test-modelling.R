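.mkFs <- function(X, ttt, event = NULL) {
  # X: subjects x features
  if (is.null(event)) event <- rep(TRUE, nrow(X))
  radiomicFeatureSet(t(X), scanner = rep(c("A", "B"), length.out = nrow(X)),
                     outcome = data.frame(ttt_months = ttt, event = event))
}

test_that("z-scoring gives exact zero mean / unit SD and is idempotent", {
  m <- matrix(c(1, 2, 3, 10, 20, 40), nrow = 2, byrow = TRUE,
              dimnames = list(c("a", "b"), paste0("s", 1:3)))
  z <- zscoreFeatures(m)
  expect_equal(unname(z["a", ]), c(-1, 0, 1))
  expect_equal(rowMeans(z), c(a = 0, b = 0), tolerance = 1e-10)
  expect_equal(apply(z, 1, sd), c(a = 1, b = 1), tolerance = 1e-10)
  expect_equal(zscoreFeatures(z), z, tolerance = 1e-12)
  m["b", ] <- 5
  expect_error(zscoreFeatures(m), "zero-SD.*b")
})

test_that("a perfect predictor is selected first with criterion 1", {
  set.seed(1)
  X <- matrix(rnorm(60 * 8), 60, 8,
              dimnames = list(NULL, paste0("f", 1:8)))
  ttt <- 10 + 3 * X[, 5]
  sel <- forwardSelect(.mkFs(X, ttt), "LR", maxK = 2)
  expect_equal(sel$features[1], "f5")
  expect_equal(sel$criterion[1], 1, tolerance = 1e-9)
})

test_that("greedy selection recovers a planted two-feature model", {
  set.seed(2)
  ok <- 0
  for (s in 1:10) {
    X <- matrix(rnorm(200 * 12), 200, 12,
                dimnames = list(NULL, paste0("f", 1:12)))
    ttt <- 50 + 2 * X[, 1] + 1 * X[, 2] + rnorm(200, 0, 0.3)
    sel <- forwardSelect(.mkFs(X, ttt), "LR", maxK = 2)
    # exhaustive oracle over all pairs
    best <- -Inf; bestPair <- NULL
    for (i in 1:11) for (j in (i + 1):12) {
      r2 <- summary(lm(ttt ~ X[, i] + X[, j]))$r.squared
      if (r2 > best) { best <- r2; bestPair <- c(i, j) }
    }
    expect_setequal(sort(sel$features[1:2]), c("f1", "f2"))
    if (setequal(sel$features[1:2], paste0("f", bestPair))) ok <- ok + 1
  }
  # greedy matches the exhaustive best pair most of the time
  expect_gte(ok, 8)
})

test_that("selection sequences are nested and tie-break by table order", {
  set.seed(3)
  X <- matrix(rnorm(50 * 9), 50, 9, dimnames = list(NULL, paste0("f", 1:9)))
  fs <- .mkFs(X, 40 + X[, 3] + rnorm(50, 0, 2))
  s2 <- forwardSelect(fs, "LR", maxK = 2)
  s4 <- forwardSelect(fs, "LR", maxK = 4)
  expect_identical(s4$features[1:2], s2$features)
  # duplicated column: the earlier one wins the tie
  X2 <- cbind(X, f_dup = X[, 3])[, c(1:2, 10, 3:9)]
  sel <- forwardSelect(.mkFs(X2, 40 + X2[, "f_dup"]), "LR", maxK = 1)
  expect_equal(sel$features, "f_dup")
})

test_that("intercept-only LOOCV predicts the left-out-complement mean", {
  set.seed(4)
  ttt <- runif(12, 10, 90)
  X <- matrix(rnorm(24), 12, 2, dimnames = list(NULL, c("f1", "f2")))
  cv <- loocv(.mkFs(X, ttt), character(0), "LR")
  want <- vapply(1:12, function(i) mean(ttt[-i]), numeric(1))
  expect_equal(cv$predictions$predicted, want, tolerance = 1e-10)
})

test_that("LR held-out residuals equal the PRESS closed form", {
  set.seed(5)
  for (rep in 1:5) {
    n <- sample(15:40, 1); p <- sample(2:4, 1)
    X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
    ttt <- 30 + X %*% rnorm(p, 0, 5) + rnorm(n, 0, 3)
    fs <- .mkFs(X, drop(ttt))
    cv <- loocv(fs, paste0("f", 1:p), "LR")
    # hat-matrix oracle on the full z-scored design (z-scoring refit per
    # fold is itself part of the model, so build the oracle the same way:
    # full-data hat matrix applies to a fixed design; use raw features
    # plus intercept, which spans the same column space as z-scored ones)
    D <- cbind(1, scale(X))
    H <- D %*% solve(crossprod(D)) %*% t(D)
    e <- drop(ttt) - drop(H %*% drop(ttt))
    press <- e / (1 - diag(H))
    resid <- cv$predictions$observed - cv$predictions$predicted
    expect_equal(resid, unname(press), tolerance = 1e-6)
  }
})

test_that("held-out R^2 can go negative on pure noise", {
  set.seed(6)
  X <- matrix(rnorm(20 * 3), 20, 3, dimnames = list(NULL, paste0("f", 1:3)))
  cv <- loocv(.mkFs(X, rnorm(20, 50, 10)), paste0("f", 1:3), "LR")
  expect_lt(cv$testing["r2"], 0.3)  # and typically < 0
  expect_true(is.finite(cv$testing["r2"]))
})

test_that("radial SVM separates XOR and flips with labels", {
  xor <- matrix(c(0, 0, 0, 1, 1, 0, 1, 1), 4, 2, byrow = TRUE)
  xor <- xor[rep(1:4, each = 6), ] + matrix(rnorm(48, 0, 0.05), 24, 2)
  y <- rep(c(TRUE, FALSE, FALSE, TRUE), each = 6)
  m <- svmFit(xor, y, cost = 10, gamma = 5)
  expect_equal(mean(m$predict(xor) == y), 1)
  m2 <- svmFit(xor, !y, cost = 10, gamma = 5)
  expect_equal(m2$predict(xor), !m$predict(xor))
  expect_error(svmFit(xor, rep(TRUE, 24)), "both classes")
})

test_that("decision-score AUC approaches the two-Gaussian closed form", {
  # scores ~ N(0,1) vs N(2,1): AUC = Phi(2/sqrt(2)) ~ 0.921
  aucs <- vapply(1:10, function(s) {
    set.seed(s)
    x <- matrix(c(rnorm(50, 0), rnorm(50, 2)), ncol = 1,
                dimnames = list(NULL, "f1"))
    y <- rep(c(FALSE, TRUE), each = 50)
    cv <- loocv(.mkFs(x, ifelse(y, 10, 90)), "f1", "SVM")
    cv$testing[["auc"]]
  }, numeric(1))
  expect_lt(abs(mean(aucs) - pnorm(sqrt(2))), 0.05)
})

test_that("rank AUC handles ties at one half and matches pROC", {
  sc <- c(1, 2, 2, 3, 5, 5, 7)
  pos <- c(FALSE, FALSE, TRUE, FALSE, TRUE, TRUE, TRUE)
  expect_equal(aucRank(sc, pos),
               as.numeric(pROC::auc(pROC::roc(pos, sc, quiet = TRUE,
                                              direction = "<"))))
  expect_equal(aucRank(c(1, 1), c(TRUE, FALSE)), 0.5)
})

test_that("single-class SVM training folds are skipped with a warning", {
  set.seed(8)
  X <- matrix(rnorm(6), 3, 2, dimnames = list(NULL, c("f1", "f2")))
  # median split of n = 3 leaves the "late" class with a single subject;
  # holding that subject out empties its class in the training fold
  ttt <- c(10, 50, 90)
  expect_warning(cv <- loocv(.mkFs(X, ttt), "f1", "SVM"), "single-class")
  expect_equal(cv$skippedFolds, 3L)
  done <- setdiff(1:3, cv$skippedFolds)
  expect_true(all(is.finite(cv$predictions$predicted[done])))
  # and a cohort with one class overall cannot be validated at all
  expect_error(suppressWarnings(
    loocv(.mkFs(X, c(10, 10, 10)), "f1", "SVM")), "unbalanced|both classes")
})

test_that("the full modelling stage returns nested deterministic reports", {
  fs <- simulateFeatureTable(38, seed = 12,
                             featureNames = paste0("f", 1:15),
                             informativeFeatures = c("f1", "f2"),
                             coefficients = c(-8, 5), noiseSd = 10)
  cv1 <- runModelling(fs, maxK = 3)
  cv2 <- runModelling(fs, maxK = 3)
  expect_identical(cvReportTable(cv1$LR), cvReportTable(cv2$LR))
  expect_identical(cvReportTable(cv1$SVM), cvReportTable(cv2$SVM))
  for (rep in cv1) {
    feats <- lapply(rep@results, `[[`, "features")
    for (k in 2:3)
      expect_identical(feats[[k]][seq_len(k - 1)], feats[[k - 1]])
  }
  tab <- cvReportTable(cv1$LR)
  expect_setequal(unique(tab$metric), c("rmse", "r2"))
  expect_equal(nrow(tab), 3 * 2 * 2)
})
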