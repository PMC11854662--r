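test_that("rank-sum p on (1,2,3) vs (4,5,6) matches exact enumeration", {
  # fully separated groups: the two most extreme of the C(6,3)=20 equally
  # likely rank assignments in each tail -> two-sided p = 2/20
  fs <- radiomicFeatureSet(
    matrix(c(1, 2, 3, 4, 5, 6), nrow = 1,
           dimnames = list("f", paste0("s", 1:6))),
    scanner = rep(c("A", "B"), each = 3))
  aud <- wilcoxonScannerTest(fs)
  expect_equal(aud$p_raw, 0.1)
})

test_that("BH adjustment reproduces the hand-applied step-up rule", {
  expect_equal(adjustFdr(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  # monotone in rank order
  set.seed(1)
  p <- runif(30)
  adj <- adjustFdr(p)
  expect_true(all(diff(adj[order(p)]) >= -1e-15))
  expect_true(all(adj >= p))
})

test_that("identical scanner distributions rarely flag features", {
  # null simulation, scaled down: 30 features, n = 38, 20 seeds
  hits <- vapply(1:20, function(s) {
    fs <- simulateFeatureTable(38, seed = s,
                               featureNames = paste0("f", 1:30),
                               scannerFraction = 16 / 38)
    sum(wilcoxonScannerTest(fs)$significant)
  }, numeric(1))
  expect_gte(mean(hits == 0), 0.95)
})

test_that("audit demands exactly two nonempty scanner groups", {
  m <- matrix(rnorm(20), 2, 10, dimnames = list(c("a", "b"), NULL))
  expect_error(wilcoxonScannerTest(
    radiomicFeatureSet(m, scanner = rep("A", 10))), "two scanner groups")
  expect_error(wilcoxonScannerTest(
    radiomicFeatureSet(m, scanner = c(rep("A", 8), "B", "C"))),
    "two scanner groups")
})

test_that("ComBat matches the reference sva implementation bitwise-near", {
  fs <- simulateFeatureTable(40, seed = 3, batchLocation = 1.5,
                             batchScale = 1.6)
  mine <- featureMatrix(combatApply(combatFit(fs), fs))
  ref <- suppressMessages(sva::ComBat(dat = featureMatrix(fs),
                                      batch = factor(scannerLabels(fs)),
                                      par.prior = TRUE))
  expect_equal(unname(mine), unname(ref), tolerance = 1e-12)
})

test_that("injected location/scale batch effects are removed", {
  fs <- simulateFeatureTable(50, seed = 4, batchLocation = 2,
                             batchScale = 2)
  harm <- harmonizeFeatures(fs)
  expect_gte(harm$nSignificantPre, 0.8 * 81)
  expect_lte(harm$nSignificantPost, 0.05 * 81)
  # location gap reduced by >= 90%
  lab <- scannerLabels(fs)
  gap <- function(M) abs(rowMeans(M[, lab == "A"]) -
                           rowMeans(M[, lab == "B"]))
  sdz <- apply(featureMatrix(fs), 1, sd)
  reduction <- 1 - gap(featureMatrix(harm$harmonized)) /
    gap(featureMatrix(fs))
  expect_gte(median(reduction), 0.9)
})

test_that("null-effect data are nearly untouched and re-harmonization contracts", {
  fs <- simulateFeatureTable(50, seed = 5)
  h1 <- combatApply(combatFit(fs), fs)
  d1 <- max(abs(featureMatrix(h1) - featureMatrix(fs)))
  expect_lt(d1, 1)  # much smaller than an injected 2-SD effect
  # EB shrinkage re-applies, so exact idempotence does not hold; but the
  # second pass must move values far less than the first
  h2 <- combatApply(combatFit(h1), h1)
  d2 <- max(abs(featureMatrix(h2) - featureMatrix(h1)))
  expect_lt(d2, 0.5 * d1)
  # grand means drift only within the shrinkage scale
  drift <- abs(rowMeans(featureMatrix(h1)) - rowMeans(featureMatrix(fs))) /
    apply(featureMatrix(fs), 1, sd)
  expect_lt(max(drift), 0.02)
  expect_equal(sum(wilcoxonScannerTest(h1)$significant), 0)
})

test_that("degenerate features and batches are handled explicitly", {
  m <- matrix(rnorm(60), 3, 20,
              dimnames = list(c("f1", "constant", "f3"), paste0("s", 1:20)))
  m["constant", ] <- 7
  fs <- radiomicFeatureSet(m, scanner = rep(c("A", "B"), 10))
  model <- combatFit(fs)
  expect_equal(model@flagged, "constant")
  h <- combatApply(model, fs)
  expect_identical(featureMatrix(h)["constant", ],
                   featureMatrix(fs)["constant", ])  # passed through
  # single batch is an error
  expect_error(combatFit(radiomicFeatureSet(m, scanner = rep("A", 20))),
               "single-batch")
  # batch with < 2 subjects is an error
  expect_error(combatFit(radiomicFeatureSet(m,
    scanner = c(rep("A", 19), "B"))), "at least 2")
})

test_that("dropUnharmonized removes exactly the resistant features", {
  fs <- simulateFeatureTable(30, seed = 6,
                             featureNames = paste0("f", 1:10))
  aud <- wilcoxonScannerTest(fs)
  expect_identical(featureMatrix(dropUnharmonized(fs, aud)),
                   featureMatrix(fs))  # nothing significant -> unchanged
  aud2 <- aud
  aud2$significant <- aud2$feature %in% c("f2", "f7")
  expect_message(red <- dropUnharmonized(fs, aud2), "dropping 2")
  expect_equal(nrow(red), 8)
  expect_false(any(c("f2", "f7") %in% rownames(red)))
  aud3 <- aud; aud3$significant <- TRUE
  expect_error(dropUnharmonized(fs, aud3), "cannot proceed")
})

test_that("the TTT-vs-scanner check reports a rank-sum p-value", {
  fs <- simulateFeatureTable(38, seed = 7, scannerFraction = 16 / 38)
  res <- tttScannerTest(fs)
  expect_true(res$p_value > 0 && res$p_value <= 1)
  expect_length(res$medians, 2)
})
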