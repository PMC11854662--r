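test_that("product-limit curve matches hand computation", {
  km <- kmCurve(c(3, 5, 8), c(TRUE, TRUE, TRUE))
  expect_equal(km$survival, c(2 / 3, 1 / 3, 0))
  expect_equal(km$time, c(3, 5, 8))
  # all censored: survival stays 1
  km2 <- kmCurve(c(3, 5, 8), rep(FALSE, 3))
  expect_true(all(km2$survival == 1))
  # mixed n = 6 fixture, hand-computed product-limit table:
  # times 2(e) 4(c) 5(e) 5(e) 7(c) 9(e); S: 5/6 at 2; at 5 risk=4, 2
  # events -> 5/6 * 2/4 = 5/12; at 9 risk=1 -> 0
  km3 <- kmCurve(c(2, 4, 5, 5, 7, 9),
                 c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE))
  ev <- km3[km3$n_event > 0, ]
  expect_equal(ev$survival, c(5 / 6, 5 / 12, 0))
  expect_error(kmCurve(numeric(), logical()), "empty")
})

test_that("curves are non-increasing, start at 1 and are stepwise", {
  set.seed(1)
  for (i in 1:10) {
    t <- rexp(20, 0.02); e <- rbinom(20, 1, 0.7) == 1
    if (!any(e)) e[1] <- TRUE
    km <- kmCurve(t, e)
    expect_true(all(diff(km$survival) <= 1e-12))
    expect_lte(km$survival[1], 1)
  }
})

test_that("log-rank is symmetric and null on identical groups", {
  t <- c(3, 6, 9, 12); e <- rep(TRUE, 4)
  lr <- logrankTest(t, e, t, e)
  expect_equal(lr$chisq, 0, tolerance = 1e-12)
  expect_equal(lr$p_value, 1, tolerance = 1e-9)
  set.seed(2)
  ta <- rexp(15, 0.02); tb <- rexp(12, 0.06)
  ab <- logrankTest(ta, rep(TRUE, 15), tb, rep(TRUE, 12))
  ba <- logrankTest(tb, rep(TRUE, 12), ta, rep(TRUE, 15))
  expect_equal(ab$chisq, ba$chisq)
  expect_error(logrankTest(ta, rep(FALSE, 15), tb, rep(FALSE, 12)),
               "no events")
  expect_error(logrankTest(numeric(), logical(), tb, rep(TRUE, 12)),
               "nonempty")
})

test_that("null log-rank p-values are close to uniform", {
  set.seed(3)
  ps <- vapply(1:200, function(i) {
    t <- rexp(26, 0.02)
    logrankTest(t[1:13], rep(TRUE, 13), t[14:26], rep(TRUE, 13))$p_value
  }, numeric(1))
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.04)
})

test_that("the median split sends ties to the low group and balances counts", {
  set.seed(4)
  fs <- simulateSurvivalTable(26, seed = 4,
                              featureNames = paste0("f", 1:5),
                              informativeFeature = "f1")
  scr <- medianSplitScreen(fs)
  expect_equal(scr$n_low + scr$n_high, rep(26L, 5))
  # distinct values -> 13/13
  expect_true(all(scr$n_low == 13 & scr$n_high == 13))
  expect_true(all(scr$p_adj >= scr$p_raw - 1e-15, na.rm = TRUE))
})

test_that("constant and heavily tied features are skipped with a warning", {
  X <- rbind(f1 = rnorm(10), f2 = rep(1, 10),
             f3 = c(rep(0, 9), 5))
  colnames(X) <- paste0("s", 1:10)
  fs <- radiomicFeatureSet(X, scanner = rep(c("A", "B"), 5),
                           outcome = data.frame(
                             ttt_months = rexp(10, 0.02) + 1,
                             event = TRUE))
  w <- capture_warnings(scr <- medianSplitScreen(fs))
  expect_length(w, 2)
  expect_match(w, "degenerate median split", all = TRUE)
  expect_true(scr$skipped[scr$feature == "f2"])
  expect_true(scr$skipped[scr$feature == "f3"])
  expect_false(scr$skipped[scr$feature == "f1"])
  expect_false(scr$significant[scr$feature == "f2"])
})

test_that("only treated subjects enter the screen by default", {
  set.seed(5)
  X <- rbind(f1 = rnorm(12))
  colnames(X) <- paste0("s", 1:12)
  fs <- radiomicFeatureSet(X, scanner = rep(c("A", "B"), 6),
                           outcome = data.frame(
                             ttt_months = rexp(12, 0.02) + 1,
                             event = rep(c(TRUE, FALSE), each = 6)))
  scr <- medianSplitScreen(fs, treatedOnly = TRUE)
  expect_equal(scr$n_low + scr$n_high, 6L)
  scrAll <- medianSplitScreen(fs, treatedOnly = FALSE)
  expect_equal(scrAll$n_low + scrAll$n_high, 12L)
})

test_that("a feature driving the hazard is detected; independents stay null", {
  # strongly inter-correlated feature family, as in real radiomic tables
  rawHits <- 0; topRank <- 0
  for (s in 1:15) {
    fs <- simulateSurvivalTable(26, seed = s, hazardRatio = 3,
                                latentCor = 0.8)
    scr <- suppressWarnings(medianSplitScreen(fs))
    i <- scr$feature == "F_stat.mean.SUVmax"
    rawHits <- rawHits + (scr$p_raw[i] < 0.05)
    # the informative feature should sit near the top of the screen
    topRank <- topRank + (rank(scr$p_raw)[i] <= 10)
  }
  expect_gte(rawHits, 9)   # ~0.74 power of the raw log-rank at this design
  expect_gte(topRank, 12)
  # independent features under a null outcome: low flag rate
  nullFlags <- vapply(1:5, function(s) {
    fs <- simulateSurvivalTable(26, seed = 100 + s, hazardRatio = 1,
                                latentCor = 0)
    sum(suppressWarnings(medianSplitScreen(fs))$significant)
  }, numeric(1))
  expect_lte(mean(nullFlags / 81), 0.05)
})

test_that("median-split curves expose the two groups for one feature", {
  fs <- simulateSurvivalTable(20, seed = 9,
                              featureNames = paste0("f", 1:3),
                              informativeFeature = "f2")
  cur <- medianSplitCurves(fs, "f2")
  expect_setequal(unique(cur$group), c("low", "high"))
  expect_true(all(cur$survival >= 0 & cur$survival <= 1))
})
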