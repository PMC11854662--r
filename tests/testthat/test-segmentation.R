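test_that("PERCIST threshold is the exact affine map of liver statistics", {
  mk <- function(m, s) new("LiverStats", mean = m, sd = s, min = 0,
                           voxelCount = 10L)
  expect_identical(percistThreshold(mk(2.0, 0.25)), 3.5)
  expect_identical(percistThreshold(mk(2.0, 0)), 3.0)
  expect_identical(percistThreshold(mk(1.8, 0.4)), 3.5)
  set.seed(1)
  for (i in 1:50) {
    m <- runif(1, 0.5, 4); s <- runif(1, 0, 1)
    expect_identical(percistThreshold(mk(m, s)), 1.5 * m + 2 * s)
  }
})

test_that("liver VOI matches the brute-force in-sphere voxel enumeration", {
  vol <- suvVolume(array(2, c(24, 24, 24)), spacing = 2)
  centerMm <- c(24, 24, 24)  # voxel (12,12,12) centre
  voi <- placeLiverVoi(vol, centerMm)
  expect_equal(sum(voi), countBallVoxels(10, c(2, 2, 2)))
  st <- liverStats(vol, voi)
  expect_equal(st@mean, 2)
  expect_equal(st@sd, 0)
  # off-lattice centre still matches enumeration around that centre
  centerMm2 <- c(23.1, 24.7, 25.3)
  voi2 <- placeLiverVoi(vol, centerMm2)
  offs <- centerMm2 - round(centerMm2 / 2) * 2
  expect_equal(sum(voi2), countBallVoxels(10, c(2, 2, 2), offset = -offs))
})

test_that("a liver VOI clipped by the grid is rejected", {
  vol <- suvVolume(array(2, c(24, 24, 24)), spacing = 2)
  expect_error(placeLiverVoi(vol, c(5, 24, 24)), "clipped")
  expect_error(placeLiverVoi(vol, c(24, 24, 44)), "clipped")
})

test_that("MTV of a rasterized hot sphere equals the enumeration oracle", {
  sp <- c(2, 2, 2)
  n <- c(30, 30, 30)
  vol <- array(1, n)
  ctr <- c(30, 30, 30)
  idx <- as.matrix(expand.grid(x = 0:29, y = 0:29, z = 0:29))
  pos <- sweep(idx, 2, sp, "*")
  inside <- rowSums(sweep(pos, 2, ctr, "-")^2) <= 100
  vol[array(inside, n)] <- 8
  sv <- suvVolume(vol, sp)
  liver <- array(FALSE, n); liver[1:3, 1:3, 1:3] <- TRUE
  les <- extractLesions(sv, 3.5, liver)
  expect_equal(nLesions(les), 1L)
  expect_equal(lesionStats(les)$mtv_cm3,
               countBallVoxels(10, sp) * 0.008)
  expect_equal(tmtv(les), lesionStats(les)$mtv_cm3)
  expect_equal(lesionStats(les)$suvmax, 8)
  expect_equal(lesionStats(les)$suvmean, 8)
})

test_that("two separated hot spheres give two lesions and additive TMTV", {
  n <- c(40, 20, 20)
  vol <- array(1, n)
  vol[5:9, 8:12, 8:12] <- 9
  vol[28:33, 8:12, 8:12] <- 7
  sv <- suvVolume(vol, c(2, 2, 2))
  liver <- array(FALSE, n); liver[1:2, 1:2, 1:2] <- TRUE
  les <- extractLesions(sv, 4, liver)
  expect_equal(nLesions(les), 2L)
  st <- lesionStats(les)
  expect_equal(tmtv(les), sum(st$mtv_cm3))
  expect_equal(sort(st$voxels), c(125, 150))
  expect_true(all(st$suvmean <= st$suvmax))
})

test_that("threshold above the global maximum yields an empty LesionSet", {
  sv <- suvVolume(array(2, c(10, 10, 10)), 2)
  liver <- array(FALSE, c(10, 10, 10)); liver[1, 1, 1] <- TRUE
  expect_warning(les <- extractLesions(sv, 99, liver), "no lesion")
  expect_equal(nLesions(les), 0L)
  expect_equal(tmtv(les), 0)
})

test_that("voxels exactly at the threshold are included (closed threshold)", {
  n <- c(12, 12, 12)
  vol <- array(1, n)
  vol[6, 6, 6] <- 3.5; vol[6, 7, 6] <- 3.5; vol[6, 6, 7] <- 3.5
  sv <- suvVolume(vol, 2)
  liver <- array(FALSE, n); liver[1, 1, 1] <- TRUE
  les <- extractLesions(sv, 3.5, liver, minLesionVoxels = 3L)
  expect_equal(nLesions(les), 1L)
  expect_equal(lesionStats(les)$voxels, 3L)
})

test_that("liver VOI and exclusion masks are removed before labelling", {
  n <- c(20, 20, 20)
  vol <- array(1, n)
  vol[4:8, 4:8, 4:8] <- 9        # lesion
  vol[13:17, 13:17, 13:17] <- 9  # physiological uptake to exclude
  sv <- suvVolume(vol, 2)
  liver <- array(FALSE, n); liver[1:2, 1:2, 1:2] <- TRUE
  excl <- array(FALSE, n); excl[12:18, 12:18, 12:18] <- TRUE
  les <- extractLesions(sv, 4, liver, exclusionMasks = list(excl))
  expect_equal(nLesions(les), 1L)
  # and the same call without exclusion finds both
  expect_equal(nLesions(extractLesions(sv, 4, liver)), 2L)
})

test_that("components below the minimum voxel count are suppressed", {
  n <- c(14, 14, 14)
  vol <- array(1, n)
  vol[3, 3, 3] <- 9                       # single hot voxel: noise
  vol[8:10, 8:10, 8:10] <- 9              # real lesion
  sv <- suvVolume(vol, 2)
  liver <- array(FALSE, n); liver[1, 1, 14] <- TRUE
  les <- extractLesions(sv, 4, liver)
  expect_equal(nLesions(les), 1L)
  expect_equal(lesionStats(les)$voxels, 27L)
})

test_that("segmentation invariants hold across random phantoms", {
  for (seed in 1:6) {
    ph <- generatePhantom(smallPhantomSpec(seed = seed))
    les <- segmentVolume(ph$volume, ph$truth$liverCenterMm)
    st <- lesionStats(les)
    expect_equal(tmtv(les), sum(st$mtv_cm3), tolerance = 1e-12)
    expect_true(all(st$suvmean <= st$suvmax + 1e-12))
    # every lesion voxel is at or above the threshold
    vals <- suvValues(ph$volume)[les@labelMap > 0]
    expect_true(all(vals >= les@threshold))
    # labels partition the supra-threshold voxels: pairwise disjoint by
    # construction of a label map; check count consistency instead
    expect_equal(sum(st$voxels), sum(les@labelMap > 0))
  }
})

test_that("high-contrast phantom lesions are recovered with Dice >= 0.8", {
  ph <- generatePhantom(smallPhantomSpec(seed = 42, nLesions = 3L,
                                         lesionPeakSuvRange = c(10, 16)))
  les <- segmentVolume(ph$volume, ph$truth$liverCenterMm)
  expect_gte(nLesions(les), 3L)
  for (lb in ph$truth$lesions$label) {
    truthMask <- ph$truth$labelMap == lb
    # best-matching extracted lesion
    dices <- vapply(lesionStats(les)$label, function(l2)
      dice(truthMask, lesionMask(les, l2)), numeric(1))
    expect_gte(max(dices), 0.8)
  }
})
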