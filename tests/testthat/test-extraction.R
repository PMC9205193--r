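test_that("MDL recovers a planted low-rank order", {
  hits <- 0L
  for (s in 1:20) {
    set.seed(s)
    A <- matrix(rnorm(100 * 3), 100, 3)
    S <- matrix(rnorm(3 * 800), 3, 800)
    X <- A %*% S + matrix(rnorm(100 * 800, sd = 0.01), 100, 800)
    if (estimateComponentCount(X) == 3L) hits <- hits + 1L
  }
  expect_gte(hits, 15L)  # majority vote
})

test_that("MDL stays low on pure i.i.d. noise", {
  low <- 0L
  for (s in 1:20) {
    set.seed(s + 100)
    X <- matrix(rnorm(30 * 600), 30, 600)
    if (estimateComponentCount(X) <= 2L) low <- low + 1L
  }
  expect_gte(low, 18L)  # >= 90% of seeds
})

test_that("MDL is invariant to duplicating voxel columns", {
  vox <- simulateVoxelData(syntheticConfig(seed = 4, voxelsPerRoi = 20))
  K1 <- estimateComponentCount(vox$X)
  K2 <- estimateComponentCount(cbind(vox$X, vox$X))
  expect_identical(K1, K2)
})

test_that("MDL rejects degenerate input", {
  expect_error(estimateComponentCount(matrix(1, 10, 50)), "degenerate")
  expect_error(estimateComponentCount(matrix(rnorm(100), 2, 50)),
               "3 subjects")
  # rank-1 input: spectrum collapses beyond the first eigenvalue
  a <- rnorm(10); s <- rnorm(50)
  expect_error(estimateComponentCount(outer(a, s)), "degenerate")
})

test_that("ICA recovers noiseless sources up to permutation and sign", {
  set.seed(21)
  A <- matrix(rnorm(30 * 2, mean = 1), 30, 2)
  S <- rbind(c(rexp(200) * (runif(200) < 0.3), rep(0, 200)),
             c(rep(0, 200), rexp(200) * (runif(200) < 0.3)))
  X <- A %*% S
  dec <- decomposeComponents(X, 2, seed = 1)
  cm <- abs(cor(t(dec@sources), t(S)))
  expect_true(all(apply(cm, 2, max) >= 0.99))
})

test_that("rank-1 decomposition returns a mixing column proportional to the loading", {
  set.seed(8)
  a <- rnorm(12, mean = 2)
  s <- rexp(300) * (runif(300) < 0.4)
  X <- outer(a, s)
  dec <- decomposeComponents(X, 1, seed = 2)
  expect_gt(abs(cor(dec@mixing[, 1], a)), 1 - 1e-8)
})

test_that("decomposition is deterministic given the seed", {
  vox <- simulateVoxelData(syntheticConfig(m1 = 15, m2 = 15,
                                           voxelsPerRoi = 30, seed = 6))
  d1 <- decomposeComponents(vox$X, 4, seed = 33)
  d2 <- decomposeComponents(vox$X, 4, seed = 33)
  expect_identical(d1@mixing, d2@mixing)
  expect_identical(d1@sources, d2@sources)
})

test_that("source rows are z-scored with nonnegative skewness", {
  vox <- simulateVoxelData(syntheticConfig(m1 = 15, m2 = 15,
                                           voxelsPerRoi = 30, seed = 7))
  dec <- decomposeComponents(vox$X, 4, seed = 1)
  expect_equal(unname(rowMeans(dec@sources)), rep(0, 4), tolerance = 1e-10)
  expect_equal(unname(apply(dec@sources, 1, sd)), rep(1, 4),
               tolerance = 1e-10)
  expect_true(all(rowMeans(dec@sources^3) >= 0))
})

test_that("component selection finds a planted mixing shift", {
  hits <- 0L
  for (s in 1:10) {
    set.seed(s)
    mixing <- matrix(rnorm(80 * 10), 80, 10)
    g <- rep(c("AD", "NC"), each = 40)
    mixing[g == "AD", 4] <- mixing[g == "AD", 4] + 2
    sel <- selectDiscriminativeComponents(mixing, g)
    if (4L %in% sel) hits <- hits + 1L
  }
  expect_equal(hits, 10L)
})

test_that("component selection is calibrated under permuted labels", {
  nSel <- integer(200)
  for (s in seq_len(200)) {
    set.seed(s + 300)
    mixing <- matrix(rnorm(40 * 8), 40, 8)
    g <- sample(rep(c("AD", "NC"), each = 20))
    nSel[s] <- length(selectDiscriminativeComponents(mixing, g))
  }
  # Bonferroni at 0.05 implies about 0.05 expected selections per dataset
  expect_lt(mean(nSel), 0.15)
})

test_that("component selection rejects degenerate inputs", {
  expect_error(selectDiscriminativeComponents(matrix(rnorm(20), 10, 2),
                                              rep("AD", 10)),
               "two groups")
  const <- matrix(1, 20, 2)
  expect_error(selectDiscriminativeComponents(
    const, rep(c("AD", "NC"), each = 10)), "degenerate")
})

test_that("binarisation thresholds a z-scored map", {
  expect_equal(binarizeComponentMap(c(4, 2, 3.5), 3), c(TRUE, FALSE, TRUE))
  expect_error(binarizeComponentMap(c(1, 2, 2.9), 3, component = 7), "7")
  expect_equal(binarizeComponentMap(c(0, 1, 2), 0), rep(TRUE, 3))
})

test_that("top-ROI selection ranks regions by overlap with tie-breaking", {
  atlas <- rep(c(1, 2, 3, 4), c(100, 50, 30, 10))
  mask <- rep(TRUE, 190)
  ids <- selectTopRois(mask, atlas, k = 3)
  expect_equal(as.integer(ids), c(1L, 2L, 3L))
  expect_equal(attr(ids, "counts"), c(100L, 50L, 30L))
  # tie -> ascending region id
  atlas2 <- rep(c(5, 2), c(50, 50))
  expect_equal(as.integer(selectTopRois(rep(TRUE, 100), atlas2, k = 1)), 2L)
  # zero overlap -> empty with warning
  expect_warning(res <- selectTopRois(rep(FALSE, 100), atlas2, k = 1),
                 "overlap")
  expect_length(res, 0L)
  expect_error(selectTopRois(rep(TRUE, 5), atlas2), "length")
})

test_that("original features are mask-restricted means", {
  # hand-computed toy: 2 subjects, 6 voxels, one network over regions 1..2
  X <- rbind(c(1, 2, 3, 4, 5, 6),
             c(6, 5, 4, 3, 2, 1))
  atlas <- c(1, 1, 1, 2, 2, 2)
  mask <- c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE)
  mk <- methods::new("NetworkMask", component = 1L, mask = mask,
                     roiIds = c(1L, 2L), roiCounts = c(2L, 2L))
  mk2 <- methods::new("NetworkMask", component = 2L,
                      mask = c(FALSE, FALSE, TRUE, FALSE, FALSE, TRUE),
                      roiIds = c(1L, 2L), roiCounts = c(1L, 1L))
  fs <- computeOriginalFeatures(X, list(mk, mk2), atlas,
                                groups = c("AD", "NC"))
  z <- featureMatrix(fs)
  expect_equal(unname(z[, 1]), c(mean(c(1, 2)), mean(c(6, 5))))
  expect_equal(unname(z[, 2]), c(mean(c(4, 5)), mean(c(3, 2))))
  # single-voxel ROIs of the second mask are identities
  expect_equal(unname(z[, 3]), X[, 3])
  expect_equal(unname(z[, 4]), X[, 6])
  # network value = mean over all mask voxels
  expect_equal(unname(networkValues(fs)[, 1]),
               rowMeans(X[, mask]))
  # constant input gives constant features
  fsC <- computeOriginalFeatures(matrix(7, 2, 6), list(mk, mk2), atlas,
                                 groups = c("AD", "NC"))
  expect_true(all(featureMatrix(fsC) == 7))
})

test_that("original features are invariant to a consistent voxel permutation", {
  vox <- simulateVoxelData(syntheticConfig(m1 = 10, m2 = 10,
                                           voxelsPerRoi = 30, seed = 12))
  dec <- decomposeComponents(vox$X, 2, seed = 1)
  mk <- networkMask(dec@sources[1, ], vox$atlas, component = 1L,
                    zThreshold = 2, k = 2)
  fs1 <- computeOriginalFeatures(vox$X, list(mk), vox$atlas, vox$groups)
  set.seed(5)
  perm <- sample(ncol(vox$X))
  mkP <- methods::new("NetworkMask", component = 1L, mask = mk@mask[perm],
                      roiIds = mk@roiIds, roiCounts = mk@roiCounts)
  fs2 <- computeOriginalFeatures(vox$X[, perm], list(mkP), vox$atlas[perm],
                                 vox$groups)
  expect_equal(featureMatrix(fs1), featureMatrix(fs2))
  expect_equal(networkValues(fs1), networkValues(fs2))
})
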