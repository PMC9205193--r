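singleBlockDesign <- function(values, kind = "OFM_ROI") {
  methods::new("CoupledDesign", kind = kind, values = as.matrix(values),
               blocks = list(all = seq_len(ncol(as.matrix(values)))))
}

test_that("a separable single-block toy is learned with zero training error", {
  X <- matrix(c(-3, -2, -1.5, 1.5, 2, 3), 6, 1)
  y <- rep(c("NC", "AD"), each = 3)
  ens <- trainBlockBoostedSvm(singleBlockDesign(X), y, positive = "AD")
  expect_length(ens@learners, 1L)
  expect_equal(as.character(predict(ens, X)), y)
  expect_lt(ens@learners[[1]]$error, 1e-6)
})

test_that("vote weight follows the closed form alpha = log((1-eps)/eps)/2", {
  # constant zero feature, 6 positives vs 2 negatives: the weighted
  # squared-hinge optimum is b = 0.5 > 0, so exactly the negatives are
  # misclassified: eps = 0.25 and alpha = log(3)/2
  X <- matrix(0, 8, 1)
  y <- c(rep("AD", 6), "NC", "NC")
  ens <- trainBlockBoostedSvm(singleBlockDesign(X), y, positive = "AD")
  expect_equal(ens@learners[[1]]$error, 0.25, tolerance = 1e-9)
  expect_equal(ens@learners[[1]]$alpha, 0.5 * log(3), tolerance = 1e-9)
  # misclassified sample weights rise, the rest fall, and they renormalise
  expect_equal(sum(ens@weightHistory[1, ]), 1)
  expect_gt(ens@weightHistory[1, 7], 1 / 8)
})

test_that("identical separable blocks give equal votes and the single-SVM rule", {
  set.seed(1)
  x <- c(runif(10, -3, -1.5), runif(10, 1.5, 3))  # cleanly separated
  y <- rep(c("NC", "AD"), each = 10)
  X2 <- cbind(x, x)
  d2 <- methods::new("CoupledDesign", kind = "CFM_network", values = X2,
                     blocks = list(net1 = 1L, net2 = 2L))
  ens2 <- trainBlockBoostedSvm(d2, y, positive = "AD")
  a <- vapply(ens2@learners, `[[`, numeric(1), "alpha")
  expect_equal(a[1], a[2], tolerance = 1e-6)
  single <- trainBlockBoostedSvm(singleBlockDesign(matrix(x)), y,
                                 positive = "AD")
  expect_equal(predict(ens2, d2), predict(single, matrix(x)))
})

test_that("an ensemble of L+1 learners is trained on CFM_network designs", {
  sim <- simulateFeatureSet(syntheticConfig(m1 = 15, m2 = 15, L = 3,
                                            seed = 21))
  d <- assembleDesign(sim$features, "CFM_network", E1 = 2, E2 = 1)
  ens <- trainBlockBoostedSvm(d, groups(sim$features))
  expect_length(ens@learners, 4L)   # L + 1
  expect_true(all(vapply(ens@learners, `[[`, numeric(1), "alpha") >= 0))
})

test_that("prediction follows the weighted vote with positive tie rule", {
  # all vote weights zero: balanced classes on a constant feature
  X <- matrix(0, 4, 1)
  y <- c("AD", "AD", "NC", "NC")
  ens <- trainBlockBoostedSvm(singleBlockDesign(X), y, positive = "AD")
  expect_equal(vapply(ens@learners, `[[`, numeric(1), "alpha"), 0)
  expect_warning(p <- predict(ens, X), "zero")
  expect_true(all(p == "AD"))
})

test_that("negating every learner flips the predictions", {
  set.seed(2)
  X <- matrix(rnorm(40), 20, 2)
  y <- ifelse(X[, 1] + 0.3 * X[, 2] > 0, "AD", "NC")
  ens <- trainBlockBoostedSvm(singleBlockDesign(X), y, positive = "AD")
  flipped <- ens
  flipped@learners <- lapply(ens@learners, function(ln) {
    ln$w <- -ln$w; ln$b <- -ln$b; ln
  })
  p <- predict(ens, X); pf <- predict(flipped, X)
  dec <- abs(drop(X %*% ens@learners[[1]]$w) + ens@learners[[1]]$b)
  nontie <- dec > 1e-9
  expect_true(all(p[nontie] != pf[nontie]))
})

test_that("metrics implement the confusion-matrix definitions", {
  yt <- c(rep("AD", 10), rep("NC", 10))
  yp <- c(rep("AD", 9), "NC", rep("NC", 8), "AD", "AD")
  m <- computeMetrics(yt, yp, positive = "AD")
  expect_equal(unname(m), c(17 / 20, 9 / 10, 8 / 10))
  expect_equal(unname(computeMetrics(yt, yt, "AD")), c(1, 1, 1))
  inv <- ifelse(yt == "AD", "NC", "AD")
  expect_equal(computeMetrics(yt, inv, "AD")[["accuracy"]], 0)
  expect_error(computeMetrics(rep("AD", 5), rep("AD", 5), "AD"),
               "single class")
})

test_that("stratified folds partition subjects and balance classes", {
  labels <- rep(c("AD", "NC"), c(25, 35))
  fold <- netCFM:::stratifiedFolds(labels, 10, seed = 3)
  expect_equal(sort(unique(fold)), 1:10)
  expect_true(all(table(fold) %in% 5:7))
  for (fd in 1:10) {
    expect_true(all(table(labels[fold == fd]) >= 2))
  }
  expect_identical(fold, netCFM:::stratifiedFolds(labels, 10, seed = 3))
})

test_that("cross-validation is deterministic and reports per-fold metrics", {
  sim <- simulateFeatureSet(syntheticConfig(m1 = 12, m2 = 12, L = 2,
                                            seed = 31))
  r1 <- evaluateCV(sim$features, "OFM_network", nFolds = 4, seed = 5)
  r2 <- evaluateCV(sim$features, "OFM_network", nFolds = 4, seed = 5)
  expect_identical(r1, r2)
  expect_equal(dim(r1$folds), c(4L, 3L))
  expect_equal(unname(r1$mean["accuracy"]),
               mean(r1$folds[, "accuracy"]))
  expect_error(evaluateCV(sim$features, "OFM_ROI", nFolds = 20),
               "folds")
})

test_that("planted strong signal is classified well by CFM_network", {
  sim <- simulateFeatureSet(syntheticConfig(m1 = 20, m2 = 20, rho = 0.8,
                                            effectSize = 2, affected = 1:2,
                                            seed = 41))
  r <- evaluateCV(sim$features, "CFM_network", E1 = 2, E2 = 1, seed = 7)
  expect_gt(r$mean[["accuracy"]], 0.8)
})

test_that("held-out rows never influence the fitted fold models", {
  sim <- simulateFeatureSet(syntheticConfig(m1 = 12, m2 = 12, L = 2,
                                            seed = 51))
  fs <- sim$features
  fitRows <- 5:24
  d1 <- assembleDesign(fs, "CFM_network", E1 = 2, E2 = 2, fitRows = fitRows)
  vals <- featureMatrix(fs)
  vals[1:4, ] <- vals[1:4, ] + 10
  fs2 <- RoiFeatureSet(vals, networkMap(fs), as.character(groups(fs)))
  d2 <- assembleDesign(fs2, "CFM_network", E1 = 2, E2 = 2, fitRows = fitRows)
  expect_equal(designMatrix(d1)[fitRows, ], designMatrix(d2)[fitRows, ])
  e1 <- trainBlockBoostedSvm(
    methods::new("CoupledDesign", kind = "CFM_network",
                 values = designMatrix(d1)[fitRows, ], blocks = d1@blocks),
    groups(fs)[fitRows])
  e2 <- trainBlockBoostedSvm(
    methods::new("CoupledDesign", kind = "CFM_network",
                 values = designMatrix(d2)[fitRows, ], blocks = d2@blocks),
    groups(fs2)[fitRows])
  expect_equal(e1@learners, e2@learners)
})

test_that("the boosting bound holds when every vote weight is positive", {
  sim <- simulateFeatureSet(syntheticConfig(m1 = 15, m2 = 15, effectSize = 1,
                                            affected = 1:2, seed = 61))
  d <- assembleDesign(sim$features, "CFM_network", E1 = 2, E2 = 1)
  ens <- trainBlockBoostedSvm(d, groups(sim$features))
  a <- vapply(ens@learners, `[[`, numeric(1), "alpha")
  eps <- vapply(ens@learners, `[[`, numeric(1), "error")
  if (all(a > 0)) {
    trainErr <- mean(predict(ens, d) != groups(sim$features))
    expect_lte(trainErr, prod(2 * sqrt(eps * (1 - eps))) + 1e-12)
  }
})

test_that("grid search spans the configured cells and flags one best", {
  sim <- simulateFeatureSet(syntheticConfig(m1 = 12, m2 = 12, L = 2,
                                            seed = 71))
  g1 <- gridSearch(sim$features, kinds = "OFM_ROI", nFolds = 3, seed = 1)
  expect_equal(nrow(g1), 1L)
  g2 <- gridSearch(sim$features, kinds = "CFM_network", E1Grid = 2:3,
                   E2Grid = 1:2, nFolds = 3, seed = 1)
  expect_equal(nrow(g2), 4L)
  expect_equal(sum(g2$best), 1L)
  g3 <- gridSearch(sim$features, kinds = c("OFM_network", "CFM_ROI"),
                   E1Grid = c(2, 4), nFolds = 3, seed = 1)
  expect_equal(nrow(g3), 3L)
})
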