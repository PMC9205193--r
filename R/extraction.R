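# Network extraction from subjects x voxels gray-matter matrices:
# MDL order selection, fixed-point spatial ICA, group testing of mixing
# coefficients, map binarisation and atlas-based ROI selection.

#' Estimate the number of components by minimum description length
#'
#' Computes the eigenvalue-based MDL order-selection criterion (the
#' Wax-Kailath form used by group-ICA tooling) on the spectrum of the
#' subjects x subjects covariance of the row-centered data, treating voxels
#' as observations.  Returns the order `K` minimising the criterion,
#' `1 <= K < subjects`.
#'
#' @param X numeric matrix, subjects x voxels.
#' @return integer component count.
#' @export
estimateComponentCount <- function(X) {
  X <- as.matrix(X)
  M <- nrow(X); V <- ncol(X)
  if (M < 3L) stop("degenerate input: need at least 3 subjects")
  Xc <- X - rowMeans(X)
  ev <- eigen(tcrossprod(Xc) / V, symmetric = TRUE, only.values = TRUE)$values
  # row-centering removes one degree of freedom; drop the trailing
  # (numerically zero) eigenvalue
  p <- M - 1L
  lambda <- pmax(ev[seq_len(p)], 0)
  if (lambda[1] <= 1e-12 || lambda[2] <= 1e-12 * lambda[1]) {
    stop("degenerate input: covariance spectrum is (near-)rank-1 or constant")
  }
  lambda <- pmax(lambda, .Machine$double.eps * lambda[1])
  mdl <- vapply(seq_len(p - 1L), function(k) {
    tail <- lambda[(k + 1):p]
    logG <- mean(log(tail))
    logA <- log(mean(tail))
    -V * (p - k) * (logG - logA) + 0.5 * k * (2 * p - k + 1) * log(V)
  }, numeric(1))
  which.min(mdl)
}

#' Decompose a gray-matter matrix into independent spatial components
#'
#' Spatial ICA: the row-centered data are whitened by PCA to `K` components
#' and unmixed by symmetric fixed-point iteration maximising negentropy
#' (tanh contrast), so the rows of `sources` are maximally independent
#' spatial maps.  Each source row is z-scored across voxels and its sign
#' fixed so the row skewness is nonnegative; the mixing matrix is the
#' least-squares projection of the centered data onto the sources.
#' Deterministic given `seed`; up to 5 restarts with derived sub-seeds on
#' non-convergence.
#'
#' @param X numeric matrix, subjects x voxels.
#' @param K number of components, `1 <= K < subjects`.
#' @param seed integer seed for the random orthogonal initialisation.
#' @param tol convergence tolerance of the fixed-point iteration.
#' @param maxIter maximum iterations per restart.
#' @return An [IcaDecomposition-class].
#' @export
decomposeComponents <- function(X, K, seed = 1, tol = 1e-6, maxIter = 1000) {
  X <- as.matrix(X)
  M <- nrow(X); V <- ncol(X)
  if (K < 1L || K >= M) stop("K must satisfy 1 <= K < subjects")
  Xc <- X - rowMeans(X)
  eg <- eigen(tcrossprod(Xc) / V, symmetric = TRUE)
  if (eg$values[K] <= 1e-12 * max(eg$values[1], 1e-300)) {
    stop("degenerate input: data rank below K")
  }
  E <- eg$vectors[, seq_len(K), drop = FALSE]
  D <- eg$values[seq_len(K)]
  Y <- diag(1 / sqrt(D), K) %*% t(E) %*% Xc   # K x V, white across voxels
  res <- best <- NULL
  for (attempt in 0:5) {
    res <- fastIcaCore(Y, subSeed(seed, 11 + attempt), tol, maxIter)
    if (res$converged) break
    if (is.null(best) || res$delta < best$delta) best <- res
  }
  if (!res$converged) {
    # a mildly unconverged fixed point is still a usable rotation; a large
    # residual means the components are not identifiable at this K
    if (best$delta < 1e-3) {
      res <- best
      warning(sprintf(
        "ICA stopped short of tol %g (residual %.2g after %d iterations); using best attempt",
        tol, best$delta, best$iterations))
    } else {
      stop(sprintf(
        "ICA failed to converge after %d restarts (%d iterations, tol %g, residual %.2g)",
        5L, res$iterations, tol, res$delta))
    }
  }
  S <- res$W %*% Y                            # K x V
  # z-score rows, fix sign by nonnegative skewness
  S <- S - rowMeans(S)
  S <- S / apply(S, 1, sd)
  skew <- rowMeans(S^3)
  flip <- ifelse(skew < 0, -1, 1)
  S <- S * flip
  A <- Xc %*% t(S) %*% solve(tcrossprod(S))
  rownames(S) <- colnames(A) <- sprintf("IC%d", seq_len(K))
  rownames(A) <- rownames(X)
  methods::new("IcaDecomposition", mixing = A, sources = S,
               iterations = res$iterations, converged = res$converged)
}

# Symmetric fixed-point FastICA on whitened K x V data, cubic (kurtosis)
# contrast: W+ = E[(Wy)^3 y^T] - 3 W, symmetric decorrelation each step.
fastIcaCore <- function(Y, seed, tol, maxIter) {
  K <- nrow(Y); V <- ncol(Y)
  W <- withSeed(seed, matrix(rnorm(K * K), K, K))
  W <- symDecorrelate(W)
  iter <- 0L; converged <- FALSE
  while (iter < maxIter) {
    iter <- iter + 1L
    WY <- W %*% Y
    Wnew <- symDecorrelate((WY^3) %*% t(Y) / V - 3 * W)
    delta <- max(abs(abs(diag(Wnew %*% t(W))) - 1))
    W <- Wnew
    if (delta < tol) { converged <- TRUE; break }
  }
  list(W = W, iterations = iter, converged = converged, delta = delta)
}

# W <- (W W^T)^{-1/2} W
symDecorrelate <- function(W) {
  eg <- eigen(tcrossprod(W), symmetric = TRUE)
  eg$vectors %*% diag(1 / sqrt(pmax(eg$values, 1e-300)),
                      length(eg$values)) %*% t(eg$vectors) %*% W
}

#' Select components whose mixing coefficients differ between groups
#'
#' Runs a two-sided two-sample t-test (pooled variance) on every mixing
#' column and keeps the components significant at the Bonferroni-corrected
#' level `alpha / K`, in their original order.
#'
#' @param mixing subjects x K mixing matrix (or an
#'   [IcaDecomposition-class]).
#' @param groups two-level factor of subject labels.
#' @param alpha family-wise significance level (default 0.05).
#' @return integer vector of selected component indices.
#' @export
selectDiscriminativeComponents <- function(mixing, groups, alpha = 0.05) {
  if (methods::is(mixing, "IcaDecomposition")) mixing <- mixing@mixing
  groups <- factor(groups)
  if (nlevels(groups) != 2L) {
    stop("need exactly two groups (got ", nlevels(groups), ")")
  }
  if (any(table(groups) < 2L)) stop("each group needs at least 2 subjects")
  K <- ncol(mixing)
  p <- vapply(seq_len(K), function(j) {
    tt <- tryCatch(
      t.test(mixing[, j] ~ groups, var.equal = TRUE),
      error = function(e) stop("degenerate input in component ", j, ": ",
                               conditionMessage(e), call. = FALSE))
    tt$p.value
  }, numeric(1))
  which(p < alpha / K)
}

#' Binarise a z-scored component map
#'
#' @param source numeric vector, one z-scored source row.
#' @param zThreshold inclusion threshold (default 3): a voxel enters the
#'   mask when its z value is `>= zThreshold`.
#' @param component integer label used in error messages.
#' @return logical mask vector.
#' @export
binarizeComponentMap <- function(source, zThreshold = 3, component = NA_integer_) {
  mask <- source >= zThreshold
  if (!any(mask)) {
    stop(sprintf("component %s: no voxel reaches z >= %g",
                 as.character(component), zThreshold))
  }
  mask
}

#' Rank atlas regions by in-mask voxel count
#'
#' Counts, for every atlas region, the voxels falling inside the mask and
#' returns the `k` regions with the largest counts (ties broken by
#' ascending region id).  Regions with zero overlap are never returned;
#' when fewer than `k` regions overlap, the available ones are returned
#' with a warning.
#'
#' @param mask logical voxel vector.
#' @param atlas integer region label per voxel, same length as `mask`.
#' @param k number of regions to keep (default 3).
#' @return integer region ids with an integer `counts` attribute.
#' @export
selectTopRois <- function(mask, atlas, k = 3) {
  if (length(mask) != length(atlas)) {
    stop("atlas length (", length(atlas), ") does not match mask length (",
         length(mask), ")")
  }
  counts <- table(factor(atlas[mask], levels = sort(unique(atlas))))
  counts <- counts[counts > 0]
  if (length(counts) < k) {
    warning(sprintf("only %d region(s) overlap the mask (asked for %d)",
                    length(counts), k))
  }
  ids <- as.integer(names(counts))
  ord <- order(-as.integer(counts), ids)
  keep <- head(ord, k)
  structure(ids[keep], counts = as.integer(counts)[keep])
}

#' Build a network mask from one component
#'
#' Convenience wrapper: binarise the z-scored source row, rank atlas
#' regions by overlap and keep the top `k`.
#'
#' @param source z-scored source row.
#' @param atlas integer region label per voxel.
#' @param component component index (for messages).
#' @param zThreshold binarisation threshold.
#' @param k regions to keep per network.
#' @return A [NetworkMask-class].
#' @export
networkMask <- function(source, atlas, component = NA_integer_,
                        zThreshold = 3, k = 3) {
  mask <- binarizeComponentMap(source, zThreshold, component)
  ids <- selectTopRois(mask, atlas, k)
  methods::new("NetworkMask", component = as.integer(component), mask = mask,
               roiIds = as.integer(ids),
               roiCounts = attr(ids, "counts"))
}

#' Compute ROI-level and network-level original features
#'
#' For each network mask, the ROI-level feature of region r is the mean of
#' `X` over the voxels in the intersection of region r with the mask, and
#' the network-level feature is the mean of `X` over all mask voxels.
#'
#' @param X subjects x voxels matrix.
#' @param masks list of [NetworkMask-class], one per retained network.
#' @param atlas integer region label per voxel.
#' @param groups two-level subject labels.
#' @return A [RoiFeatureSet-class] whose `networkValues` are the mask
#'   means.
#' @export
computeOriginalFeatures <- function(X, masks, atlas, groups) {
  stopifnot(length(masks) >= 1)
  M <- nrow(X)
  L <- length(masks)
  roiVals <- list(); netVals <- matrix(0, M, L)
  network <- integer(0); featureIds <- character(0)
  for (l in seq_len(L)) {
    mk <- masks[[l]]
    if (length(mk@mask) != length(atlas)) {
      stop("network ", l, ": mask length does not match atlas")
    }
    netVals[, l] <- rowMeans(X[, mk@mask, drop = FALSE])
    for (r in mk@roiIds) {
      vox <- which(mk@mask & atlas == r)
      if (!length(vox)) {
        stop(sprintf("network %d: region %d has no voxels inside the mask",
                     l, r))
      }
      roiVals[[length(roiVals) + 1L]] <- rowMeans(X[, vox, drop = FALSE])
      network <- c(network, l)
      featureIds <- c(featureIds, sprintf("net%d_roi%d", l, r))
    }
  }
  vals <- do.call(cbind, roiVals)
  colnames(vals) <- featureIds
  RoiFeatureSet(vals, network = network, groups = groups,
                networkValues = netVals, subjectIds = rownames(X),
                featureIds = featureIds)
}

#' Run the full network-extraction pipeline
#'
#' MDL order selection, spatial ICA, group testing of the mixing
#' coefficients, binarisation of the significant components and
#' ROI/network feature computation, in one call.
#'
#' @param X subjects x voxels matrix.
#' @param atlas integer region label per voxel.
#' @param groups two-level subject labels.
#' @param alpha Bonferroni family-wise level for component selection.
#' @param zThreshold binarisation threshold on the z-scored maps.
#' @param k regions kept per network.
#' @param K optional fixed component count (default: MDL estimate).
#' @param seed integer seed for the ICA initialisation.
#' @return A list with `features` (a [RoiFeatureSet-class]),
#'   `decomposition`, `selected` (component indices) and `masks`.
#' @export
extractNetworkFeatures <- function(X, atlas, groups, alpha = 0.05,
                                   zThreshold = 3, k = 3, K = NULL,
                                   seed = 1) {
  if (is.null(K)) K <- estimateComponentCount(X)
  dec <- decomposeComponents(X, K, seed = seed)
  sel <- selectDiscriminativeComponents(dec@mixing, groups, alpha)
  if (!length(sel)) stop("no component passed the Bonferroni selection")
  masks <- lapply(sel, function(j) {
    networkMask(dec@sources[j, ], atlas, component = j,
                zThreshold = zThreshold, k = k)
  })
  feats <- computeOriginalFeatures(X, masks, atlas, groups)
  list(features = feats, decomposition = dec, selected = sel, masks = masks)
}
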