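#' Construct a RoiFeatureSet
#'
#' @param values numeric matrix, subjects x ROI features.
#' @param network integer vector, length `ncol(values)`: network id (1..L)
#'   of each feature.  Every network must have the same number of features.
#' @param groups factor or character, length `nrow(values)`: two-level
#'   subject group labels.
#' @param networkValues optional subjects x L matrix of network-level
#'   features; when `NULL`, network feature j is the row-wise mean of
#'   network j's ROI columns.
#' @param subjectIds,featureIds optional identifiers.
#' @return A [RoiFeatureSet-class].
#' @examples
#' x <- matrix(rnorm(40 * 6), 40, 6)
#' fs <- RoiFeatureSet(x, network = rep(1:2, each = 3),
#'                     groups = rep(c("AD", "NC"), each = 20))
#' fs
#' @export
RoiFeatureSet <- function(values, network, groups, networkValues = NULL,
                          subjectIds = NULL, featureIds = NULL) {
  values <- as.matrix(values)
  M <- nrow(values); N <- ncol(values)
  if (length(network) != N) {
    stop("network map must assign every feature column (got ",
         length(network), " assignments for ", N, " features)")
  }
  network <- as.integer(network)
  if (length(groups) != M) stop("need one group label per subject")
  if (is.null(subjectIds)) {
    subjectIds <- rownames(values)
    if (is.null(subjectIds)) subjectIds <- sprintf("S%03d", seq_len(M))
  }
  if (anyDuplicated(subjectIds)) {
    stop("duplicate subject id: ",
         subjectIds[anyDuplicated(subjectIds)])
  }
  L <- length(unique(network))
  if (is.null(featureIds)) {
    featureIds <- colnames(values)
    if (is.null(featureIds)) {
      featureIds <- character(N)
      for (l in seq_len(L)) {
        idx <- which(network == l)
        featureIds[idx] <- sprintf("net%d_roi%d", l, seq_along(idx))
      }
    }
  }
  dimnames(values) <- NULL
  if (is.null(networkValues)) {
    networkValues <- vapply(seq_len(L), function(l) {
      rowMeans(values[, network == l, drop = FALSE])
    }, numeric(M))
    networkValues <- matrix(networkValues, nrow = M)
  }
  colnames(networkValues) <- sprintf("net%d", seq_len(L))
  rownames(networkValues) <- subjectIds
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(gmv = t(values)),
    rowData = S4Vectors::DataFrame(network = network, row.names = featureIds),
    colData = S4Vectors::DataFrame(group = factor(groups),
                                   row.names = subjectIds))
  methods::new("RoiFeatureSet", se, networkValues = networkValues)
}

#' Configure the two-group synthetic generator
#'
#' Defines a population of `L` brain networks with `n` ROI features each.
#' ROI features within a network are equicorrelated Gaussians (correlation
#' `rho`, marginal standard deviation `noiseSd`), independent across
#' networks.  Networks in `affected` carry the group difference: the patient
#' group's mean is lowered by `effectSize * noiseSd` (gray-matter atrophy)
#' and its within-network correlation is changed by `rhoShift` (a
#' coupling-borne difference invisible to per-feature means).  In voxel
#' mode each network is a contiguous spatial component spanning `n` atlas
#' regions of `voxelsPerRoi` voxels; subject maps are mixing coefficients
#' times component maps plus Gaussian voxel noise, and the group difference
#' is planted in the mixing coefficients of affected networks.
#'
#' @param m1,m2 subjects in the patient and control group (>= 10).
#' @param L number of networks (>= 2).
#' @param n ROI features per network (>= 2).
#' @param rho within-network equicorrelation in \[0, 1).
#' @param affected integer network indices carrying the group difference.
#' @param effectSize standardized mean shift (Cohen's d units).
#' @param rhoShift additive correlation change in the patient group.
#' @param noiseSd marginal feature sd (feature mode) / additive voxel noise
#'   sd (voxel mode).
#' @param voxelsPerRoi voxels per atlas region (voxel mode).
#' @param mixingSd between-subject sd of the mixing coefficients (voxel
#'   mode).
#' @param seed integer root seed; all randomness derives from it.
#' @return A validated [SyntheticConfig-class].
#' @export
syntheticConfig <- function(m1 = 40, m2 = 40, L = 4, n = 3, rho = 0.5,
                            affected = 1, effectSize = 2, rhoShift = 0,
                            noiseSd = 0.1, voxelsPerRoi = 50,
                            mixingSd = 0.5, seed = 1) {
  methods::new("SyntheticConfig",
    m1 = as.integer(m1), m2 = as.integer(m2), L = as.integer(L),
    n = as.integer(n), rho = as.numeric(rho),
    affected = as.integer(affected), effectSize = as.numeric(effectSize),
    rhoShift = as.numeric(rhoShift), noiseSd = as.numeric(noiseSd),
    voxelsPerRoi = as.integer(voxelsPerRoi), mixingSd = as.numeric(mixingSd),
    seed = as.integer(seed))
}

# Cholesky factor of an n x n equicorrelation matrix scaled to sd.
equicorChol <- function(n, rho, sd) {
  sigma <- sd^2 * ((1 - rho) * diag(n) + rho * matrix(1, n, n))
  chol(sigma)
}

#' Simulate a two-group ROI feature table
#'
#' Draws `m1 + m2` subjects with `n * L` ROI features from the population
#' described by `config` (see [syntheticConfig()]).  The first `m1` rows are
#' the patient group ("AD"), the rest controls ("NC").  Network-level
#' features are the row-wise means of each network's ROI columns.
#'
#' @param config a [SyntheticConfig-class].
#' @return A list with `features` (a [RoiFeatureSet-class]) and `truth`
#'   (affected network indices and the true per-group ROI means).
#' @examples
#' sim <- simulateFeatureSet(syntheticConfig(m1 = 20, m2 = 20, seed = 7))
#' sim$features
#' @export
simulateFeatureSet <- function(config) {
  methods::validObject(config)
  if (config@noiseSd == 0) {
    stop("noiseSd: feature mode needs a positive marginal sd")
  }
  withSeed(subSeed(config@seed, 1), {
    m1 <- config@m1; m2 <- config@m2; L <- config@L; n <- config@n
    M <- m1 + m2
    vals <- matrix(0, M, n * L)
    trueMeans <- matrix(0, 2, n * L,
                        dimnames = list(c("AD", "NC"), NULL))
    for (l in seq_len(L)) {
      cols <- (l - 1) * n + seq_len(n)
      hit <- l %in% config@affected
      rhoAD <- if (hit) config@rho + config@rhoShift else config@rho
      cholNC <- equicorChol(n, config@rho, config@noiseSd)
      cholAD <- equicorChol(n, rhoAD, config@noiseSd)
      shift <- if (hit) -config@effectSize * config@noiseSd else 0
      vals[seq_len(m1), cols] <-
        matrix(rnorm(m1 * n), m1, n) %*% cholAD + shift
      vals[m1 + seq_len(m2), cols] <- matrix(rnorm(m2 * n), m2, n) %*% cholNC
      trueMeans["AD", cols] <- shift
    }
    fs <- RoiFeatureSet(vals, network = rep(seq_len(L), each = n),
                        groups = rep(c("AD", "NC"), c(m1, m2)))
    list(features = fs,
         truth = list(affected = config@affected, trueMeans = trueMeans))
  })
}

#' Simulate a two-group subjects x voxels gray-matter matrix
#'
#' Each network l is a spatial component occupying the contiguous voxel
#' block of its `n` atlas regions; within every region the component
#' amplitude ramps linearly up to 1, so after z-scoring each region
#' contributes supra-threshold voxels to the binarised map.  Subject maps
#' are `mixing %*% sources` plus i.i.d. Gaussian noise of sd `noiseSd`;
#' mixing coefficients are N(1, mixingSd^2), lowered by
#' `effectSize * mixingSd` for patients on affected networks.
#'
#' @param config a [SyntheticConfig-class].
#' @return A list with `X` (subjects x voxels), `atlas` (integer region
#'   label per voxel, regions `1..n*L`), `groups`, and `truth` (component
#'   supports, component-to-region map, mixing matrix, affected indices).
#' @examples
#' vox <- simulateVoxelData(syntheticConfig(m1 = 20, m2 = 20,
#'                                          voxelsPerRoi = 10, seed = 3))
#' dim(vox$X)
#' @export
simulateVoxelData <- function(config) {
  methods::validObject(config)
  withSeed(subSeed(config@seed, 2), {
    m1 <- config@m1; m2 <- config@m2; L <- config@L; n <- config@n
    vpr <- config@voxelsPerRoi
    M <- m1 + m2
    V <- L * n * vpr
    atlas <- rep(seq_len(L * n), each = vpr)
    ramp <- seq_len(vpr) / vpr
    sources <- matrix(0, L, V)
    supports <- vector("list", L)
    rois <- vector("list", L)
    for (l in seq_len(L)) {
      sup <- (l - 1) * n * vpr + seq_len(n * vpr)
      sources[l, sup] <- rep(ramp, n)
      supports[[l]] <- sup
      rois[[l]] <- (l - 1) * n + seq_len(n)
    }
    mixing <- matrix(rnorm(M * L, mean = 1, sd = config@mixingSd), M, L)
    for (l in config@affected) {
      mixing[seq_len(m1), l] <-
        mixing[seq_len(m1), l] - config@effectSize * config@mixingSd
    }
    X <- mixing %*% sources
    if (config@noiseSd > 0) {
      X <- X + matrix(rnorm(M * V, sd = config@noiseSd), M, V)
    }
    rownames(X) <- sprintf("S%03d", seq_len(M))
    list(X = X, atlas = atlas,
         groups = factor(rep(c("AD", "NC"), c(m1, m2))),
         truth = list(affected = config@affected, supports = supports,
                      componentRois = rois, mixing = mixing,
                      sources = sources))
  })
}
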