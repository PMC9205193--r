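#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats cor pt sd var rnorm runif optim pnorm setNames t.test predict
#' @importFrom utils read.csv write.csv head
NULL

#' RoiFeatureSet: regional gray-matter features organised into networks
#'
#' A [SummarizedExperiment::SummarizedExperiment] whose rows are ROI-level
#' features (mean gray-matter volume per region) and whose columns are
#' subjects.  `rowData` carries the feature-to-network assignment
#' (`network`, integer 1..L) and the region id (`roi`); `colData` carries the
#' binary group label (`group`).  The object additionally stores the
#' network-level feature matrix (subjects x networks) in the
#' `networkValues` slot: when features come from voxel data this is the mean
#' gray-matter value over the whole network mask, which is not in general the
#' mean of the network's ROI features.
#'
#' Every network must contribute the same number `n` of ROI features, so the
#' total feature count is `N = n * L`.
#'
#' @slot networkValues numeric matrix, subjects x networks.
#' @export
setClass("RoiFeatureSet",
  contains = "SummarizedExperiment",
  representation(networkValues = "matrix")
)

setValidity("RoiFeatureSet", function(object) {
  msg <- character()
  rd <- SummarizedExperiment::rowData(object)
  if (!"network" %in% colnames(rd)) {
    return("rowData must contain a 'network' column")
  }
  net <- as.integer(rd$network)
  L <- length(unique(net))
  if (!setequal(unique(net), seq_len(L))) {
    msg <- c(msg, "network ids must be consecutive integers 1..L")
  }
  tab <- table(net)
  if (length(unique(as.integer(tab))) != 1L) {
    msg <- c(msg, sprintf(
      "every network must have the same number of features (counts: %s)",
      paste(as.integer(tab), collapse = ", ")))
  }
  cd <- SummarizedExperiment::colData(object)
  if (!"group" %in% colnames(cd)) {
    msg <- c(msg, "colData must contain a 'group' column")
  } else if (nlevels(factor(cd$group)) != 2L && ncol(object) > 0L) {
    msg <- c(msg, "group must have exactly two levels")
  }
  a <- SummarizedExperiment::assay(object)
  if (anyNA(a)) msg <- c(msg, "feature values must not contain NA")
  nv <- object@networkValues
  if (nrow(nv) != ncol(object)) {
    msg <- c(msg, "networkValues must have one row per subject")
  }
  if (ncol(nv) != L) {
    msg <- c(msg, "networkValues must have one column per network")
  }
  if (length(msg)) msg else TRUE
})

#' IcaDecomposition: mixing matrix and z-scored source maps
#'
#' Result of the spatial independent component analysis of a
#' subjects x voxels matrix.  `mixing` is subjects x K (each column the
#' subjects' contributions to one component); `sources` is K x voxels, each
#' row z-scored across voxels with its sign fixed so the row skewness is
#' nonnegative.
#'
#' @slot mixing numeric matrix, subjects x K.
#' @slot sources numeric matrix, K x voxels.
#' @slot iterations integer, fixed-point iterations used.
#' @slot converged logical.
#' @export
setClass("IcaDecomposition", representation(
  mixing = "matrix", sources = "matrix",
  iterations = "integer", converged = "logical"
))

setValidity("IcaDecomposition", function(object) {
  if (ncol(object@mixing) != nrow(object@sources)) {
    return("mixing columns must match source rows")
  }
  TRUE
})

#' NetworkMask: binarised component map with member regions
#'
#' @slot component integer component index.
#' @slot mask logical voxel vector (TRUE where the z-scored source map
#'   reaches the threshold).
#' @slot roiIds integer region ids, sorted by descending in-mask voxel count
#'   (ties by ascending id).
#' @slot roiCounts integer in-mask voxel counts parallel to `roiIds`.
#' @export
setClass("NetworkMask", representation(
  component = "integer", mask = "logical",
  roiIds = "integer", roiCounts = "integer"
))

setValidity("NetworkMask", function(object) {
  if (length(object@roiIds) != length(object@roiCounts)) {
    return("roiIds and roiCounts must be parallel")
  }
  if (is.unsorted(rev(object@roiCounts))) {
    return("roiCounts must be non-increasing")
  }
  TRUE
})

#' CouplingWeights: revised-correlation weight matrices for one block
#'
#' For each feature k of an expanded block (n features, powers 1..E1),
#' `intra[[k]]` is the E1 x E1 matrix of revised Pearson correlations between
#' the powers of feature k, and `inter[[k]]` is the E1 x (E1*(n-1)) matrix of
#' revised correlations between powers of k and powers of every other feature
#' (feature-major, power-minor column order).  Correlations whose two-sided
#' p-value exceeds `alpha` are exactly zero.  `taylor` holds the factorial
#' damping weights (1/1!, ..., 1/E1!).
#'
#' @slot n integer, features in the block.
#' @slot E1 integer, expansion order.
#' @slot alpha numeric, significance level of the revision rule.
#' @slot intra list of E1 x E1 matrices.
#' @slot inter list of E1 x (E1*(n-1)) matrices.
#' @slot taylor numeric vector of length E1.
#' @export
setClass("CouplingWeights", representation(
  n = "integer", E1 = "integer", alpha = "numeric",
  intra = "list", inter = "list", taylor = "numeric"
))

setValidity("CouplingWeights", function(object) {
  msg <- character()
  if (length(object@intra) != object@n) msg <- c(msg, "need one intra matrix per feature")
  if (length(object@inter) != object@n) msg <- c(msg, "need one inter matrix per feature")
  for (k in seq_along(object@intra)) {
    Ri <- object@intra[[k]]
    if (!all(dim(Ri) == c(object@E1, object@E1))) {
      msg <- c(msg, sprintf("intra[[%d]] must be E1 x E1", k)); next
    }
    if (any(abs(Ri) > 1 + 1e-9)) msg <- c(msg, "correlations must lie in [-1, 1]")
    if (any(abs(diag(Ri) - 1) > 1e-12)) msg <- c(msg, "intra diagonal must be 1")
  }
  if (length(msg)) msg else TRUE
})

#' IntraCoupling: network-level intra-coupled representation U
#'
#' The subjects x (N*E1) matrix formed by concatenating, network by network,
#' the Taylor-weighted coupled feature blocks.  No column mixes features from
#' two networks; `blocks` records the column range of each network.
#'
#' @slot U numeric matrix, subjects x (N*E1).
#' @slot E1 integer expansion order.
#' @slot blocks list of integer column-index vectors, one per network.
#' @slot weights list of [CouplingWeights-class], one per network.
#' @slot scaling list of min-max scaling parameters used before expansion.
#' @export
setClass("IntraCoupling", representation(
  U = "matrix", E1 = "integer", blocks = "list",
  weights = "list", scaling = "list"
))

#' CcaPair: canonical correlations of one network pair
#'
#' @slot pair integer length-2 network index pair (l1 < l2).
#' @slot correlations numeric, descending canonical correlations in [0, 1].
#' @slot retained numeric, top-E2 correlations zero-padded to length E2.
#' @export
setClass("CcaPair", representation(
  pair = "integer", correlations = "numeric", retained = "numeric"
))

setValidity("CcaPair", function(object) {
  r <- object@correlations
  if (any(r < -1e-9) || any(r > 1 + 1e-9)) return("correlations must lie in [0, 1]")
  if (is.unsorted(rev(r), strictly = FALSE)) return("correlations must be descending")
  TRUE
})

#' InterCoupling: network-level inter-coupled representation f
#'
#' Subjects x L matrix whose column l sums, over the other networks l' and
#' powers e = 1..E2, the scaled network-level feature of l' raised to power e,
#' damped by 1/e! and weighted by the e-th retained canonical correlation of
#' the pair (l, l').
#'
#' @slot f numeric matrix, subjects x L.
#' @slot E2 integer, retained canonical correlation count.
#' @slot cca list of [CcaPair-class] for every unordered network pair.
#' @slot scaling list, min-max parameters for the network-level features.
#' @export
setClass("InterCoupling", representation(
  f = "matrix", E2 = "integer", cca = "list", scaling = "list"
))

#' CoupledDesign: an assembled design matrix with block metadata
#'
#' One of the four benchmark representations: `OFM_ROI` (scaled ROI
#' features), `OFM_network` (scaled network features), `CFM_ROI`
#' (intra-coupling of all ROI features as a single whole-brain block) and
#' `CFM_network` (per-network intra-coupling concatenated with the
#' inter-coupling columns).  `blocks` lists the column indices each base
#' learner of the block-wise ensemble sees.
#'
#' @slot kind character, one of the four representation names.
#' @slot values numeric matrix, subjects x columns.
#' @slot blocks named list of integer column-index vectors.
#' @export
setClass("CoupledDesign", representation(
  kind = "character", values = "matrix", blocks = "list"
))

setValidity("CoupledDesign", function(object) {
  kinds <- c("OFM_ROI", "OFM_network", "CFM_ROI", "CFM_network")
  if (!object@kind %in% kinds) {
    return(sprintf("kind must be one of %s", paste(kinds, collapse = ", ")))
  }
  idx <- as.integer(sort(unlist(object@blocks, use.names = FALSE)))
  if (!identical(idx, seq_len(ncol(object@values)))) {
    return("blocks must partition the design columns")
  }
  TRUE
})

#' BoostedEnsemble: block-wise AdaBoost over linear SVM base learners
#'
#' One base learner per design block, fitted sequentially with AdaBoost
#' sample reweighting.  Each learner stores the linear decision function
#' (weight vector and intercept on its block's columns) and its vote weight
#' `alpha` (0 whenever its weighted training error reached 1/2).
#'
#' @slot learners list; each element has `block`, `w`, `b`, `alpha`,
#'   `error`.
#' @slot blocks named list of column indices (the design's block map).
#' @slot positive character, the label treated as the positive (patient)
#'   class.
#' @slot levels character, the two class labels.
#' @slot weightHistory numeric matrix of training sample weights, one row
#'   per boosting step.
#' @export
setClass("BoostedEnsemble", representation(
  learners = "list", blocks = "list", positive = "character",
  levels = "character", weightHistory = "matrix"
))

setValidity("BoostedEnsemble", function(object) {
  for (ln in object@learners) {
    if (ln$alpha < 0) return("vote weights must be nonnegative")
    if (ln$error >= 0.5 && ln$alpha != 0) {
      return("alpha must be 0 when weighted error >= 0.5")
    }
  }
  TRUE
})

#' SyntheticConfig: parameters of the two-group synthetic generator
#'
#' @slot m1,m2 integer group sizes (patients, controls).
#' @slot L integer number of networks.
#' @slot n integer ROI features per network.
#' @slot rho numeric within-network equicorrelation in [0, 1).
#' @slot affected integer indices of networks carrying the group difference.
#' @slot effectSize numeric standardized mean shift (Cohen's d units).
#' @slot rhoShift numeric additive change of the within-network correlation
#'   in the patient group on affected networks (coupling-borne signal).
#' @slot noiseSd numeric marginal feature standard deviation.
#' @slot voxelsPerRoi integer voxels per atlas region (voxel mode).
#' @slot mixingSd numeric subject-loading standard deviation (voxel mode).
#' @slot seed integer root seed.
#' @export
setClass("SyntheticConfig", representation(
  m1 = "integer", m2 = "integer", L = "integer", n = "integer",
  rho = "numeric", affected = "integer", effectSize = "numeric",
  rhoShift = "numeric", noiseSd = "numeric", voxelsPerRoi = "integer",
  mixingSd = "numeric", seed = "integer"
))

setValidity("SyntheticConfig", function(object) {
  msg <- character()
  if (object@m1 < 10L || object@m2 < 10L) msg <- c(msg, "m1, m2: group sizes must be >= 10")
  if (object@L < 2L) msg <- c(msg, "L: need at least 2 networks")
  if (object@n < 2L) msg <- c(msg, "n: need at least 2 ROIs per network")
  if (object@rho < 0 || object@rho >= 1) msg <- c(msg, "rho: must lie in [0, 1)")
  if (length(object@affected) &&
      !all(object@affected %in% seq_len(object@L))) {
    msg <- c(msg, "affected: indices must lie in 1..L")
  }
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd: must be nonnegative")
  if (object@voxelsPerRoi < 1L) msg <- c(msg, "voxelsPerRoi: must be >= 1")
  if (object@rho + max(object@rhoShift, 0) >= 1) {
    msg <- c(msg, "rhoShift: patient-group correlation must stay below 1")
  }
  if (length(msg)) msg else TRUE
})
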