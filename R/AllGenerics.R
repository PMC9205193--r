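#' Accessors for netCFM classes
#'
#' `featureMatrix` returns the subjects x features ROI-level matrix,
#' `networkValues` the subjects x networks matrix, `networkMap` the
#' feature-to-network assignment, `groups` the subject labels, and
#' `designMatrix` / `designBlocks` the assembled design and its block map.
#'
#' @param x an object.
#' @return See the individual descriptions.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' @rdname accessors
#' @export
setGeneric("networkValues", function(x) standardGeneric("networkValues"))

#' @rdname accessors
#' @export
setGeneric("networkMap", function(x) standardGeneric("networkMap"))

#' @rdname accessors
#' @export
setGeneric("groups", function(x) standardGeneric("groups"))

#' @rdname accessors
#' @export
setGeneric("designMatrix", function(x) standardGeneric("designMatrix"))

#' @rdname accessors
#' @export
setGeneric("designBlocks", function(x) standardGeneric("designBlocks"))

#' @rdname accessors
#' @export
setMethod("featureMatrix", "RoiFeatureSet", function(x) {
  t(SummarizedExperiment::assay(x, "gmv"))
})

#' @rdname accessors
#' @export
setMethod("networkValues", "RoiFeatureSet", function(x) x@networkValues)

#' @rdname accessors
#' @export
setMethod("networkMap", "RoiFeatureSet", function(x) {
  as.integer(SummarizedExperiment::rowData(x)$network)
})

#' @rdname accessors
#' @export
setMethod("groups", "RoiFeatureSet", function(x) {
  factor(SummarizedExperiment::colData(x)$group)
})

#' @rdname accessors
#' @export
setMethod("designMatrix", "CoupledDesign", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("designBlocks", "CoupledDesign", function(x) x@blocks)

setMethod("show", "RoiFeatureSet", function(object) {
  L <- length(unique(networkMap(object)))
  cat(sprintf("RoiFeatureSet: %d subjects, %d ROI features in %d networks\n",
              ncol(object), nrow(object), L))
  cat("groups:", paste(sprintf("%s=%d", names(table(groups(object))),
                               as.integer(table(groups(object)))),
                       collapse = ", "), "\n")
})

setMethod("show", "IcaDecomposition", function(object) {
  cat(sprintf("IcaDecomposition: %d subjects, %d components, %d voxels (%s, %d iterations)\n",
              nrow(object@mixing), ncol(object@mixing), ncol(object@sources),
              if (object@converged) "converged" else "not converged",
              object@iterations))
})

setMethod("show", "CouplingWeights", function(object) {
  cat(sprintf("CouplingWeights: n=%d features, E1=%d, alpha=%.3g\n",
              object@n, object@E1, object@alpha))
})

setMethod("show", "IntraCoupling", function(object) {
  cat(sprintf("IntraCoupling: %d subjects x %d columns (E1=%d, %d networks)\n",
              nrow(object@U), ncol(object@U), object@E1, length(object@blocks)))
})

setMethod("show", "CcaPair", function(object) {
  cat(sprintf("CcaPair (%d, %d): correlations %s\n",
              object@pair[1], object@pair[2],
              paste(sprintf("%.3f", object@correlations), collapse = ", ")))
})

setMethod("show", "InterCoupling", function(object) {
  cat(sprintf("InterCoupling: %d subjects x %d networks (E2=%d)\n",
              nrow(object@f), ncol(object@f), object@E2))
})

setMethod("show", "CoupledDesign", function(object) {
  cat(sprintf("CoupledDesign '%s': %d subjects x %d columns, %d block(s)\n",
              object@kind, nrow(object@values), ncol(object@values),
              length(object@blocks)))
})

setMethod("show", "BoostedEnsemble", function(object) {
  a <- vapply(object@learners, `[[`, numeric(1), "alpha")
  cat(sprintf("BoostedEnsemble: %d base learners, vote weights %s\n",
              length(object@learners),
              paste(sprintf("%.3f", a), collapse = ", ")))
})

setMethod("show", "SyntheticConfig", function(object) {
  cat(sprintf(
    "SyntheticConfig: m1=%d m2=%d, L=%d networks x n=%d ROIs, rho=%.2f, d=%.2f on {%s}\n",
    object@m1, object@m2, object@L, object@n, object@rho, object@effectSize,
    paste(object@affected, collapse = ",")))
})
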