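# Network-level inter-coupled representation: pairwise canonical
# correlation analysis between networks' ROI blocks and assembly of the
# four benchmark design matrices.

#' Canonical correlations between two feature blocks
#'
#' Computes the canonical correlations from the singular values of the
#' whitened cross-covariance `S11^{-1/2} S12 S22^{-1/2}`, with a ridge of
#' `1e-8` added to each within-block covariance for stability at small
#' block sizes.  Correlations are clipped to \[0, 1\] and returned in
#' descending order; `retained` holds the top `E2`, zero-padded when fewer
#' exist.
#'
#' @param block1,block2 numeric matrices, subjects x n1 and subjects x n2.
#' @param E2 number of correlations to retain (default: all).
#' @param pair integer length-2 network labels carried in the result.
#' @param ridge diagonal regularisation of the within-block covariances.
#' @return A [CcaPair-class].
#' @export
pairwiseCCA <- function(block1, block2, E2 = NULL, pair = c(1L, 2L),
                        ridge = 1e-8) {
  block1 <- as.matrix(block1); block2 <- as.matrix(block2)
  M <- nrow(block1)
  if (nrow(block2) != M) stop("blocks must have the same number of subjects")
  n1 <- ncol(block1); n2 <- ncol(block2)
  if (M <= max(n1, n2) + 1L) {
    stop("too few subjects (", M, ") for CCA on blocks of width ",
         n1, " and ", n2, "; more samples are needed")
  }
  X <- scale(block1, scale = FALSE); Y <- scale(block2, scale = FALSE)
  S11 <- crossprod(X) / (M - 1)
  S22 <- crossprod(Y) / (M - 1)
  # ridge scaled by the average variance keeps the regularisation, and
  # hence the correlations, invariant under affine transforms of a block
  S11 <- S11 + ridge * max(mean(diag(S11)), 1e-300) * diag(n1)
  S22 <- S22 + ridge * max(mean(diag(S22)), 1e-300) * diag(n2)
  S12 <- crossprod(X, Y) / (M - 1)
  Wm <- invSqrt(S11) %*% S12 %*% invSqrt(S22)
  rho <- svd(Wm)$d
  rho <- pmin(pmax(rho, 0), 1)
  rho <- sort(rho, decreasing = TRUE)[seq_len(min(n1, n2))]
  if (is.null(E2)) E2 <- length(rho)
  retained <- numeric(E2)
  keep <- seq_len(min(E2, length(rho)))
  retained[keep] <- rho[keep]
  methods::new("CcaPair", pair = as.integer(pair), correlations = rho,
               retained = retained)
}

# Symmetric inverse square root.
invSqrt <- function(S) {
  eg <- eigen(S, symmetric = TRUE)
  eg$vectors %*% diag(1 / sqrt(pmax(eg$values, 1e-300)),
                      nrow(S)) %*% t(eg$vectors)
}

#' Build the network-level inter-coupled representation f
#'
#' Fits a CCA on `fitRows` for every unordered network pair (on the scaled
#' ROI blocks) and forms, for each subject i and network l,
#' `f_i(l) = sum over other networks l' and powers e = 1..E2 of
#' (1/e!) * v(i, l')^e * wtilde_e(l, l')`, where `v` are the min-max
#' scaled network-level features and `wtilde` the retained canonical
#' correlations of pair (l, l') (zero-padded beyond the available count,
#' with a warning).
#'
#' @param x a [RoiFeatureSet-class].
#' @param E2 retained canonical correlation count, `>= 1`.
#' @param fitRows subject indices used to fit scaling and CCA.
#' @return An [InterCoupling-class].
#' @export
buildInterRepresentation <- function(x, E2, fitRows = seq_len(ncol(x))) {
  if (E2 < 1) stop("E2 must be >= 1")
  net <- networkMap(x)
  L <- length(unique(net))
  if (L < 2L) stop("need at least 2 networks for inter-coupling")
  scl <- scaleFeatures(x, fitRows)
  n <- min(table(net))
  if (E2 > n) {
    warning(sprintf(
      "E2 = %d exceeds the %d available canonical correlations; zero-padded",
      as.integer(E2), as.integer(n)))
  }
  ccas <- list()
  for (l1 in seq_len(L - 1)) {
    for (l2 in (l1 + 1):L) {
      b1 <- scl$roi[fitRows, net == l1, drop = FALSE]
      b2 <- scl$roi[fitRows, net == l2, drop = FALSE]
      ccas[[sprintf("%d_%d", l1, l2)]] <-
        pairwiseCCA(b1, b2, E2 = E2, pair = c(l1, l2))
    }
  }
  M <- nrow(scl$network)
  omega <- 1 / factorial(seq_len(E2))
  Vpow <- lapply(seq_len(E2), function(e) scl$network^e)  # each M x L
  f <- matrix(0, M, L, dimnames = list(rownames(scl$network),
                                       sprintf("inter_net%d", seq_len(L))))
  for (l in seq_len(L)) {
    for (lp in setdiff(seq_len(L), l)) {
      key <- sprintf("%d_%d", min(l, lp), max(l, lp))
      wt <- ccas[[key]]@retained
      for (e in seq_len(E2)) {
        f[, l] <- f[, l] + omega[e] * Vpow[[e]][, lp] * wt[e]
      }
    }
  }
  methods::new("InterCoupling", f = f, E2 = as.integer(E2), cca = ccas,
               scaling = scl["networkParams"])
}

#' Assemble one of the four benchmark design matrices
#'
#' * `OFM_ROI`: the scaled ROI-level original features (N columns, one
#'   block).
#' * `OFM_network`: the scaled network-level original features (L columns,
#'   one block).
#' * `CFM_ROI`: the intra-coupled representation of all N ROI features
#'   treated as a single whole-brain block (N*E1 columns, one block).
#' * `CFM_network`: the per-network intra-coupled representation
#'   concatenated with the inter-coupled columns (N*E1 + L columns;
#'   one block per network plus one inter block).
#'
#' Scaling, coupling weights and CCA are all fitted on `fitRows` only and
#' applied to every subject.
#'
#' @param x a [RoiFeatureSet-class].
#' @param kind one of `"OFM_ROI"`, `"OFM_network"`, `"CFM_ROI"`,
#'   `"CFM_network"`.
#' @param E1 expansion order (coupled kinds).
#' @param E2 retained canonical correlations (`CFM_network` only).
#' @param fitRows subject indices used for all fitted parameters.
#' @param alpha significance level of the revision rule.
#' @return A [CoupledDesign-class].
#' @export
assembleDesign <- function(x, kind = c("CFM_network", "OFM_ROI",
                                       "OFM_network", "CFM_ROI"),
                           E1 = 3, E2 = 2, fitRows = seq_len(ncol(x)),
                           alpha = 0.05) {
  kind <- match.arg(kind)
  net <- networkMap(x)
  L <- length(unique(net))
  if (kind == "OFM_ROI") {
    scl <- scaleFeatures(x, fitRows)
    return(methods::new("CoupledDesign", kind = kind, values = scl$roi,
                        blocks = list(all = seq_len(ncol(scl$roi)))))
  }
  if (kind == "OFM_network") {
    scl <- scaleFeatures(x, fitRows)
    return(methods::new("CoupledDesign", kind = kind, values = scl$network,
                        blocks = list(all = seq_len(ncol(scl$network)))))
  }
  if (kind == "CFM_ROI") {
    whole <- RoiFeatureSet(featureMatrix(x),
                           network = rep(1L, length(net)),
                           groups = as.character(groups(x)),
                           subjectIds = colnames(x),
                           featureIds = rownames(x))
    intra <- buildIntraRepresentation(whole, E1, fitRows, alpha)
    return(methods::new("CoupledDesign", kind = kind, values = intra@U,
                        blocks = list(all = seq_len(ncol(intra@U)))))
  }
  intra <- buildIntraRepresentation(x, E1, fitRows, alpha)
  inter <- buildInterRepresentation(x, E2, fitRows)
  vals <- cbind(intra@U, inter@f)
  blocks <- c(intra@blocks, list(inter = ncol(intra@U) + seq_len(L)))
  methods::new("CoupledDesign", kind = kind, values = vals, blocks = blocks)
}
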