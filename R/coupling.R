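# Network-level intra-coupled representation: power expansion of ROI
# features within each network, significance-revised Pearson weight
# matrices, and factorial-damped coupled feature vectors.

#' Scale ROI and network features to the unit interval
#'
#' Min-max scaling with parameters fitted on `fitRows` only (see
#' [fitMinMax()]); held-out rows may fall outside \[0, 1\].
#'
#' @param x a [RoiFeatureSet-class].
#' @param fitRows integer subject indices used to fit the parameters.
#' @return A list with `roi` (scaled subjects x N matrix), `network`
#'   (scaled subjects x L matrix) and the two parameter sets (`roiParams`,
#'   `networkParams`).
#' @export
scaleFeatures <- function(x, fitRows = seq_len(ncol(x))) {
  z <- featureMatrix(x)
  v <- networkValues(x)
  rp <- fitMinMax(z, fitRows)
  np <- fitMinMax(v, fitRows)
  list(roi = applyMinMax(z, rp), network = applyMinMax(v, np),
       roiParams = rp, networkParams = np)
}

#' Expand a feature block to integer powers
#'
#' Maps an M x n block to the M x (n*E1) expanded block whose column
#' (k, e) is the e-th elementwise power of feature k, ordered feature-major
#' then power (`k=1: e=1..E1, k=2: ...`).
#'
#' @param block numeric matrix, subjects x n.
#' @param E1 expansion order, `>= 1`.
#' @return The expanded matrix.
#' @examples
#' expandBlock(matrix(c(2, -0.5), 2, 1), E1 = 2)
#' @export
expandBlock <- function(block, E1) {
  block <- as.matrix(block)
  if (E1 < 1) stop("E1 must be >= 1")
  n <- ncol(block)
  out <- matrix(0, nrow(block), n * E1)
  cn <- character(n * E1)
  base <- colnames(block)
  if (is.null(base)) base <- sprintf("x%d", seq_len(n))
  for (k in seq_len(n)) {
    for (e in seq_len(E1)) {
      out[, (k - 1) * E1 + e] <- block[, k]^e
      cn[(k - 1) * E1 + e] <- sprintf("%s_p%d", base[k], e)
    }
  }
  colnames(out) <- cn
  rownames(out) <- rownames(block)
  out
}

# Pearson correlation matrix with entries revised to 0 when the two-sided
# p-value of the t-transform of r (df = M - 2) exceeds alpha.
# Zero-variance columns get all-zero correlations (diagonal handled by the
# caller).
revisedCorrelation <- function(E, alpha) {
  M <- nrow(E)
  if (M < 4L) stop("need at least 4 fitting subjects for revised correlations")
  sds <- apply(E, 2, sd)
  degen <- sds == 0
  if (any(degen)) {
    warning(sprintf("%d zero-variance expanded column(s); correlations set to 0",
                    sum(degen)))
  }
  Es <- E
  Es[, degen] <- 0
  Es[, !degen] <- scale(E[, !degen, drop = FALSE])
  R <- crossprod(Es) / (M - 1)
  R[degen, ] <- 0; R[, degen] <- 0
  R <- pmin(pmax(R, -1), 1)
  r2 <- pmin(R^2, 1 - 1e-15)
  tval <- abs(R) * sqrt((M - 2) / (1 - r2))
  pval <- 2 * pt(tval, df = M - 2, lower.tail = FALSE)
  R[pval > alpha] <- 0
  diag(R) <- ifelse(degen, 0, 1)
  R
}

#' Compute the coupling weight matrices of one expanded block
#'
#' From the expanded block of a network (n features, powers 1..E1), builds
#' for every feature k the intra matrix `R_intra(k)` (correlations between
#' the powers of k) and the inter matrix `R_inter(k)` (correlations between
#' powers of k and powers of every other feature).  Correlations whose
#' two-sided p-value (t-transform, df = M-2) exceeds `alpha` are revised to
#' exactly 0.  Weights are estimated on `fitRows` only.
#'
#' @param expanded matrix from [expandBlock()], subjects x (n*E1).
#' @param n features in the block.
#' @param E1 expansion order.
#' @param alpha significance level of the revision rule (default 0.05).
#' @param fitRows subject indices used for estimation.
#' @return A [CouplingWeights-class].
#' @export
computeCouplingWeights <- function(expanded, n, E1, alpha = 0.05,
                                   fitRows = seq_len(nrow(expanded))) {
  stopifnot(ncol(expanded) == n * E1)
  R <- revisedCorrelation(expanded[fitRows, , drop = FALSE], alpha)
  # ensure intra diagonals are 1 even for degenerate features: a feature is
  # always perfectly self-coupled
  intra <- vector("list", n); inter <- vector("list", n)
  for (k in seq_len(n)) {
    own <- (k - 1) * E1 + seq_len(E1)
    others <- setdiff(seq_len(n * E1), own)
    Ri <- R[own, own, drop = FALSE]
    diag(Ri) <- 1
    intra[[k]] <- Ri
    inter[[k]] <- R[own, others, drop = FALSE]
  }
  methods::new("CouplingWeights", n = as.integer(n), E1 = as.integer(E1),
               alpha = alpha, intra = intra, inter = inter,
               taylor = 1 / factorial(seq_len(E1)))
}

#' Couple one expanded block with its weight matrices
#'
#' For each subject i and feature k the length-E1 coupled vector is
#' `(x_intra * omega) %*% t(R_intra(k)) + (x_inter * rep(omega, n-1)) %*%
#' t(R_inter(k))`, where `x_intra` holds the E1 powers of feature k,
#' `x_inter` the powers of the other features in feature order, and
#' `omega = (1/1!, ..., 1/E1!)`.  Results are concatenated over k.
#'
#' @param expanded matrix from [expandBlock()].
#' @param weights a [CouplingWeights-class] fitted on a compatible block.
#' @return subjects x (n*E1) coupled block.
#' @export
coupleBlock <- function(expanded, weights) {
  n <- weights@n; E1 <- weights@E1
  if (ncol(expanded) != n * E1) {
    stop("expanded block has ", ncol(expanded), " columns; weights expect ",
         n * E1)
  }
  omega <- weights@taylor
  M <- nrow(expanded)
  out <- matrix(0, M, n * E1)
  for (k in seq_len(n)) {
    own <- (k - 1) * E1 + seq_len(E1)
    others <- setdiff(seq_len(n * E1), own)
    Xintra <- sweep(expanded[, own, drop = FALSE], 2, omega, "*")
    uk <- Xintra %*% t(weights@intra[[k]])
    if (n > 1L) {
      Xinter <- sweep(expanded[, others, drop = FALSE], 2,
                      rep(omega, n - 1L), "*")
      uk <- uk + Xinter %*% t(weights@inter[[k]])
    }
    out[, own] <- uk
  }
  dimnames(out) <- dimnames(expanded)
  out
}

#' Build the network-level intra-coupled representation U
#'
#' Scales the ROI features (min-max on `fitRows`), then per network expands
#' the block to powers 1..E1, estimates the revised-correlation weights on
#' `fitRows` and couples all rows.  The result concatenates the per-network
#' coupled blocks in network order; features of different networks never
#' interact.  `E1 = 1` short-circuits to the scaled original features
#' (the representation without coupled interaction analysis).
#'
#' @param x a [RoiFeatureSet-class].
#' @param E1 expansion order (1..6).
#' @param fitRows subject indices used to fit scaling and weights.
#' @param alpha significance level of the revision rule.
#' @param scale logical; `FALSE` skips the pre-expansion min-max scaling.
#' @return An [IntraCoupling-class].
#' @export
buildIntraRepresentation <- function(x, E1, fitRows = seq_len(ncol(x)),
                                     alpha = 0.05, scale = TRUE) {
  if (!E1 %in% 1:6) stop("E1 must be an integer in 1..6")
  E1 <- as.integer(E1)
  net <- networkMap(x)
  L <- length(unique(net))
  z <- featureMatrix(x)
  scl <- if (scale) fitMinMax(z, fitRows) else NULL
  zs <- if (scale) applyMinMax(z, scl) else z
  if (E1 == 1L) {
    blocks <- lapply(seq_len(L), function(l) which(net == l))
    names(blocks) <- sprintf("net%d", seq_len(L))
    colnames(zs) <- sprintf("%s_p1", colnames(zs))
    return(methods::new("IntraCoupling", U = zs, E1 = 1L, blocks = blocks,
                        weights = list(), scaling = list(roi = scl)))
  }
  Ublocks <- vector("list", L); Wlist <- vector("list", L)
  blocks <- vector("list", L)
  ofs <- 0L
  for (l in seq_len(L)) {
    cols <- which(net == l)
    n <- length(cols)
    Ez <- expandBlock(zs[, cols, drop = FALSE], E1)
    W <- computeCouplingWeights(Ez, n, E1, alpha, fitRows)
    Ublocks[[l]] <- coupleBlock(Ez, W)
    Wlist[[l]] <- W
    blocks[[l]] <- ofs + seq_len(n * E1)
    ofs <- ofs + n * E1
  }
  names(blocks) <- sprintf("net%d", seq_len(L))
  U <- do.call(cbind, Ublocks)
  rownames(U) <- rownames(zs)
  methods::new("IntraCoupling", U = U, E1 = as.integer(E1), blocks = blocks,
               weights = Wlist, scaling = list(roi = scl))
}
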