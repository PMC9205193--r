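# Independent reference implementations (naive loops) and small fixture
# builders shared across the suite.

# Naive triple-loop coupling: subject x feature x power, reading the
# coupled-vector formula literally.  Independent of coupleBlock's
# vectorised path.
naiveCoupleBlock <- function(expanded, weights) {
  n <- weights@n; E1 <- weights@E1
  omega <- 1 / factorial(seq_len(E1))
  M <- nrow(expanded)
  out <- matrix(0, M, n * E1)
  for (i in seq_len(M)) {
    for (k in seq_len(n)) {
      Ri <- weights@intra[[k]]
      Re <- weights@inter[[k]]
      others <- setdiff(seq_len(n), k)
      for (p in seq_len(E1)) {
        acc <- 0
        for (q in seq_len(E1)) {
          xq <- expanded[i, (k - 1) * E1 + q]
          acc <- acc + xq * omega[q] * Ri[p, q]
        }
        for (j in seq_along(others)) {
          tau <- others[j]
          for (q in seq_len(E1)) {
            xq <- expanded[i, (tau - 1) * E1 + q]
            acc <- acc + xq * omega[q] * Re[p, (j - 1) * E1 + q]
          }
        }
        out[i, (k - 1) * E1 + p] <- acc
      }
    }
  }
  out
}

# Naive assembly of the inter-coupled vector from scaled network features
# and a list of retained canonical-correlation vectors keyed "l1_l2".
naiveInterAssembly <- function(vScaled, retained, E2) {
  M <- nrow(vScaled); L <- ncol(vScaled)
  f <- matrix(0, M, L)
  for (i in seq_len(M)) {
    for (l in seq_len(L)) {
      for (lp in setdiff(seq_len(L), l)) {
        key <- sprintf("%d_%d", min(l, lp), max(l, lp))
        wt <- retained[[key]]
        for (e in seq_len(E2)) {
          f[i, l] <- f[i, l] +
            (1 / factorial(e)) * vScaled[i, lp]^e * wt[e]
        }
      }
    }
  }
  f
}

# Random RoiFeatureSet with L networks of n features, no planted signal.
randomFeatureSet <- function(M = 20, L = 2, n = 3, seed = 1) {
  set.seed(seed)
  vals <- matrix(rnorm(M * L * n), M, L * n)
  RoiFeatureSet(vals, network = rep(seq_len(L), each = n),
                groups = rep(c("AD", "NC"), length.out = M))
}

# Hand-built CouplingWeights with prescribed intra/inter matrices.
manualWeights <- function(n, E1, intra, inter, alpha = 0.05) {
  methods::new("CouplingWeights", n = as.integer(n), E1 = as.integer(E1),
               alpha = alpha, intra = intra, inter = inter,
               taylor = 1 / factorial(seq_len(E1)))
}
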