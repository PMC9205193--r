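# Internal helpers: seeded RNG isolation, min-max scaling, the
# sample-weighted linear SVM base learner.

# Run `expr` under `seed` without disturbing the caller's RNG stream.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Derive a reproducible sub-seed from a root seed and a stream label,
# kept below 2^31.
subSeed <- function(seed, stream) {
  (as.numeric(seed) * 7919 + stream * 104729) %% 2147483647
}

#' Fit and apply per-feature min-max scaling
#'
#' Scaling parameters (column minimum and range) are estimated on `fitRows`
#' only and applied to all rows, so held-out subjects can fall outside
#' \[0, 1\] (values are deliberately not clipped).  Constant columns map to
#' 0.5 and are flagged with a warning.
#'
#' @param x numeric matrix, subjects x features.
#' @param fitRows integer row indices used to estimate the parameters
#'   (default: all rows).
#' @return `fitMinMax`: a list with `min`, `range` and `constant`;
#'   `applyMinMax`: the scaled matrix.
#' @export
fitMinMax <- function(x, fitRows = seq_len(nrow(x))) {
  stopifnot(length(fitRows) >= 1)
  xf <- x[fitRows, , drop = FALSE]
  mins <- apply(xf, 2, min)
  maxs <- apply(xf, 2, max)
  rng <- maxs - mins
  constant <- rng == 0
  if (any(constant)) {
    warning(sprintf("%d constant feature column(s) mapped to 0.5",
                    sum(constant)))
  }
  list(min = mins, range = rng, constant = constant)
}

#' @rdname fitMinMax
#' @param params a list returned by `fitMinMax`.
#' @export
applyMinMax <- function(x, params) {
  stopifnot(ncol(x) == length(params$min))
  out <- sweep(x, 2, params$min, "-")
  rng <- ifelse(params$constant, 1, params$range)
  out <- sweep(out, 2, rng, "/")
  out[, params$constant] <- 0.5
  dimnames(out) <- dimnames(x)
  out
}

# Sample-weighted L2-regularised squared-hinge linear SVM, solved in the
# primal with BFGS.  Deterministic (zero initialisation).  `y` in {-1, +1},
# `sw` nonnegative sample weights (rescaled to sum to length(y)).
wsvmFit <- function(X, y, sw = NULL, C = 1) {
  M <- nrow(X)
  stopifnot(length(y) == M, all(y %in% c(-1, 1)))
  if (is.null(sw)) sw <- rep(1, M)
  if (length(unique(y)) < 2L) {
    stop("degenerate input: training labels contain a single class")
  }
  sw <- sw / sum(sw) * M
  p <- ncol(X)
  obj <- function(theta) {
    w <- theta[seq_len(p)]; b <- theta[p + 1]
    xi <- pmax(0, 1 - y * (drop(X %*% w) + b))
    0.5 * sum(w^2) + C * sum(sw * xi^2)
  }
  grad <- function(theta) {
    w <- theta[seq_len(p)]; b <- theta[p + 1]
    xi <- pmax(0, 1 - y * (drop(X %*% w) + b))
    coef <- -2 * C * sw * y * xi
    c(w + drop(crossprod(X, coef)), sum(coef))
  }
  fit <- optim(rep(0, p + 1), obj, grad, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-12))
  list(w = fit$par[seq_len(p)], b = fit$par[p + 1])
}

# Decision values (signed margins) of a linear learner.
wsvmDecision <- function(model, X) {
  drop(X %*% model$w) + model$b
}
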