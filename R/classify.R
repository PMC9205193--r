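# Block-wise AdaBoost over sample-weighted linear SVM base learners,
# stratified cross-validated evaluation and the (E1, E2) grid search.

#' Train the block-wise boosted linear-SVM ensemble
#'
#' Runs AdaBoost over the design's blocks in fixed order (networks
#' ascending, inter block last): at step t a sample-weighted linear SVM is
#' fitted on block t's columns, its weighted training error
#' `eps_t` (clipped to \[1e-10, 1 - 1e-10\]) gives the vote weight
#' `alpha_t = 0.5 * log((1 - eps_t) / eps_t)` when `eps_t < 0.5` (else 0),
#' and the sample weights are multiplied by `exp(alpha_t)` on
#' misclassified subjects and renormalised.  A design with a single block
#' yields a single learner; `CFM_network` yields L + 1.
#'
#' @param design a [CoupledDesign-class].
#' @param labels two-level subject labels.
#' @param positive label treated as the positive (patient) class; default
#'   the first level.
#' @param C SVM regularisation constant.
#' @param rounds number of passes over the block sequence.
#' @return A [BoostedEnsemble-class].
#' @export
trainBlockBoostedSvm <- function(design, labels, positive = NULL, C = 1,
                                 rounds = 1) {
  X <- designMatrix(design)
  labels <- factor(labels)
  if (nlevels(labels) != 2L) stop("training labels must contain two classes")
  if (any(table(labels) < 2L)) stop("need at least 2 subjects per class")
  lev <- levels(labels)
  if (is.null(positive)) positive <- lev[1]
  if (!positive %in% lev) stop("positive label not present")
  y <- ifelse(labels == positive, 1, -1)
  M <- nrow(X)
  sw <- rep(1 / M, M)
  blocks <- designBlocks(design)
  order <- rep(seq_along(blocks), rounds)
  learners <- vector("list", length(order))
  hist <- matrix(0, length(order), M)
  for (t in seq_along(order)) {
    bi <- order[t]
    cols <- blocks[[bi]]
    model <- wsvmFit(X[, cols, drop = FALSE], y, sw, C)
    h <- ifelse(wsvmDecision(model, X[, cols, drop = FALSE]) >= 0, 1, -1)
    mis <- h != y
    eps <- sum(sw[mis]) / sum(sw)
    eps <- min(max(eps, 1e-10), 1 - 1e-10)
    alpha <- if (eps < 0.5) 0.5 * log((1 - eps) / eps) else 0
    sw <- sw * exp(alpha * mis)
    sw <- sw / sum(sw)
    hist[t, ] <- sw
    learners[[t]] <- list(block = names(blocks)[bi], cols = cols,
                          w = model$w, b = model$b,
                          alpha = alpha, error = eps)
  }
  methods::new("BoostedEnsemble", learners = learners, blocks = blocks,
               positive = positive, levels = lev, weightHistory = hist)
}

#' Predict with a boosted ensemble
#'
#' Weighted-vote sign rule: the positive class wins when
#' `sum_t alpha_t * h_t(x) >= 0` (exact ties go to the positive class).
#' When every vote weight is zero the prediction is all-positive by the
#' tie rule and a warning is raised.
#'
#' @param object a [BoostedEnsemble-class].
#' @param design a [CoupledDesign-class] with the ensemble's block
#'   structure (or a bare matrix with matching columns).
#' @return factor of predicted labels.
#' @export
setMethod("predict", "BoostedEnsemble", function(object, design) {
  X <- if (methods::is(design, "CoupledDesign")) {
    bl <- designBlocks(design)
    if (!identical(lapply(bl, as.integer),
                   lapply(object@blocks, as.integer))) {
      stop("design block structure does not match the ensemble")
    }
    designMatrix(design)
  } else as.matrix(design)
  ncolNeeded <- max(unlist(lapply(object@learners, `[[`, "cols")))
  if (ncol(X) < ncolNeeded) stop("design has too few columns for the ensemble")
  if (all(vapply(object@learners, `[[`, numeric(1), "alpha") == 0)) {
    warning("all vote weights are zero; predicting the positive class")
  }
  score <- rep(0, nrow(X))
  for (ln in object@learners) {
    h <- ifelse(wsvmDecision(ln[c("w", "b")],
                             X[, ln$cols, drop = FALSE]) >= 0, 1, -1)
    score <- score + ln$alpha * h
  }
  neg <- setdiff(object@levels, object@positive)
  factor(ifelse(score >= 0, object@positive, neg), levels = object@levels)
})

#' Confusion-matrix classification metrics
#'
#' Accuracy `(TP+TN)/(TP+TN+FP+FN)`, sensitivity `TP/(TP+FN)` (true
#' positive rate on the patient class) and specificity `TN/(TN+FP)`.
#'
#' @param yTrue,yPred equal-length label vectors.
#' @param positive the positive (patient) label.
#' @return named numeric vector `accuracy`, `sensitivity`, `specificity`
#'   (proportions in \[0, 1\]).
#' @export
computeMetrics <- function(yTrue, yPred, positive) {
  stopifnot(length(yTrue) == length(yPred))
  yTrue <- as.character(yTrue); yPred <- as.character(yPred)
  if (length(unique(yTrue)) < 2L) {
    stop("yTrue contains a single class; sensitivity/specificity undefined")
  }
  pos <- yTrue == positive
  tp <- sum(pos & yPred == positive)
  fn <- sum(pos & yPred != positive)
  tn <- sum(!pos & yPred != positive)
  fp <- sum(!pos & yPred == positive)
  c(accuracy = (tp + tn) / length(yTrue),
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp))
}

# Stratified fold assignment: within each class, shuffle and deal
# round-robin.  Deterministic given the seed.
stratifiedFolds <- function(labels, nFolds, seed) {
  labels <- factor(labels)
  fold <- integer(length(labels))
  withSeed(seed, {
    for (lv in levels(labels)) {
      idx <- sample(which(labels == lv))
      fold[idx] <- rep(seq_len(nFolds), length.out = length(idx))
    }
  })
  fold
}

#' Cross-validated evaluation of one representation
#'
#' Stratified `nFolds`-fold cross-validation: in each fold the scaling,
#' coupling weights, CCA and the boosted ensemble are fitted on the
#' training rows only (`fitPolicy = "train"`, the default leakage-safe
#' policy) and the held-out rows are scored.  `fitPolicy = "transductive"`
#' fits the representation parameters on all rows (the ensemble is still
#' trained on training rows only).
#'
#' @param x a [RoiFeatureSet-class].
#' @param kind representation kind (see [assembleDesign()]).
#' @param E1,E2 coupling orders.
#' @param nFolds folds (default 10).
#' @param seed integer seed for the fold assignment.
#' @param positive positive-class label (default: first group level).
#' @param C SVM regularisation constant.
#' @param rounds boosting passes.
#' @param alpha revision-rule significance level.
#' @param fitPolicy `"train"` or `"transductive"`.
#' @return A list with `mean` (named metric vector), `folds` (per-fold
#'   metric matrix) and `predictions`.
#' @export
evaluateCV <- function(x, kind = "CFM_network", E1 = 3, E2 = 2, nFolds = 10,
                       seed = 1, positive = NULL, C = 1, rounds = 1,
                       alpha = 0.05, fitPolicy = c("train", "transductive")) {
  fitPolicy <- match.arg(fitPolicy)
  labels <- groups(x)
  if (any(table(labels) < nFolds)) {
    stop("each class needs at least ", nFolds,
         " subjects; use fewer folds")
  }
  if (is.null(positive)) positive <- levels(labels)[1]
  fold <- stratifiedFolds(labels, nFolds, seed)
  M <- length(labels)
  preds <- factor(rep(levels(labels)[1], M), levels = levels(labels))
  mets <- matrix(0, nFolds, 3,
                 dimnames = list(NULL, c("accuracy", "sensitivity",
                                         "specificity")))
  for (fd in seq_len(nFolds)) {
    test <- which(fold == fd)
    train <- which(fold != fd)
    fitRows <- if (fitPolicy == "train") train else seq_len(M)
    design <- assembleDesign(x, kind, E1 = E1, E2 = E2, fitRows = fitRows,
                             alpha = alpha)
    Xall <- designMatrix(design)
    trainDesign <- methods::new("CoupledDesign", kind = design@kind,
                                values = Xall[train, , drop = FALSE],
                                blocks = design@blocks)
    ens <- trainBlockBoostedSvm(trainDesign, labels[train],
                                positive = positive, C = C, rounds = rounds)
    preds[test] <- predict(ens, Xall[test, , drop = FALSE])
    mets[fd, ] <- computeMetrics(labels[test], preds[test], positive)
  }
  list(mean = colMeans(mets), folds = mets, predictions = preds)
}

#' Grid search over representations and coupling orders
#'
#' Evaluates [evaluateCV()] for every requested representation kind and
#' admissible (E1, E2) cell: the original-feature kinds have no
#' hyper-parameters (one cell each), `CFM_ROI` spans `E1Grid`, and
#' `CFM_network` spans `E1Grid x E2Grid`.  The best cell maximises mean
#' accuracy; ties are broken by smaller E1 then smaller E2 (original
#' kinds sort first).
#'
#' @param x a [RoiFeatureSet-class].
#' @param kinds representation kinds to compare.
#' @param E1Grid,E2Grid search grids (defaults `{2,3,4}` and `{1,...,5}`).
#' @param seed fold seed shared by all cells.
#' @param ... passed to [evaluateCV()].
#' @return A data.frame with one row per cell (`kind`, `E1`, `E2`,
#'   `accuracy`, `sensitivity`, `specificity`, `best`); metric columns are
#'   proportions in \[0, 1\].
#' @export
gridSearch <- function(x, kinds = c("OFM_ROI", "OFM_network", "CFM_ROI",
                                    "CFM_network"),
                       E1Grid = 2:4, E2Grid = 1:5, seed = 1, ...) {
  stopifnot(length(E1Grid) >= 1, length(E2Grid) >= 1)
  cells <- list()
  for (kind in kinds) {
    grid <- switch(kind,
      OFM_ROI = , OFM_network = data.frame(E1 = NA_real_, E2 = NA_real_),
      CFM_ROI = data.frame(E1 = E1Grid, E2 = NA_real_),
      CFM_network = expand.grid(E2 = E2Grid, E1 = E1Grid)[, c("E1", "E2")],
      stop("unknown representation kind: ", kind))
    for (i in seq_len(nrow(grid))) {
      e1 <- grid$E1[i]; e2 <- grid$E2[i]
      res <- evaluateCV(x, kind = kind,
                        E1 = if (is.na(e1)) 1 else e1,
                        E2 = if (is.na(e2)) 1 else e2,
                        seed = seed, ...)
      cells[[length(cells) + 1L]] <- data.frame(
        kind = kind, E1 = e1, E2 = e2,
        accuracy = res$mean["accuracy"],
        sensitivity = res$mean["sensitivity"],
        specificity = res$mean["specificity"],
        row.names = NULL)
    }
  }
  out <- do.call(rbind, cells)
  ord <- order(-out$accuracy,
               ifelse(is.na(out$E1), 0, out$E1),
               ifelse(is.na(out$E2), 0, out$E2))
  out$best <- FALSE
  out$best[ord[1]] <- TRUE
  out
}

#' Best cell of a grid-search result
#'
#' @param grid data.frame from [gridSearch()].
#' @return the single best row.
#' @export
bestCell <- function(grid) grid[grid$best, , drop = FALSE]
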