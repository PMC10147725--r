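# glmnet warns about class counts below 8 and enforces grouped = FALSE on
# small folds; both situations are routine at reduced problem sizes and
# the warnings carry no actionable signal, so they are muffled here
.quietGlmnet <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("fewer than 8|grouped=FALSE enforced", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
}

#' LASSO feature selection by repeated cross-validated deviance
#'
#' Fits the logistic LASSO path and chooses the penalty minimizing the
#' mean binomial deviance over `repeats` independent stratified
#' `folds`-fold cross-validations (default 10 repeats of fivefold);
#' features with nonzero coefficients at that penalty are returned. The
#' minimum-CV-deviance rule (rather than the 1-SE rule) is used because it
#' keeps moderately sized feature sets.
#'
#' @param features numeric matrix, subjects x features (typically the
#'   significant AUC features).
#' @param labels factor/character with values "patient"/"control".
#' @param repeats cross-validation repeats (default 10).
#' @param folds folds per repeat (default 5).
#' @param seed integer seed.
#' @return A list: `selected` (feature names), `lambda` (chosen penalty),
#'   `coefficients` (nonzero coefficients at `lambda`).
#' @export
lassoSelect <- function(features, labels, repeats = 10L, folds = 5L,
                        seed = 1L) {
  features <- as.matrix(features)
  if (ncol(features) < 2L) stop("need at least 2 candidate features")
  y <- as.numeric(labels == "patient")
  path <- .quietGlmnet(glmnet::glmnet(features, y, family = "binomial"))
  lambda <- path$lambda
  cvmSum <- numeric(length(lambda))
  for (r in seq_len(repeats)) {
    set.seed(deriveSeed(seed, paste0("lasso:", r)))
    foldid <- .stratifiedFolds(y, folds)
    cv <- .quietGlmnet(
      glmnet::cv.glmnet(features, y, family = "binomial",
                        lambda = lambda, foldid = foldid,
                        type.measure = "deviance"))
    cvmSum <- cvmSum + cv$cvm[match(lambda, cv$lambda)]
  }
  best <- lambda[which.min(cvmSum)]
  beta <- stats::coef(path, s = best)[-1L, 1L]
  sel <- names(beta)[beta != 0]
  if (!length(sel))
    stop("LASSO selected no feature at the minimum-deviance penalty; ",
         "consider a weaker penalty rule or a larger candidate set")
  list(selected = sel, lambda = best, coefficients = beta[beta != 0])
}

#' Min-max scaling fit on the training set, applied to the test set
#'
#' Maps each training column to \[0,1\] and transforms the test set with
#' the training minima and ranges (test values may leave \[0,1\]; they are
#' not clipped). Constant training columns are dropped with a warning.
#'
#' @param train numeric matrix, subjects x features.
#' @param test optional numeric matrix with the same columns.
#' @return A list: `train`, `test` (or NULL), `mins`, `ranges`, `kept`
#'   (retained column indices).
#' @export
#' @examples
#' s <- scaleMinMax(matrix(c(2, 4), 2, 1), matrix(3, 1, 1))
#' s$train; s$test   # {0,1} and 0.5
scaleMinMax <- function(train, test = NULL) {
  train <- as.matrix(train)
  mins <- apply(train, 2L, min)
  ranges <- apply(train, 2L, max) - mins
  kept <- which(ranges > 0)
  if (length(kept) < ncol(train))
    warning(sprintf("dropped %d constant column(s)", ncol(train) - length(kept)))
  if (!length(kept)) stop("all columns are constant")
  sc <- function(m) sweep(sweep(m[, kept, drop = FALSE], 2L, mins[kept]),
                          2L, ranges[kept], "/")
  list(train = sc(train),
       test = if (!is.null(test)) sc(as.matrix(test)),
       mins = mins[kept], ranges = ranges[kept], kept = kept)
}

#' Cohen's kappa from a 2x2 confusion matrix
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` with
#' marginal-product chance agreement. For balanced marginals this equals
#' `2 * accuracy - 1`.
#'
#' @param confusion 2x2 matrix of counts (rows = truth, columns =
#'   prediction, same class order).
#' @return Kappa on the \[-1,1\] scale.
#' @export
kappaFromConfusion <- function(confusion) {
  confusion <- as.matrix(confusion)
  n <- sum(confusion)
  if (n == 0) stop("empty confusion matrix")
  po <- sum(diag(confusion)) / n
  pe <- sum(rowSums(confusion) * colSums(confusion)) / n^2
  if (pe >= 1) stop("degenerate marginals (chance agreement = 1)")
  (po - pe) / (1 - pe)
}

# one stratified k-fold CV of the linear SVM; returns per-fold metrics (%)
# and mean |primal weight| per feature
.svmCvOnce <- function(x, y, cost, folds, foldSeed) {
  set.seed(foldSeed)
  fid <- .stratifiedFolds(y, folds)
  perFold <- matrix(NA_real_, folds, 4L,
                    dimnames = list(NULL, c("accuracy", "sensitivity",
                                            "specificity", "kappa")))
  wSum <- numeric(ncol(x))
  for (k in seq_len(folds)) {
    tr <- fid != k
    if (length(unique(y[tr])) < 2L) stop("degenerate training fold")
    sc <- scaleMinMax(x[tr, , drop = FALSE], x[!tr, , drop = FALSE])
    yf <- factor(y[tr], levels = c("control", "patient"))
    fit <- e1071::svm(sc$train, yf, kernel = "linear", cost = cost,
                      scale = FALSE)
    pred <- stats::predict(fit, sc$test)
    truth <- factor(y[!tr], levels = c("control", "patient"))
    cm <- table(truth, factor(pred, levels = c("control", "patient")))
    perFold[k, "accuracy"] <- 100 * sum(diag(cm)) / sum(cm)
    perFold[k, "sensitivity"] <- if (sum(cm["patient", ]) == 0) NA_real_ else
      100 * cm["patient", "patient"] / sum(cm["patient", ])
    perFold[k, "specificity"] <- if (sum(cm["control", ]) == 0) NA_real_ else
      100 * cm["control", "control"] / sum(cm["control", ])
    perFold[k, "kappa"] <- 100 * tryCatch(kappaFromConfusion(cm),
                                          error = function(e) NA_real_)
    w <- abs(drop(crossprod(fit$coefs, fit$SV)))
    wFull <- numeric(ncol(x))
    wFull[sc$kept] <- w
    wSum <- wSum + wFull
  }
  list(perFold = perFold, wMean = wSum / folds)
}

#' Repeated cross-validated linear SVM
#'
#' Stratified fivefold cross-validation repeated `repeats` times (default
#' 100, i.e. 500 fold evaluations). Per fold: min-max scaling is fit on
#' the training split and applied to the test split, a linear SVM with
#' fixed cost `c` is trained, and accuracy, sensitivity (patient recall),
#' specificity (control recall) and Cohen's kappa are evaluated on the
#' held-out fold. Reported as mean +/- sd over all fold evaluations, on
#' the percent scale, together with the mean absolute primal weight per
#' feature.
#'
#' @param features numeric matrix, subjects x features.
#' @param labels factor/character with values "patient"/"control".
#' @param c SVM cost parameter (default 1).
#' @param folds folds per repeat (default 5).
#' @param repeats CV repeats (default 100).
#' @param seed integer seed.
#' @return A [ClassifierReport-class] (permutation fields unset).
#' @export
svmCrossval <- function(features, labels, c = 1, folds = 5L, repeats = 100L,
                        seed = 1L) {
  x <- as.matrix(features)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  labels <- as.character(labels)
  allFolds <- NULL
  wSum <- numeric(ncol(x))
  for (r in seq_len(repeats)) {
    cv <- .svmCvOnce(x, labels, cost = c, folds = folds,
                     foldSeed = deriveSeed(seed, paste0("svmcv:", r)))
    allFolds <- rbind(allFolds, cv$perFold)
    wSum <- wSum + cv$wMean
  }
  metrics <- data.frame(mean = colMeans(allFolds, na.rm = TRUE),
                        sd = apply(allFolds, 2L, stats::sd, na.rm = TRUE),
                        row.names = colnames(allFolds))
  new("ClassifierReport", metrics = metrics,
      selectedFeatures = colnames(x),
      featureWeights = stats::setNames(wSum / repeats, colnames(x)),
      params = list(c = c, folds = as.integer(folds),
                    repeats = as.integer(repeats), seed = as.integer(seed),
                    nFoldEvaluations = as.integer(folds * repeats)),
      permP = NA_real_, permPSmoothed = NA_real_, nPerm = 0L)
}

#' Label-permutation significance test for the classifier
#'
#' Relabels all subjects uniformly at random `nPerm` times; each permuted
#' run performs one stratified fivefold cross-validation and records its
#' mean accuracy. The one-tailed p is the fraction of permuted runs whose
#' accuracy reaches the true accuracy (`count / nPerm`), reported together
#' with the `(1 + count) / (1 + nPerm)` smoothed companion.
#'
#' @param features numeric matrix, subjects x features.
#' @param labels true labels ("patient"/"control").
#' @param nPerm number of permutations (default 5000; >= 100 advised).
#' @param seed integer seed.
#' @param c SVM cost (default 1).
#' @param folds folds per CV (default 5).
#' @param trueAccuracy reference accuracy in percent; if `NULL`, the mean
#'   accuracy of a [svmCrossval()] run with the same seed is used.
#' @param repeats repeats for the reference accuracy when computed here.
#' @return A list: `permP`, `permPSmoothed`, `count`, `nPerm`,
#'   `trueAccuracy`, `permAccuracies`.
#' @export
permutationTestClassifier <- function(features, labels, nPerm = 5000L,
                                      seed = 1L, c = 1, folds = 5L,
                                      trueAccuracy = NULL, repeats = 100L) {
  x <- as.matrix(features)
  labels <- as.character(labels)
  if (is.null(trueAccuracy)) {
    rep0 <- svmCrossval(x, labels, c = c, folds = folds, repeats = repeats,
                        seed = seed)
    trueAccuracy <- classifierMetrics(rep0)["accuracy", "mean"]
  }
  permAcc <- numeric(nPerm)
  for (b in seq_len(nPerm)) {
    set.seed(deriveSeed(seed, paste0("permlab:", b)))
    yPerm <- sample(labels)
    cv <- .svmCvOnce(x, yPerm, cost = c, folds = folds,
                     foldSeed = deriveSeed(seed, paste0("permcv:", b)))
    permAcc[b] <- mean(cv$perFold[, "accuracy"])
  }
  count <- sum(permAcc >= trueAccuracy)
  list(permP = count / nPerm, permPSmoothed = (1 + count) / (1 + nPerm),
       count = count, nPerm = as.integer(nPerm),
       trueAccuracy = trueAccuracy, permAccuracies = permAcc)
}

# univariate two-sample t screening at alpha; falls back to the single
# best feature so downstream fits are always defined
.screenFeatures <- function(x, y, alpha) {
  p <- apply(x, 2L, function(v) {
    if (stats::sd(v) == 0) return(1)
    stats::t.test(v[y == "patient"], v[y == "control"])$p.value
  })
  sel <- which(p < alpha)
  if (!length(sel)) sel <- which.min(p)
  sel
}

# screening + LASSO on the given rows only; returns column indices
.selectOn <- function(x, y, rows, alpha, seed) {
  sel <- .screenFeatures(x[rows, , drop = FALSE], y[rows], alpha)
  if (length(sel) >= 2L) {
    ls <- tryCatch(
      lassoSelect(x[rows, sel, drop = FALSE], y[rows], repeats = 2L,
                  seed = seed),
      error = function(e) NULL)
    if (!is.null(ls)) sel <- sel[match(ls$selected, colnames(x)[sel])]
  }
  sel
}

#' Selection-leakage audit of the classification chain
#'
#' Runs the screening + LASSO + linear-SVM chain in two orderings on the
#' same data: (a) "leaky" - features are screened and selected on all
#' subjects before cross-validation (the ordering that reuses test
#' subjects during selection); (b) "nested" - screening and selection are
#' redone inside each training fold. With `permuteLabels = TRUE` each
#' repeat freshly permutes the labels, so both orderings run under the
#' null and their gap isolates selection bias.
#'
#' @param features numeric matrix, subjects x features.
#' @param labels labels ("patient"/"control").
#' @param nRepeats audit repeats (default 20).
#' @param seed integer seed.
#' @param alpha screening level (default 0.05).
#' @param c SVM cost.
#' @param folds folds per CV.
#' @param permuteLabels permute labels each repeat (null audit).
#' @return A list: `leakyAccuracy`, `nestedAccuracy` (means, percent),
#'   `perRepeat` data.frame, `headlineVariant` naming which ordering any
#'   headline number would come from.
#' @export
leakageAudit <- function(features, labels, nRepeats = 20L, seed = 1L,
                         alpha = 0.05, c = 1, folds = 5L,
                         permuteLabels = FALSE) {
  x <- as.matrix(features)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  labels <- as.character(labels)
  out <- data.frame(repeatIdx = seq_len(nRepeats), leaky = NA_real_,
                    nested = NA_real_)
  for (r in seq_len(nRepeats)) {
    set.seed(deriveSeed(seed, paste0("audit:", r)))
    y <- if (permuteLabels) sample(labels) else labels
    # (a) leaky: select on everyone, then cross-validate
    selAll <- .selectOn(x, y, seq_along(y), alpha,
                        deriveSeed(seed, paste0("audit-lasso:", r)))
    cvA <- .svmCvOnce(x[, selAll, drop = FALSE], y, cost = c, folds = folds,
                      foldSeed = deriveSeed(seed, paste0("audit-cvA:", r)))
    out$leaky[r] <- mean(cvA$perFold[, "accuracy"])
    # (b) nested: select inside each training fold
    set.seed(deriveSeed(seed, paste0("audit-folds:", r)))
    fid <- .stratifiedFolds(y, folds)
    accB <- numeric(folds)
    for (k in seq_len(folds)) {
      tr <- which(fid != k)
      selK <- .selectOn(x, y, tr, alpha,
                        deriveSeed(seed, paste0("audit-lassoB:", r, ":", k)))
      sc <- scaleMinMax(x[tr, selK, drop = FALSE],
                        x[-tr, selK, drop = FALSE])
      fit <- e1071::svm(sc$train,
                        factor(y[tr], levels = c("control", "patient")),
                        kernel = "linear", cost = c, scale = FALSE)
      pred <- stats::predict(fit, sc$test)
      accB[k] <- 100 * mean(as.character(pred) == y[-tr])
    }
    out$nested[r] <- mean(accB)
  }
  list(leakyAccuracy = mean(out$leaky), nestedAccuracy = mean(out$nested),
       perRepeat = out,
       headlineVariant = "leaky (screening and LASSO before cross-validation)")
}
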