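# Vectorized Freedman-Lane permutation GLM for a group contrast.
# Y: n x m response matrix; groupInd: 0/1 indicator; Z: reduced design
# (intercept + covariates). Residuals of the reduced model are permuted,
# the full model refit, and the group t-statistic recomputed, columnwise.
.freedmanLane <- function(Y, groupInd, Z, nPerm, seed,
                          tail = c("two", "greater", "less")) {
  tail <- match.arg(tail)
  Y <- as.matrix(Y)
  n <- nrow(Y)
  qz <- qr(Z)
  if (qz$rank < ncol(Z)) stop("rank-deficient covariate design")
  QZ <- qr.Q(qz)
  gPerp <- groupInd - QZ %*% crossprod(QZ, groupInd)
  gg <- sum(gPerp^2)
  if (gg < 1e-10 * sum(groupInd^2))
    stop("group indicator is collinear with the covariates")
  dfres <- n - ncol(Z) - 1L
  if (dfres < 1L) stop("not enough subjects for the design")
  sdY <- apply(Y, 2L, stats::sd)
  if (any(sdY == 0))
    stop("constant feature(s): ",
         paste(colnames(Y)[sdY == 0], collapse = ", "))

  E <- Y - QZ %*% crossprod(QZ, Y)        # reduced-model residuals
  tStat <- function(Eb) {
    beta <- drop(crossprod(gPerp, Eb)) / gg
    rss <- colSums((Eb - QZ %*% crossprod(QZ, Eb))^2) - beta^2 * gg
    rss <- pmax(rss, 1e-300)
    list(beta = beta, t = beta * sqrt(gg * dfres / rss))
  }
  obs <- tStat(E)
  set.seed(seed)
  exceed <- numeric(ncol(Y))
  cmp <- switch(tail,
    two = function(tp, to) abs(tp) >= abs(to),
    greater = function(tp, to) tp >= to,
    less = function(tp, to) tp <= to)
  for (b in seq_len(nPerm)) {
    tp <- tStat(E[sample.int(n), , drop = FALSE])$t
    exceed <- exceed + cmp(tp, obs$t)
  }
  list(coef = obs$beta, t = obs$t,
       p = (1 + exceed) / (1 + nPerm), nPerm = as.integer(nPerm))
}

#' Permutation-based GLM test of a group effect with covariate adjustment
#'
#' Freedman-Lane scheme: the reduced model (intercept + covariates) is fit,
#' its residuals are permuted, the full model (adding the group indicator)
#' is refit, and the two-sided permutation p-value is
#' `(1 + #{|t_perm| >= |t_obs|}) / (1 + nPerm)`.
#'
#' @param feature numeric response vector (one topological attribute).
#' @param group factor/character with levels "patient" and "control".
#' @param covariates optional numeric matrix/data.frame of covariates.
#' @param nPerm number of permutations.
#' @param seed integer seed.
#' @return A list: `coef` (patient-minus-control adjusted effect), `t`,
#'   `p` (two-sided), `direction` ("patient>control" or
#'   "control>patient"), `nPerm`.
#' @export
permutationGlm <- function(feature, group, covariates = NULL,
                           nPerm = 10000L, seed = 1L) {
  n <- length(feature)
  if (n < 6L) stop("need at least 6 subjects")
  groupInd <- as.numeric(group == "patient")
  if (length(unique(groupInd)) < 2L) stop("both groups must be present")
  Z <- cbind(intercept = rep(1, n),
             if (!is.null(covariates)) as.matrix(covariates))
  r <- .freedmanLane(matrix(feature, ncol = 1L,
                            dimnames = list(NULL, "feature")),
                     groupInd, Z, nPerm, seed, tail = "two")
  list(coef = unname(r$coef), t = unname(r$t), p = unname(r$p),
       direction = if (r$coef > 0) "patient>control" else "control>patient",
       nPerm = r$nPerm)
}

#' Cohen's d (pooled standard deviation)
#'
#' `d = (mean(x) - mean(y)) / s_pooled` with the n-1 pooled variance.
#'
#' @param x,y numeric samples (each of length >= 2).
#' @return The standardized mean difference.
#' @export
#' @examples
#' cohensD(c(1, 2, 3), c(2, 3, 4))  # -1
cohensD <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx < 2L || ny < 2L) stop("both samples need >= 2 observations")
  sp <- sqrt(((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) /
               (nx + ny - 2))
  if (sp == 0) stop("zero pooled standard deviation")
  (mean(x) - mean(y)) / sp
}

#' Label an effect size by the conventional 0.2 / 0.5 / 0.8 bands
#'
#' @param d Cohen's d (sign ignored).
#' @return "negligible", "small", "medium" or "large".
#' @export
effectSizeLabel <- function(d) {
  a <- abs(d)
  if (a >= 0.8) "large" else if (a >= 0.5) "medium"
  else if (a >= 0.2) "small" else "negligible"
}

#' Pearson partial correlation with covariate adjustment
#'
#' Residualizes `x` and `y` on the covariates (plus intercept) and
#' correlates the residuals; the p-value is t-based with `n - k - 2`
#' degrees of freedom (k covariates). With no covariates this reduces to
#' the plain Pearson correlation test.
#'
#' @param x,y numeric vectors.
#' @param covariates optional numeric matrix/data.frame.
#' @return A list: `r`, `p`, `df`, `nCovariates`.
#' @export
partialCorrelation <- function(x, y, covariates = NULL) {
  n <- length(x)
  k <- if (is.null(covariates)) 0L else ncol(as.matrix(covariates))
  if (n <= k + 2L) stop("need n > k + 2 observations")
  Z <- cbind(rep(1, n), if (k) as.matrix(covariates))
  QZ <- qr.Q(qr(Z))
  rx <- x - QZ %*% crossprod(QZ, x)
  ry <- y - QZ %*% crossprod(QZ, y)
  if (stats::sd(rx) <= 1e-10 * max(stats::sd(x), 1e-300) ||
      stats::sd(ry) <= 1e-10 * max(stats::sd(y), 1e-300))
    stop("degenerate residuals (a variable lies in the covariate span)")
  r <- drop(stats::cor(rx, ry))
  df <- n - k - 2L
  tval <- r * sqrt(df / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tval), df), df = df, nCovariates = k)
}

#' Compare every AUC feature between groups
#'
#' Applies the Freedman-Lane permutation GLM to each feature of the table
#' (by default 10,000 permutations for the four global attributes, 5,000
#' for nodal ones), reports the adjusted group effect, two-sided
#' permutation p, contrast direction and unadjusted Cohen's d
#' (control minus patient, so positive d means control > patient), and
#' flags features with `p < alpha`. No multiplicity correction is applied;
#' the flagged set feeds feature selection.
#'
#' @param ft feature table from [buildFeatureTable()].
#' @param nPermGlobal permutations for global features (default 10000).
#' @param nPermNodal permutations for nodal features (default 5000).
#' @param seed integer seed.
#' @param alpha significance level for flagging (default 0.05).
#' @param covariates record columns to adjust for (default age, education,
#'   ftnd).
#' @return data.frame, one row per feature, with attribute
#'   `"significant"` holding the flagged feature names.
#' @export
compareFeatures <- function(ft, nPermGlobal = 10000L, nPermNodal = 5000L,
                            seed = 1L, alpha = 0.05,
                            covariates = c("age", "education", "ftnd")) {
  Y <- t(SummarizedExperiment::assay(ft, "auc"))
  cd <- SummarizedExperiment::colData(ft)
  groupInd <- as.numeric(cd$group == "patient")
  Z <- cbind(intercept = rep(1, nrow(Y)),
             as.matrix(as.data.frame(cd[, covariates, drop = FALSE])))
  scope <- SummarizedExperiment::rowData(ft)$scope
  res <- vector("list", 2L)
  blocks <- list(global = which(scope == "global"),
                 nodal = which(scope == "nodal"))
  nPerms <- c(global = nPermGlobal, nodal = nPermNodal)
  out <- NULL
  for (blk in names(blocks)) {
    idx <- blocks[[blk]]
    if (!length(idx)) next
    r <- .freedmanLane(Y[, idx, drop = FALSE], groupInd, Z,
                       nPerms[[blk]], deriveSeed(seed, paste0("glm:", blk)),
                       tail = "two")
    d <- apply(Y[, idx, drop = FALSE], 2L, function(v)
      cohensD(v[groupInd == 0], v[groupInd == 1]))
    out <- rbind(out, data.frame(
      feature = colnames(Y)[idx],
      attribute = SummarizedExperiment::rowData(ft)$attribute[idx],
      node = SummarizedExperiment::rowData(ft)$node[idx],
      coef = r$coef, t = r$t, p = r$p,
      direction = ifelse(r$coef > 0, "patient>control", "control>patient"),
      cohen_d = d,
      effect_size = vapply(d, effectSizeLabel, character(1)),
      n_perm = nPerms[[blk]], row.names = NULL))
  }
  out <- out[match(rownames(ft), out$feature), ]
  rownames(out) <- NULL
  out$significant <- out$p < alpha
  attr(out, "significant") <- out$feature[out$significant]
  out
}

#' Partial correlations of significant features with clinical scores
#'
#' Computed among patients only, adjusting for age, education and FTND
#' (cigarette smoking) by default.
#'
#' @param ft feature table from [buildFeatureTable()].
#' @param features feature names to correlate (e.g. the significant set
#'   from [compareFeatures()]).
#' @param clinicalVars clinical record columns (default BPRS total, the
#'   five factors and HAMA).
#' @param covariates record columns to adjust for.
#' @return data.frame: feature, clinical, r, p, df.
#' @export
clinicalCorrelations <- function(ft, features,
                                 clinicalVars = .recordColumns()$clinical,
                                 covariates = c("age", "education", "ftnd")) {
  cd <- as.data.frame(SummarizedExperiment::colData(ft))
  pat <- cd$group == "patient"
  Y <- t(SummarizedExperiment::assay(ft, "auc"))[pat, , drop = FALSE]
  covM <- as.matrix(cd[pat, covariates, drop = FALSE])
  out <- NULL
  for (f in features) for (cl in intersect(clinicalVars, names(cd))) {
    y <- cd[[cl]][pat]
    if (anyNA(y)) next
    # features or scores that are constant among patients (e.g. an
    # integer-valued hubness AUC) carry no correlation information
    pc <- tryCatch(partialCorrelation(Y[, f], y, covM),
                   error = function(e) NULL)
    if (is.null(pc)) next
    out <- rbind(out, data.frame(feature = f, clinical = cl, r = pc$r,
                                 p = pc$p, df = pc$df, row.names = NULL))
  }
  out
}
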