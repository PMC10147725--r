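test_that("min-max scaling maps train to [0,1] and projects test unclipped", {
  tr <- matrix(c(2, 4, 3, 6), ncol = 2)
  te <- matrix(c(3, 5, 4.5, 9), ncol = 2)
  sc <- scaleMinMax(tr, te)
  expect_equal(sc$train, matrix(c(0, 1, 0, 1), ncol = 2),
               ignore_attr = TRUE)
  expect_equal(sc$test[1, 1], 0.5)
  expect_equal(sc$test[2, 1], 1.5)             # outside [0,1] by design

  # constant columns are dropped with a warning
  trC <- cbind(tr, 7)
  expect_warning(scC <- scaleMinMax(trC), "constant")
  expect_equal(ncol(scC$train), 2)
  expect_equal(scC$kept, c(1L, 2L))

  # idempotence: rescaling an already scaled block is the identity
  sc2 <- scaleMinMax(sc$train)
  expect_equal(sc2$train, sc$train, ignore_attr = TRUE)
})

test_that("Cohen's kappa matches its closed forms", {
  expect_equal(kappaFromConfusion(matrix(c(10, 0, 0, 10), 2)), 1)
  # balanced margins with accuracy a: kappa = 2a - 1
  a <- 0.8
  conf <- matrix(c(40 * a, 40 * (1 - a), 40 * (1 - a), 40 * a), 2)
  expect_equal(kappaFromConfusion(conf), 2 * a - 1, tolerance = 1e-12)
  # chance-level performance: kappa ~ 0
  expect_equal(kappaFromConfusion(matrix(c(25, 25, 25, 25), 2)), 0)
  expect_error(kappaFromConfusion(matrix(0, 2, 2)), "empty")
  expect_error(kappaFromConfusion(matrix(c(5, 0, 0, 0), 2)), "chance")
})

test_that("LASSO selection recovers informative features and rejects noise", {
  set.seed(111)
  n <- 60
  y <- rep(c("control", "patient"), each = n / 2)
  x <- matrix(rnorm(n * 8), n, 8,
              dimnames = list(NULL, paste0("f", 1:8)))
  x[, 2] <- x[, 2] + 2 * (y == "patient")      # informative
  x[, 5] <- x[, 5] - 1.5 * (y == "patient")    # informative
  sel <- lassoSelect(x, y, repeats = 3, seed = 4)
  expect_true(all(c("f2", "f5") %in% sel$selected))
  expect_lte(length(sel$selected), 6)          # mostly noise excluded
  expect_gt(sel$coefficients[["f2"]], 0)       # patient-elevated
  expect_lt(sel$coefficients[["f5"]], 0)

  # deterministic
  sel2 <- lassoSelect(x, y, repeats = 3, seed = 4)
  expect_identical(sel$selected, sel2$selected)
  expect_equal(sel$lambda, sel2$lambda)
  expect_error(lassoSelect(x[, 1, drop = FALSE], y), "2 candidate")
})

test_that("SVM cross-validation separates separable data and not shuffled data", {
  set.seed(112)
  n <- 40
  y <- rep(c("control", "patient"), each = n / 2)
  x <- matrix(rnorm(n * 3), n, 3)
  x[, 1] <- x[, 1] + 4 * (y == "patient")
  rep1 <- svmCrossval(x, y, repeats = 10, seed = 9)
  expect_s4_class(rep1, "ClassifierReport")
  m <- classifierMetrics(rep1)
  expect_gt(m["accuracy", "mean"], 95)         # percent scale
  expect_gt(m["kappa", "mean"], 90)            # kappa reported in percent
  # balanced folds: accuracy = (sensitivity + specificity) / 2
  expect_equal(m["accuracy", "mean"],
               (m["sensitivity", "mean"] + m["specificity", "mean"]) / 2,
               tolerance = 1e-8)
  expect_equal(rep1@params$nFoldEvaluations, 50)
  # the separating feature dominates the weight vector
  expect_equal(unname(which.max(featureWeights(rep1))), 1L)

  yShuf <- sample(y)
  rep0 <- svmCrossval(x, yShuf, repeats = 10, seed = 9)
  expect_lt(abs(classifierMetrics(rep0)["accuracy", "mean"] - 50), 15)

  # deterministic under the seed
  rep2 <- svmCrossval(x, y, repeats = 10, seed = 9)
  expect_identical(classifierMetrics(rep1), classifierMetrics(rep2))
})

test_that("the label-permutation test calibrates and hits its floor", {
  set.seed(113)
  n <- 30
  y <- rep(c("control", "patient"), each = n / 2)
  x <- matrix(rnorm(n * 2), n, 2)
  x[, 1] <- x[, 1] + 5 * (y == "patient")
  pt <- permutationTestClassifier(x, y, nPerm = 39, seed = 2, repeats = 3)
  expect_equal(pt$permP, 0)                     # raw count can reach zero
  expect_equal(pt$permPSmoothed, 1 / 40)
  expect_gt(pt$trueAccuracy, 90)

  # under shuffled labels the p-value is not extreme
  pt0 <- permutationTestClassifier(x, sample(y), nPerm = 39, seed = 2,
                                   repeats = 3)
  expect_gt(pt0$permPSmoothed, 0.05)

  pt2 <- permutationTestClassifier(x, y, nPerm = 39, seed = 2, repeats = 3)
  expect_identical(pt$permPSmoothed, pt2$permPSmoothed)
})

test_that("the leakage audit shows leaky selection inflating null accuracy", {
  set.seed(114)
  n <- 40
  y <- rep(c("control", "patient"), each = n / 2)
  x <- matrix(rnorm(n * 60), n, 60)            # pure noise, many features
  aud <- leakageAudit(x, y, nRepeats = 6, seed = 3, permuteLabels = TRUE)
  expect_gt(aud$leakyAccuracy, aud$nestedAccuracy)
  expect_gt(aud$leakyAccuracy, 55)             # optimistic on noise
  expect_lt(abs(aud$nestedAccuracy - 50), 12)  # honest near chance
  expect_equal(nrow(aud$perRepeat), 6)
})
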