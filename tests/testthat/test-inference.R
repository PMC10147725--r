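test_that("permutation GLM hits its floor under huge separation and respects it", {
  set.seed(81)
  y <- c(rnorm(10, 0, 0.01), rnorm(10, 5, 0.01))
  grp <- rep(c("control", "patient"), each = 10)
  r <- permutationGlm(y, grp, nPerm = 999, seed = 3)
  expect_equal(r$p, 1 / 1000)                  # (1 + 0) / (1 + 999)
  expect_equal(r$direction, "patient>control")
  expect_gte(r$p, 1 / (r$nPerm + 1))

  expect_error(permutationGlm(rep(1, 20), grp, nPerm = 99), "constant")
  expect_error(permutationGlm(y[1:4], grp[1:4], nPerm = 99), "6 subjects")
})

test_that("permutation GLM p-values are uniform under the null", {
  set.seed(82)
  ps <- replicate(120, {
    y <- rnorm(24)
    grp <- rep(c("control", "patient"), each = 12)
    covs <- cbind(age = rnorm(24), edu = rnorm(24))
    permutationGlm(y, grp, covs, nPerm = 99, seed = sample.int(1e6, 1))$p
  })
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("covariate-driven group differences are absorbed by adjustment", {
  set.seed(83)
  hits <- 0
  for (i in 1:30) {
    grp <- rep(c("control", "patient"), each = 15)
    age <- rnorm(30) + 1.5 * (grp == "patient")   # confounded covariate
    y <- 2 * age + rnorm(30)                       # effect only through age
    r <- permutationGlm(y, grp, cbind(age = age), nPerm = 199,
                        seed = 9000 + i)
    hits <- hits + (r$p < 0.05)
  }
  expect_lte(hits, 3)                              # <= 10% of 30 runs
})

test_that("Cohen's d and its labels match hand computation", {
  expect_equal(cohensD(c(1, 2, 3), c(2, 3, 4)), -1)
  expect_equal(cohensD(c(5, 6), c(5, 6)), 0)
  expect_error(cohensD(c(1, 1), c(1, 1)), "pooled")
  expect_error(cohensD(1, c(1, 2)), "2 observations")
  expect_identical(effectSizeLabel(0.51), "medium")
  expect_identical(effectSizeLabel(-0.85), "large")
  expect_identical(effectSizeLabel(0.3), "small")
  expect_identical(effectSizeLabel(0.1), "negligible")
})

test_that("partial correlation reduces to Pearson, annihilates covariates, recovers rho", {
  set.seed(84)
  x <- rnorm(50); y <- 0.5 * x + rnorm(50)
  pc <- partialCorrelation(x, y)
  ct <- cor.test(x, y)
  expect_equal(pc$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(pc$p, ct$p.value, tolerance = 1e-10)

  # a variable inside the covariate span has no residual signal left
  z <- rnorm(50)
  expect_error(partialCorrelation(x, z, covariates = cbind(z)),
               "degenerate")
  # adjusting for the shared driver annihilates an induced correlation
  cvA <- rnorm(50)
  xA <- cvA + 0.05 * rnorm(50)
  yA <- cvA + 0.05 * rnorm(50)
  expect_gt(abs(stats::cor(xA, yA)), 0.9)
  pc2 <- partialCorrelation(xA, yA, covariates = cbind(cvA))
  expect_lt(abs(pc2$r), 0.35)

  # bivariate normal with partial rho = 0.5 given a shared covariate
  n <- 500
  cv <- rnorm(n)
  e1 <- rnorm(n); e2 <- 0.5 * e1 + sqrt(1 - 0.25) * rnorm(n)
  xx <- cv + e1; yy <- cv + e2
  pc3 <- partialCorrelation(xx, yy, covariates = cbind(cv))
  expect_lt(abs(pc3$r - 0.5), 0.1)
})

test_that("compareFeatures flags injected contrasts with the right direction", {
  cfg <- simulationConfig(nPerGroup = 10, nNodes = 24, nModules = 3,
                          effectModularity = 0.4, seed = 91)
  coh <- generateCohort(cfg)
  ft <- buildFeatureTable(coh, thresholdGrid(), seed = 6, nNull = 20,
                          restarts = 3)
  cmp <- compareFeatures(ft, nPermGlobal = 499, nPermNodal = 199, seed = 7)
  qRow <- cmp[cmp$feature == "q", ]
  expect_lt(qRow$p, 0.05)
  expect_identical(qRow$direction, "control>patient")
  expect_gt(qRow$cohen_d, 0)
  expect_true(all(cmp$p >= 1 / (cmp$n_perm + 1)))
  # deterministic given the seed
  cmp2 <- compareFeatures(ft, nPermGlobal = 499, nPermNodal = 199, seed = 7)
  expect_identical(cmp, cmp2)
})

test_that("clinical correlations recover a planted metric-score coupling", {
  cfg <- simulationConfig(nPerGroup = 25, nNodes = 24, nModules = 3,
                          clinicalCoupling = list(coef = -300, noiseSd = 1,
                                                  target = "bprs_total"),
                          seed = 92)
  coh <- generateCohort(cfg)
  ft <- buildFeatureTable(coh, thresholdGrid(), seed = 3, nNull = 20,
                          restarts = 3)
  cc <- clinicalCorrelations(ft, features = "q",
                             clinicalVars = "bprs_total")
  expect_lt(cc$r, 0)                             # negative coupling recovered
  expect_lt(cc$p, 0.05)
})
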