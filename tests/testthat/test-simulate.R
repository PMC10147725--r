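test_that("generated matrices satisfy every connectivity invariant and are reproducible", {
  cfg <- simulationConfig(nPerGroup = 4, nNodes = 24, nModules = 3, seed = 21)
  coh <- generateCohort(cfg)
  expect_equal(nrow(subjectRecords(coh)), 8)
  for (cm in connMatrices(coh)) {
    w <- weightsMatrix(cm)
    expect_true(all(w >= 0) && all(w <= 1))
    expect_equal(w, t(w))
    expect_equal(diag(w), rep(0, 24), ignore_attr = TRUE)
  }
  # same seed -> bit-identical cohort
  coh2 <- generateCohort(cfg)
  expect_identical(lapply(connMatrices(coh), weightsMatrix),
                   lapply(connMatrices(coh2), weightsMatrix))
  expect_identical(subjectRecords(coh), subjectRecords(coh2))
  # controls carry no clinical scores, patients do
  recs <- subjectRecords(coh)
  expect_true(all(is.na(recs$bprs_total[recs$group == "control"])))
  expect_true(all(is.finite(recs$bprs_total[recs$group == "patient"])))
})

test_that("with zero effects the two groups share one generating law", {
  # patient and control mean modularity agree within sampling error
  cfg <- simulationConfig(nPerGroup = 12, nNodes = 24, nModules = 3, seed = 5)
  coh <- generateCohort(cfg)
  recs <- subjectRecords(coh)
  qOf <- function(sid) {
    g <- thresholdGraph(connMatrices(coh)[[sid]], 0.005)
    modularityLouvain(g, seed = 1, restarts = 5)$q
  }
  qs <- vapply(recs$subject_id, qOf, numeric(1))
  qP <- qs[recs$group == "patient"]
  qC <- qs[recs$group == "control"]
  expect_gt(t.test(qP, qC)$p.value, 0.01)
})

test_that("modularity effect lowers patient Q, monotonically in the effect", {
  gaps <- vapply(c(0, 0.25, 0.5), function(f) {
    cfg <- simulationConfig(nPerGroup = 6, nNodes = 24, nModules = 3,
                            effectModularity = f, seed = 31)
    coh <- generateCohort(cfg)
    recs <- subjectRecords(coh)
    qs <- vapply(recs$subject_id, function(sid) {
      g <- thresholdGraph(connMatrices(coh)[[sid]], 0.005)
      modularityLouvain(g, seed = 1, restarts = 5)$q
    }, numeric(1))
    mean(qs[recs$group == "control"]) - mean(qs[recs$group == "patient"])
  }, numeric(1))
  expect_gt(gaps[2], gaps[1])
  expect_gt(gaps[3], gaps[2])
  expect_gt(gaps[3], 0.05)
})

test_that("edge-component injection shifts exactly the named edges of one group", {
  coh <- testCohort(nPerGroup = 3, nNodes = 12, nModules = 2, seed = 7)
  tri <- cbind(c(1, 1, 2), c(2, 3, 3))

  same <- injectEdgeComponent(coh, tri, delta = 0)
  expect_identical(lapply(connMatrices(same), weightsMatrix),
                   lapply(connMatrices(coh), weightsMatrix))

  shifted <- injectEdgeComponent(coh, tri, delta = 0.4, group = "patient")
  recs <- subjectRecords(coh)
  pid <- recs$subject_id[recs$group == "patient"][1]
  cid <- recs$subject_id[recs$group == "control"][1]
  w0 <- weightsMatrix(connMatrices(coh)[[pid]])
  w1 <- weightsMatrix(connMatrices(shifted)[[pid]])
  expect_equal(w1[1, 2], min(1, w0[1, 2] + 0.4))
  delta <- abs(w1 - w0) > 0
  expect_equal(sum(delta[upper.tri(delta)]), 3)  # a triangle is 3 links
  expect_identical(weightsMatrix(connMatrices(shifted)[[cid]]),
                   weightsMatrix(connMatrices(coh)[[cid]]))

  expect_error(injectEdgeComponent(coh, tri[0, ], delta = 0.1), "empty")
})

test_that("config validation rejects impossible probabilities and sparse regimes warn", {
  expect_error(simulationConfig(pWithin = 1.2), "probabilities")
  expect_error(simulationConfig(effectModularity = 1), "effectModularity")
  cfgSparse <- simulationConfig(nPerGroup = 3, nNodes = 60, nModules = 6,
                                pWithin = 0.05, pBetween = 0.01, seed = 1)
  expect_warning(generateCohort(cfgSparse), "disconnected")
})
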