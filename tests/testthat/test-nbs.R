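test_that("edge-wise stats respect the presence mask and flip with the tail", {
  coh <- testCohort(nPerGroup = 6, nNodes = 12, nModules = 2, seed = 101)
  es <- edgewiseStats(coh, covariates = NULL)
  expect_true(all(es$p >= 0 & es$p <= 1))
  expect_equal(es$df, 12 - 2)                  # intercept + group

  esRev <- edgewiseStats(coh, covariates = NULL, tail = "control>patient")
  expect_equal(esRev$t, -es$t, tolerance = 1e-12)
  expect_equal(es$p + esRev$p, rep(1, length(es$p)), tolerance = 1e-10)

  # the presence mask drops an edge absent in half of one group
  recs <- subjectRecords(coh)
  mats <- connMatrices(coh)
  pats <- recs$subject_id[recs$group == "patient"]
  pair <- es$edges[1, ]
  for (sid in pats[1:4]) {                     # 4/6 patients lose the edge
    w <- weightsMatrix(mats[[sid]])
    w[pair$from, pair$to] <- w[pair$to, pair$from] <- 0
    mats[[sid]] <- connectivityMatrix(w, nodeIds(coh), subjectId = sid)
  }
  es2 <- edgewiseStats(cohort(recs, mats, atlasTable(coh)), covariates = NULL)
  expect_equal(nrow(es2$edges), nrow(es$edges) - 1)
  expect_false(any(es2$edges$from == pair$from & es2$edges$to == pair$to))
})

test_that("suprathreshold component sizes match a union-find oracle", {
  set.seed(102)
  for (i in 1:25) {
    n <- sample(6:12, 1)
    labs <- paste0("n", seq_len(n))
    full <- which(upper.tri(matrix(0, n, n)))
    pick <- sort(sample(full, sample(4:length(full), 1)))
    ij <- arrayInd(pick, c(n, n))
    edges <- data.frame(from = labs[ij[, 1]], to = labs[ij[, 2]])
    p <- runif(nrow(edges))
    sc <- suprathresholdComponents(edges, p, alphaPrimary = 0.4)
    sel <- p < 0.4
    if (!any(sel)) {
      expect_length(sc$sizes, 0)
    } else {
      expect_equal(sc$sizes,
                   unionFindComponentSizes(as.matrix(edges[sel, ])))
      expect_equal(sort(unlist(sc$components)), which(sel))
    }
  }
})

test_that("an injected clique surfaces as a significant component", {
  # dense within-module regime so every injected edge passes the
  # presence mask in both groups
  coh <- generateCohort(simulationConfig(nPerGroup = 10, nNodes = 16,
                                         nModules = 2, pWithin = 0.9,
                                         pBetween = 0.3, seed = 103))
  clique <- t(combn(c(2, 3, 5, 7), 2))         # 6 edges within one module
  boosted <- injectEdgeComponent(coh, clique, delta = 0.6, group = "patient")
  res <- nbsTest(boosted, nPerm = 199, seed = 5, covariates = NULL)
  expect_s4_class(res, "NBSResult")
  expect_gte(length(nbsComponents(res)), 1)
  top <- nbsComponents(res)[[1]]
  lab <- nodeIds(coh)
  key <- paste(pmin(top$from, top$to), pmax(top$from, top$to))
  want <- paste(pmin(lab[clique[, 1]], lab[clique[, 2]]),
                pmax(lab[clique[, 1]], lab[clique[, 2]]))
  expect_true(all(want %in% key))
  expect_gte(res@sizes[1], 6)
  expect_lt(fweP(res)[1], 0.05)
  expect_gte(fweP(res)[1], 1 / 200)            # permutation floor

  # deterministic under the same seed
  res2 <- nbsTest(boosted, nPerm = 199, seed = 5, covariates = NULL)
  expect_identical(fweP(res), fweP(res2))
  expect_identical(res@nullMaxSizes, res2@nullMaxSizes)

  # the reverse tail should not find the patient-elevated clique
  rev <- nbsTest(boosted, nPerm = 99, seed = 5, covariates = NULL,
                 tail = "control>patient")
  revKeys <- unlist(lapply(nbsComponents(rev), function(d)
    paste(pmin(d$from, d$to), pmax(d$from, d$to))))
  expect_false(any(want %in% revKeys))
})

test_that("nbsTest validates its cohort and exposes its parameters", {
  coh <- testCohort(nPerGroup = 4, nNodes = 10, nModules = 2, seed = 104)
  res <- nbsTest(coh, nPerm = 49, seed = 1, covariates = NULL)
  expect_equal(res@params$nPerm, 49L)
  expect_equal(res@params$tail, "patient>control")
  expect_gt(res@params$nEdgesTested, 0)
  expect_length(res@nullMaxSizes, 49)

  recs <- subjectRecords(coh)[1:5, ]           # 4 controls, 1 patient
  tiny <- cohort(recs, connMatrices(coh)[recs$subject_id], atlasTable(coh))
  expect_error(nbsTest(tiny, nPerm = 9), "2 subjects per group")
})
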