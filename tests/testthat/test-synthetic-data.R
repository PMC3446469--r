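test_that("invalid configuration fields are rejected by name", {
  expect_error(simulationConfig(propIfnHigh = 1.5), "propIfnHigh")
  expect_error(simulationConfig(moduleRho = 1), "moduleRho")
  expect_error(simulationConfig(noiseSd = 0), "noiseSd")
  expect_error(simulationConfig(pNonresponseGivenHigh = -0.1),
               "pNonresponseGivenHigh")
  expect_error(simulationConfig(irgNames = c("A", "A", letters[1:6])),
               "irgNames")
})

test_that("cohorts have the advertised shape and reproduce bit-for-bit", {
  cfg <- simulationConfig(nPatients = 15, nGenes = 120, seed = 42)
  co1 <- simulateCohort(cfg)
  co2 <- simulateCohort(cfg)
  expect_identical(exprs(co1), exprs(co2))
  expect_identical(clinicalTable(co1), clinicalTable(co2))
  expect_equal(dim(exprs(co1)), c(128L, 15L))
  clin <- clinicalTable(co1)
  expect_equal(nrow(clin), 15L)
  expect_true(all(clin$nonresponse_das28 %in% 0:1))
  # label is consistent with the continuous improvement draw
  expect_equal(as.integer(-clin$delta_das28 < 1.2), clin$nonresponse_das28)
  expect_true(all(clin$eular_category %in% c("good", "moderate", "none")))
  # a different seed changes the draw
  expect_false(identical(
    exprs(simulateCohort(simulationConfig(nPatients = 15, nGenes = 120,
                                          seed = 43))),
    exprs(co1)))
})

test_that("realized module correlation matches the derived implied value", {
  for (seed in c(1, 7)) {
    cfg <- simulationConfig(nPatients = 1500, nGenes = 0, seed = seed)
    co <- simulateCohort(cfg)
    cm <- cor(t(exprs(co)[cfg@irgNames, ]))
    expect_equal(mean(cm[upper.tri(cm)]), impliedIrgCorrelation(cfg),
                 tolerance = 0.05)
  }
  # and the default configuration implies the reported r of about 0.91
  expect_equal(impliedIrgCorrelation(simulationConfig()), 0.91,
               tolerance = 0.005)
})

test_that("background genes carry no label association", {
  cfg <- simulationConfig(nPatients = 40, nGenes = 1000, seed = 11)
  co <- simulateCohort(cfg)
  lab <- responseLabels(co)
  m <- exprs(co)[-(1:8), ]
  ps <- apply(m, 1, function(v)
    t.test(v[lab == 1], v[lab == 0], var.equal = TRUE)$p.value)
  frac <- mean(ps < 0.05)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / 1000))
})

test_that("module-free and perfectly separated limits give AUC 0.5 and 1", {
  nullCfg <- simulationConfig(nPatients = 2000, nGenes = 0,
                              moduleShift = 0, seed = 5)
  co <- simulateCohort(nullCfg)
  a0 <- auc(rocCurve(computeIfnScore(co), responseLabels(co)))
  expect_equal(a0, 0.5, tolerance = 0.04)

  sepCfg <- simulationConfig(nPatients = 60, nGenes = 0, moduleShift = 10,
                             noiseSd = 0.5, pNonresponseGivenHigh = 1,
                             pNonresponseGivenLow = 0, seed = 6)
  co <- simulateCohort(sepCfg)
  expect_equal(auc(rocCurve(computeIfnScore(co), responseLabels(co))), 1.0)
})

test_that("qPCR panels are linear-scale with the same log2 module structure", {
  cfg <- simulationConfig(nPatients = 2000, nGenes = 0, moduleShift = 2,
                          seed = 8)
  qp <- simulateQpcrPanel(cfg)
  expect_identical(scaleTag(qp), "linear")
  expect_equal(nrow(qp), 8L)
  expect_identical(exprs(simulateQpcrPanel(cfg)), exprs(qp))
  lg <- log2Transform(qp)
  high <- clinicalTable(qp)$latent_ifn_high == 1
  sc <- scores(computeIfnScore(lg, irgPanel()))
  expect_equal(mean(sc[high]) - mean(sc[!high]), 2, tolerance = 0.1)
})
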