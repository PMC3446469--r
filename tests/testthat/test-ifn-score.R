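test_that("the IFN score is the arithmetic mean over the gene set", {
  m <- matrix(3, 8, 2, dimnames = list(irgPanel()@members, c("P1", "P2")))
  sc <- computeIfnScore(makeCohort(m))
  expect_equal(unname(scores(sc)), c(3, 3))

  m2 <- matrix(0:7, 8, 1, dimnames = list(irgPanel()@members, "P1"))
  expect_equal(unname(scores(computeIfnScore(makeCohort(m2)))), 3.5)

  # one-gene set returns that gene's row
  one <- geneSet("ISG15")
  expect_equal(unname(scores(computeIfnScore(makeCohort(m2), one))),
               unname(m2["ISG15", ]))
  expect_error(computeIfnScore(makeCohort(m2[1:3, , drop = FALSE])),
               "ISG15")
})

test_that("scoring is linear and decomposes over single genes", {
  set.seed(1)
  m <- matrix(rnorm(8 * 6), 8, 6,
              dimnames = list(irgPanel()@members, paste0("p", 1:6)))
  base <- scores(computeIfnScore(makeCohort(m)))
  shifted <- scores(computeIfnScore(makeCohort(m + 1.7)))
  expect_equal(shifted, base + 1.7)
  single <- sapply(irgPanel()@members, function(g)
    scores(computeIfnScore(makeCohort(m), geneSet(g))))
  expect_equal(rowMeans(single), base)
})

test_that("the shipped panels carry the published gene names", {
  expect_identical(irgPanel()@members,
                   c("LY6E", "HERC5", "IFI44L", "ISG15", "MxA", "MxB",
                     "EPSTI1", "RSAD2"))
  expect_identical(irgPanel3()@members, c("EPSTI1", "RSAD2", "MxA"))
})

test_that("cohort combination centers away per-platform gene offsets", {
  set.seed(2)
  m <- matrix(rnorm(8 * 10), 8, 10,
              dimnames = list(irgPanel()@members, paste0("t", 1:10)))
  test <- makeCohort(m)
  offset <- m + matrix(rnorm(8, sd = 3), 8, 10)   # per-gene constant shift
  colnames(offset) <- paste0("v", 1:10)
  val <- makeCohort(offset)
  combined <- combineCohorts(test, val)
  expect_true(combined@centered)
  expect_equal(unname(scores(combined)[paste0("t", 1:10)]),
               unname(scores(combined)[paste0("v", 1:10)]),
               tolerance = 1e-9)
  expect_error(combineCohorts(test, test), "overlapping")
})

test_that("combining preserves within-cohort group separation", {
  cfg <- simulationConfig(nPatients = 20, nGenes = 0, exactCounts = TRUE,
                          pNonresponseGivenHigh = 1,
                          pNonresponseGivenLow = 0, seed = 3)
  co <- simulateCohort(cfg)
  m <- exprs(co)
  high <- clinicalTable(co)$latent_ifn_high == 1
  shifted <- m + 5   # a global platform shift
  colnames(shifted) <- paste0("v", seq_len(ncol(m)))
  combined <- combineCohorts(co, makeCohort(shifted))
  sep <- function(sc) mean(sc[high]) - mean(sc[!high])
  within <- sep(scores(computeIfnScore(medianCenterGenes(co))))
  got <- sep(scores(combined)[colnames(m)])
  expect_equal(got, within, tolerance = 1e-9)
})

test_that("the score group test matches the closed-form t statistic", {
  sv <- makeScore(c(1, 2, 3, 4, 5, 6))
  res <- scoreGroupTest(sv, c(1, 1, 1, 0, 0, 0))
  expect_equal(res$t, -3.674235, tolerance = 1e-6)
  expect_equal(res$df, 4)
  expect_equal(res$p, 2 * pt(-3.674235, 4), tolerance = 1e-6)
  expect_equal(unname(res$groupMeans), c(5, 2))

  same <- makeScore(rep(c(1, 2), 4))
  equal <- scoreGroupTest(same, c(0, 1, 0, 1, 1, 0, 1, 0))
  expect_equal(equal$t, 0)
  expect_equal(equal$p, 1)
  expect_error(scoreGroupTest(sv, c(1, 0, 0, 0, 0, 0)), "at least 2")
})

test_that("group-test p values are uniform under the null", {
  ps <- vapply(1:500, function(seed) {
    set.seed(seed)
    scoreGroupTest(makeScore(rnorm(16)), rep(c(0, 1), 8))$p
  }, numeric(1))
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})
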