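test_that("fold filter applies the at-least-two-fold boundary rule", {
  const <- makeCohort(matrix(5, 4, 6))
  expect_length(foldChangeFilter(const)@passing, 0)

  # all four patients deviate exactly log2(2) from the median: boundary
  # counts as exceeding
  edge <- makeCohort(rbind(g1 = c(0, 0, 2, 2)))
  res <- foldChangeFilter(edge, fold = 2, minPatients = 3)
  expect_identical(res@passing, "g1")
  expect_identical(unname(res@exceedCount), 4L)
  expect_error(foldChangeFilter(edge, minPatients = 5), "exceeds")
})

test_that("fold filter agrees with the brute-force oracle on random data", {
  for (seed in 1:3) {
    set.seed(seed)
    m <- matrix(rnorm(50 * 12, sd = 0.8), 50, 12,
                dimnames = list(sprintf("g%02d", 1:50), paste0("p", 1:12)))
    got <- foldChangeFilter(makeCohort(m), fold = 2, minPatients = 3)
    expect_identical(got@passing, filterBruteForce(m, 2, 3))
  }
})

test_that("fold filter is invariant to patient order and row offsets", {
  set.seed(4)
  m <- matrix(rnorm(30 * 10, sd = 0.9), 30, 10,
              dimnames = list(paste0("g", 1:30), paste0("p", 1:10)))
  base <- foldChangeFilter(makeCohort(m))@passing
  perm <- m[, sample(ncol(m))]
  expect_identical(foldChangeFilter(makeCohort(perm))@passing, base)
  shifted <- m + 7   # constant added to every row
  expect_identical(foldChangeFilter(makeCohort(shifted))@passing, base)
})

test_that("SAM d with s0 = 0 reduces to the two-sample t statistic", {
  set.seed(2)
  m <- matrix(rnorm(40 * 12), 40, 12)
  lab <- rep(c(0L, 1L), each = 6)
  co <- makeCohort(m)
  sam <- samTwoClass(co, lab, nPermutations = 100, s0 = 0)
  tref <- apply(m, 1, function(v)
    t.test(v[lab == 1], v[lab == 0], var.equal = TRUE)$statistic)
  expect_equal(unname(sam@d), unname(tref), tolerance = 1e-10)
})

test_that("SAM calls a strongly shifted gene and validates its inputs", {
  set.seed(3)
  n <- 40; lab <- rep(c(0L, 1L), each = 20)
  m <- matrix(rnorm(1000 * n), 1000, n,
              dimnames = list(paste0("g", 1:1000), paste0("p", 1:n)))
  m["g1", lab == 1] <- m["g1", lab == 1] + 10   # 10-SD mean shift
  sam <- samTwoClass(makeCohort(m), lab, nPermutations = 200)
  expect_true("g1" %in% sam@called)
  expect_lt(sam@q["g1"], 0.05)
  # q-values are monotone non-increasing in |d|
  ord <- order(abs(sam@d), decreasing = TRUE)
  expect_true(all(diff(sam@q[ord]) >= -1e-12))
  expect_true(all(sam@q >= 0 & sam@q <= 1))

  expect_error(samTwoClass(makeCohort(m), rep(0L, n), 200), "non-empty")
  expect_error(
    samTwoClass(makeCohort(m[, 1:5]), c(1L, 0L, 0L, 0L, 0L), 200),
    "at least 2")
  expect_error(samTwoClass(makeCohort(m), lab, nPermutations = 50),
               ">= 100")
})

test_that("small cohorts are analyzed by exact permutation enumeration", {
  set.seed(5)
  m <- matrix(rnorm(20 * 8), 20, 8)
  lab <- rep(c(0L, 1L), each = 4)
  sam <- samTwoClass(makeCohort(m), lab, nPermutations = 100)
  expect_true(sam@exact)
  expect_identical(sam@nPermutations, 70L)  # choose(8, 4) enumerations
})

test_that("planted module genes are recovered with high sensitivity", {
  hits <- vapply(1:10, function(seed) {
    cfg <- simulationConfig(nPatients = 40, nGenes = 500,
                            moduleShift = 4 * 0.35, propIfnHigh = 0.5,
                            exactCounts = TRUE, pNonresponseGivenHigh = 1,
                            pNonresponseGivenLow = 0, seed = seed)
    co <- simulateCohort(cfg)
    sam <- samTwoClass(co, responseLabels(co), nPermutations = 200,
                       seed = seed)
    mean(irgPanel()@members %in% sam@called)
  }, numeric(1))
  expect_gte(mean(hits), 0.9)
})
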