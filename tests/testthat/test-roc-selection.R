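test_that("ROC handles separation, ties, and the hand-computed fixture", {
  perfect <- rocCurve(c(5, 6, 1, 2), c(1, 1, 0, 0))
  expect_equal(auc(perfect), 1.0)
  allTied <- rocCurve(rep(2, 6), c(1, 0, 1, 0, 1, 0))
  expect_equal(auc(allTied), 0.5)
  r <- rocCurve(c(1, 2, 3, 4), c(0, 1, 0, 1))
  expect_equal(auc(r), 0.75)
  # curve runs from (0,0) to (1,1), monotone in both coordinates
  expect_equal(r@sensitivity[1], 0)
  expect_equal(r@fpr[1], 0)
  expect_equal(tail(r@sensitivity, 1), 1)
  expect_equal(tail(r@fpr, 1), 1)
  expect_error(rocCurve(1:4, c(1, 1, 1, 1)), "non-empty")
})

test_that("trapezoidal AUC equals the brute-force pairwise statistic", {
  for (seed in 1:50) {
    set.seed(seed)
    n <- sample(6:30, 1)
    s <- sample(seq(0, 3, by = 0.5), n, replace = TRUE)   # forces ties
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    expect_equal(auc(rocCurve(s, y)), aucBruteForce(s, y),
                 tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly increasing score transforms", {
  set.seed(7)
  s <- rnorm(40); y <- rbinom(40, 1, 0.4); y[1:2] <- c(0, 1)
  a <- auc(rocCurve(s, y))
  expect_equal(auc(rocCurve(exp(s), y)), a)
  expect_equal(auc(rocCurve(10 * s + 3, y)), a)
})

test_that("subset search enumerates all combinations and ranks them", {
  set.seed(8)
  m <- matrix(rnorm(8 * 20), 8, 20,
              dimnames = list(irgPanel()@members, paste0("p", 1:20)))
  lab <- rep(c(0L, 1L), 10)
  res <- exhaustiveSubsetSearch(makeCohort(m), irgPanel(), lab)
  expect_equal(nrow(res@table), 255L)   # 2^8 - 1 non-empty subsets
  full <- auc(rocCurve(colMeans(m), lab))
  expect_gte(res@bestAuc, full)
  expect_true(all(res@table$auc <= res@bestAuc))
  # all reported ties actually attain the maximum
  for (sub in res@bestSubsets)
    expect_equal(auc(rocCurve(colMeans(m[sub, , drop = FALSE]), lab)),
                 res@bestAuc)
  big <- geneSet(paste0("g", 1:21))
  expect_error(exhaustiveSubsetSearch(makeCohort(m), big, lab), "20")
})

test_that("the argmax subset retains a planted informative gene", {
  hits <- vapply(1:25, function(seed) {
    set.seed(seed)
    n <- 400
    lab <- rbinom(n, 1, 0.5)
    m <- rbind(info = rnorm(n) + 1.5 * lab,
               noise1 = rnorm(n), noise2 = rnorm(n))
    colnames(m) <- paste0("p", 1:n)
    res <- exhaustiveSubsetSearch(makeCohort(m), geneSet(rownames(m)), lab)
    all(vapply(res@bestSubsets, function(b) "info" %in% b, logical(1)))
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("fixed-specificity cutoffs maximize sensitivity under the bound", {
  perfect <- rocCurve(c(5, 6, 1, 2), c(1, 1, 0, 0))
  cp <- cutoffAtSpecificity(perfect, 1)
  expect_equal(cp$sensitivity, 1)
  expect_equal(cp$specificity, 1)

  tied <- rocCurve(rep(2, 6), c(1, 0, 1, 0, 1, 0))
  ct <- cutoffAtSpecificity(tied, 1)
  expect_equal(ct$sensitivity, 0)

  r <- rocCurve(c(1, 2, 3, 4), c(0, 1, 0, 1))
  cr <- cutoffAtSpecificity(r, 1)
  expect_gt(cr$threshold, 3)
  expect_equal(cr$sensitivity, 0.5)
  expect_equal(cr$specificity, 1)
})

test_that("package AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(9)
  for (i in 1:5) {
    s <- round(rnorm(30), 1)
    y <- c(0, 1, rbinom(28, 1, 0.5))
    ref <- as.numeric(pROC::auc(pROC::roc(y, s, direction = "<",
                                          quiet = TRUE)))
    expect_equal(auc(rocCurve(s, y)), ref, tolerance = 1e-12)
  }
})

test_that("bootstrap intervals bracket the point estimate", {
  set.seed(10)
  s <- c(rnorm(17, 1), rnorm(9))
  y <- rep(c(1, 0), c(17, 9))
  ci <- bootstrapAucCi(s, y, B = 500, seed = 4)
  expect_lte(ci$lower, ci$auc)
  expect_gte(ci$upper, ci$auc)
  expect_equal(ci$auc, aucBruteForce(s, y))
})
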