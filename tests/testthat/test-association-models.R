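test_that("binary-predictor OR equals the 2x2 cross-product ratio", {
  # predictor = 1: 6 non-responders / 2 responders; predictor = 0: 2 / 6
  response <- c(rep(0, 6), rep(1, 2), rep(0, 2), rep(1, 6))
  predictor <- rep(c(1, 0), each = 8)
  fit <- logisticFit(response, predictor)
  expect_equal(fit@table$or, 1 / 9, tolerance = 1e-6)
  expect_equal(fit@table$or, (2 * 6) / (6 * 2) * (2 / 6) / (6 / 2),
               tolerance = 1e-6)  # (a*d)/(b*c) = (2*2)/(6*6)
  expect_true(fit@table$ciLow <= fit@table$or &
                fit@table$or <= fit@table$ciHigh)
})

test_that("random 2x2 tables match their cross-product odds ratio", {
  set.seed(1)
  for (i in 1:20) {
    counts <- sample(2:10, 4, replace = TRUE)   # a b / c d, no zero cells
    y <- rep(c(1, 0, 1, 0), counts)
    x <- rep(c(1, 1, 0, 0), counts)
    fit <- logisticFit(y, x)
    expect_equal(fit@table$or,
                 (counts[1] * counts[4]) / (counts[2] * counts[3]),
                 tolerance = 1e-6)
  }
})

test_that("Nagelkerke R2 spans its range and the null model scores zero", {
  expect_equal(nagelkerkeR2(-10, -10, 30), 0)
  expect_equal(nagelkerkeR2(-20, 0, 30), 1)   # capped perfect prediction
  set.seed(2)
  y <- rbinom(50, 1, 0.5); y[1:2] <- 0:1
  fit <- logisticFit(y)                        # intercept only
  expect_equal(fit@nagelkerkeR2, 0)
  expect_equal(fit@logLik0, fit@logLik1)
  expect_equal(nrow(fit@table), 0L)
})

test_that("degenerate inputs raise explicit errors", {
  expect_error(logisticFit(rep(1, 10), rnorm(10)), "non-degenerate")
  y <- rep(c(0, 1), each = 10)
  xsep <- c(rnorm(10), rnorm(10) + 100)       # perfect separation
  expect_error(logisticFit(y, xsep), "separation")
  expect_error(logisticFit(y, data.frame(a = rnorm(20), b = rnorm(20),
                                         c = rnorm(20))), "at most 2")
  x <- rnorm(20)
  expect_error(logisticFit(y, data.frame(a = x, b = 2 * x)), "collinear")
})

test_that("fits transform correctly under affine predictor rescaling", {
  set.seed(3)
  y <- rbinom(80, 1, 0.5); y[1:2] <- 0:1
  x <- rnorm(80)
  f1 <- logisticFit(y, x)
  f2 <- logisticFit(y, 10 * x + 5)
  expect_equal(f2@table$estimate, f1@table$estimate / 10, tolerance = 1e-6)
  expect_equal(f2@table$se, f1@table$se / 10, tolerance = 1e-6)
  expect_equal(f2@table$p, f1@table$p, tolerance = 1e-6)
  expect_equal(f2@nagelkerkeR2, f1@nagelkerkeR2, tolerance = 1e-8)
})

test_that("null predictors give OR near 1 with uniform p values", {
  set.seed(4)
  ors <- replicate(200, {
    y <- rbinom(500, 1, 0.5); y[1:2] <- 0:1
    logisticFit(y, rnorm(500))@table$or
  })
  expect_equal(mean(log(ors)), 0, tolerance = 0.02)
})

test_that("the covariate screen reports stable and collinear adjustments", {
  cfg <- simulationConfig(nPatients = 300, nGenes = 0, seed = 5)
  co <- simulateCohort(cfg)
  sc <- computeIfnScore(co)
  clin <- clinicalTable(co)
  rep1 <- covariateScreen(clin, sc, covariates = c("seropositivity", "age"))
  uni <- rep1[rep1$model == "univariate" & rep1$predictor == "ifn_score", ]
  expect_lt(uni$or, 1)       # higher score, lower odds of response
  expect_lt(uni$p, 0.05)
  bi <- rep1[rep1$model == "bivariate", ]
  # independent covariates leave the score association intact
  expect_true(all(!bi$score_sign_flip))
  expect_true(all(!bi$score_lost_significance))
  expect_true(all(abs(log(bi$score_or / uni$or)) < log(1.1)))

  # a covariate identical to the score is flagged collinear
  clin$copy <- scores(sc)
  rep2 <- covariateScreen(clin, sc, covariates = "copy")
  expect_true(rep2$collinear[rep2$model == "bivariate"])
})

test_that("a confounder attenuates the score association toward the null", {
  set.seed(6)
  n <- 2000
  conf <- rnorm(n)
  scRaw <- conf + 0.3 * rnorm(n)                 # driven by the confounder
  response <- rbinom(n, 1, plogis(-1.2 * conf))
  clin <- data.frame(patient_id = paste0("p", 1:n),
                     nonresponse_das28 = 1L - response, confounder = conf)
  sv <- makeScore(scRaw)
  rep <- covariateScreen(clin, sv, covariates = "confounder")
  uni <- rep[rep$model == "univariate" & rep$predictor == "ifn_score", ]
  bi <- rep[rep$model == "bivariate", ]
  expect_lt(uni$or, 1)
  expect_gt(bi$score_or, uni$or)   # adjusted OR moves toward 1
  expect_lt(abs(log(bi$score_or)), abs(log(uni$or)) / 2)
})
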