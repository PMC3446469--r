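#' Nagelkerke pseudo R-squared
#'
#' `(1 - (L0/L1)^(2/n)) / (1 - L0^(2/n))` computed from the log likelihoods
#' of the intercept-only (`ll0`) and fitted (`ll1`) models.
#'
#' @param ll0,ll1 log likelihoods of the null and fitted model.
#' @param n number of observations.
#' @return the rescaled likelihood-ratio R-squared in `[0, 1]`.
#' @export
nagelkerkeR2 <- function(ll0, ll1, n) {
  coxSnell <- 1 - exp((2 / n) * (ll0 - ll1))
  maxR2 <- 1 - exp((2 / n) * ll0)
  max(0, min(1, coxSnell / maxR2))
}

#' Logistic regression with odds ratios and Wald intervals
#'
#' Maximum-likelihood logistic regression of a binary clinical response on
#' at most two predictors (small cohorts preclude larger models), fitted by
#' iteratively reweighted least squares. Reports per-predictor odds ratios
#' with 95% Wald intervals `exp(beta +- 1.96 * SE)`, two-sided p values,
#' and the Nagelkerke R-squared. Perfect separation is a hard error rather
#' than a silently diverging fit.
#'
#' @param outcome binary 0/1 vector (1 = clinical response, i.e. DAS28
#'   improvement >= 1.2, in the published analyses).
#' @param predictors `NULL` (null model), a numeric vector, or a
#'   data.frame/matrix with at most 2 columns.
#' @return a [LogisticFit-class].
#' @examples
#' y <- rep(c(1, 0), c(8, 8))
#' x <- c(rep(1, 2), rep(0, 6), rep(1, 6), rep(0, 2))
#' logisticFit(y, x)   # OR = (2*2)/(6*6) = 1/9
#' @export
logisticFit <- function(outcome, predictors = NULL) {
  outcome <- as.integer(outcome)
  if (!all(outcome %in% c(0L, 1L)) || length(unique(outcome)) < 2L)
    stop("outcome must be binary and non-degenerate")
  if (is.null(predictors)) {
    df <- data.frame(.y = outcome)
  } else {
    if (is.vector(predictors) && !is.list(predictors))
      predictors <- data.frame(predictor = predictors)
    predictors <- as.data.frame(predictors)
    if (ncol(predictors) > 2L)
      stop("at most 2 predictors are supported")
    if (nrow(predictors) != length(outcome))
      stop("predictors must have one row per outcome")
    df <- data.frame(.y = outcome, predictors, check.names = FALSE)
  }
  keep <- stats::complete.cases(df)
  nDropped <- sum(!keep)
  if (nDropped)
    message(nDropped, " observation(s) excluded for missing values")
  df <- df[keep, , drop = FALSE]
  n <- nrow(df)

  # separation manifests as a "fitted probabilities 0 or 1" warning; it is
  # diagnosed explicitly below, so the warning itself is muffled
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., data = df, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-10,
                                            maxit = 100L)),
    warning = function(w) {
      if (grepl("fitted probabilities|did not converge",
                conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  if (anyNA(coef(fit)))
    stop("collinear predictors: ",
         paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "))
  mu <- stats::fitted(fit)
  if (all(abs(mu - df$.y) < 1e-6) && ncol(df) > 1L)
    stop("perfect separation: the predictor(s) classify the outcome ",
         "exactly; odds ratios are unbounded")

  ll1 <- as.numeric(stats::logLik(fit))
  ll0 <- as.numeric(stats::logLik(
    stats::glm(.y ~ 1, data = df, family = stats::binomial())))
  sm <- summary(fit)$coefficients
  terms <- setdiff(rownames(sm), "(Intercept)")
  tab <- data.frame(
    term = terms,
    estimate = sm[terms, 1L], se = sm[terms, 2L],
    or = exp(sm[terms, 1L]),
    ciLow = exp(sm[terms, 1L] - 1.96 * sm[terms, 2L]),
    ciHigh = exp(sm[terms, 1L] + 1.96 * sm[terms, 2L]),
    p = sm[terms, 4L],
    row.names = NULL, stringsAsFactors = FALSE)
  methods::new("LogisticFit", table = tab, logLik0 = ll0, logLik1 = ll1,
               nagelkerkeR2 = nagelkerkeR2(ll0, ll1, n), n = as.integer(n))
}

#' Univariate and bivariate covariate screen
#'
#' Reproduces the stepwise association analysis around the IFN score: one
#' univariate logistic fit of clinical response on the score, one univariate
#' fit per covariate, and one bivariate fit (score + covariate) per
#' covariate. For each adjustment the report notes whether the score's odds
#' ratio flips the direction of association or loses nominal significance
#' (p >= 0.05), and whether the pair was collinear. Patients with missing
#' covariate values are excluded fit-wise (counts in column `n`).
#'
#' @param clinical data.frame with `nonresponse_das28` and the covariate
#'   columns.
#' @param score a [ScoreVector-class] (patients matched by `patient_id` when
#'   present, otherwise by position).
#' @param covariates covariate column names to screen.
#' @return a data.frame report: `model`, `predictor`, `or`, `ciLow`,
#'   `ciHigh`, `p`, `r2_nagelkerke`, `n`, and for bivariate rows the
#'   score-stability flags `score_or`, `score_p`, `score_sign_flip`,
#'   `score_lost_significance`, `collinear`.
#' @export
covariateScreen <- function(clinical, score,
                            covariates = c("seropositivity",
                                           "n_prior_tnf_blockers",
                                           "lipid_lowering", "erosions",
                                           "prednisolone", "methotrexate",
                                           "age", "gender")) {
  clinical <- as.data.frame(clinical)
  if (!"nonresponse_das28" %in% names(clinical))
    stop("clinical table must contain 'nonresponse_das28'")
  covariates <- intersect(covariates, names(clinical))
  if (!length(covariates)) stop("no requested covariates present")
  sc <- scores(score)
  if ("patient_id" %in% names(clinical) && !is.null(names(sc))) {
    idx <- match(names(sc), clinical$patient_id)
    if (anyNA(idx)) stop("clinical table is missing scored patients")
    clinical <- clinical[idx, , drop = FALSE]
  } else if (nrow(clinical) != length(sc)) {
    stop("clinical table and score have different patient counts")
  }
  response <- 1L - as.integer(clinical$nonresponse_das28)

  row <- function(model, predictor, fit, extra = NULL) {
    tab <- fit@table[fit@table$term == make.names(predictor) |
                       fit@table$term == predictor, , drop = FALSE]
    if (!nrow(tab)) tab <- fit@table[1L, , drop = FALSE]
    out <- data.frame(model = model, predictor = predictor,
                      or = tab$or, ciLow = tab$ciLow, ciHigh = tab$ciHigh,
                      p = tab$p, r2_nagelkerke = fit@nagelkerkeR2,
                      n = fit@n, stringsAsFactors = FALSE)
    if (!is.null(extra)) out <- cbind(out, extra)
    out
  }

  naRow <- function(model, predictor) {
    data.frame(model = model, predictor = predictor, or = NA_real_,
               ciLow = NA_real_, ciHigh = NA_real_, p = NA_real_,
               r2_nagelkerke = NA_real_, n = NA_integer_,
               stringsAsFactors = FALSE)
  }
  uniScore <- tryCatch(logisticFit(response, data.frame(ifn_score = sc)),
                       error = function(e) e)
  if (inherits(uniScore, "error")) {
    # e.g. a perfectly separating score: reported, not fatal to the screen
    uniSig <- NA; uniDir <- NA
    rows <- list(naRow("univariate", "ifn_score"))
  } else {
    uniSig <- uniScore@table$p < 0.05
    uniDir <- sign(uniScore@table$estimate)
    rows <- list(row("univariate", "ifn_score", uniScore))
  }

  for (cv in covariates) {
    v <- clinical[[cv]]
    if (is.character(v) || is.factor(v)) v <- as.integer(factor(v)) - 1L
    fitU <- tryCatch(logisticFit(response, stats::setNames(
      data.frame(v), cv)), error = function(e) e)
    if (!inherits(fitU, "error")) rows <- c(rows, list(row("univariate",
                                                           cv, fitU)))
    fitB <- tryCatch(
      logisticFit(response, stats::setNames(data.frame(sc, v),
                                            c("ifn_score", cv))),
      error = function(e) e)
    if (inherits(fitB, "error")) {
      collinear <- grepl("collinear|separation", conditionMessage(fitB))
      rows <- c(rows, list(data.frame(
        model = "bivariate", predictor = cv, or = NA_real_,
        ciLow = NA_real_, ciHigh = NA_real_, p = NA_real_,
        r2_nagelkerke = NA_real_, n = NA_integer_,
        score_or = NA_real_, score_p = NA_real_,
        score_sign_flip = NA, score_lost_significance = NA,
        collinear = collinear, stringsAsFactors = FALSE)))
      next
    }
    st <- fitB@table[fitB@table$term == "ifn_score", ]
    rows <- c(rows, list(row("bivariate", cv, fitB, extra = data.frame(
      score_or = st$or, score_p = st$p,
      score_sign_flip = sign(st$estimate) != uniDir,
      score_lost_significance = uniSig && st$p >= 0.05,
      collinear = FALSE, stringsAsFactors = FALSE))))
  }
  out <- do.call(rbind, lapply(rows, function(r) {
    for (cl in c("score_or", "score_p", "score_sign_flip",
                 "score_lost_significance", "collinear"))
      if (!cl %in% names(r)) r[[cl]] <- NA
    r
  }))
  rownames(out) <- NULL
  out
}

#' Write an association report as tab-separated text
#'
#' @param report data.frame from [covariateScreen()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeAssociationReport <- function(report, path) {
  write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
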