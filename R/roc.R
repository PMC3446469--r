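# rank-based AUC: Mann-Whitney probability with half credit for ties;
# identical to trapezoidal integration of the empirical ROC curve
.aucRank <- function(scores, labels) {
  n1 <- sum(labels == 1L); n0 <- length(labels) - n1
  r <- rank(scores)                     # ties -> midranks = half credit
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

.alignScoreLabels <- function(scores, labels) {
  if (methods::is(scores, "ScoreVector")) scores <- scores@scores
  if (!is.null(names(scores)) && !is.null(names(labels))) {
    if (!all(names(scores) %in% names(labels)))
      stop("labels are missing some scored patients")
    labels <- labels[names(scores)]
  }
  list(scores = as.numeric(scores),
       labels = .checkBinaryLabels(labels, length(scores)))
}

#' Empirical ROC curve and integrated AUC
#'
#' Constructs the empirical ROC curve of a score against binary non-response
#' labels: a patient is called positive (non-responder) when their score is
#' at or above the threshold; sensitivity and 1 - specificity are evaluated
#' at every distinct score value. The AUC is the trapezoidal integral of the
#' curve, which equals the Mann-Whitney probability that a random
#' non-responder outscores a random responder, with ties receiving half
#' credit.
#'
#' @param scores a [ScoreVector-class] or named/plain numeric vector.
#' @param labels binary 0/1 labels (1 = non-responder); both classes must be
#'   non-empty.
#' @return a [RocResult-class].
#' @examples
#' rocCurve(c(1, 2, 3, 4), c(0, 1, 0, 1))   # AUC 0.75
#' @export
rocCurve <- function(scores, labels) {
  al <- .alignScoreLabels(scores, labels)
  s <- al$scores; y <- al$labels
  nPos <- sum(y == 1L); nNeg <- sum(y == 0L)
  ord <- order(s, decreasing = TRUE)
  sSort <- s[ord]; ySort <- y[ord]
  last <- !duplicated(sSort, fromLast = TRUE)   # one point per distinct score
  tp <- cumsum(ySort)[last]
  fp <- cumsum(1L - ySort)[last]
  thresholds <- c(Inf, sSort[last])
  sens <- c(0, tp / nPos)
  fpr <- c(0, fp / nNeg)
  auc <- sum(diff(fpr) * (sens[-1L] + sens[-length(sens)]) / 2)
  methods::new("RocResult", thresholds = thresholds, sensitivity = sens,
               fpr = fpr, auc = auc, positiveClass = "non-response",
               nPos = nPos, nNeg = nNeg)
}

#' Exhaustively search gene subsets for maximal AUC
#'
#' Evaluates every non-empty subset of the gene set: the subset score of a
#' patient is the mean log2 expression over the subset members, and its AUC
#' against the non-response labels is computed as in [rocCurve()]. All
#' subsets tied at the maximal AUC are reported (the published search over
#' the eight interferon response genes found three tied subsets, of sizes
#' 3, 4 and 6).
#'
#' @param x a log2-scale [IFNCohort-class].
#' @param gs a [GeneSet-class] with at most 20 members (2^20 - 1 subsets is
#'   the enumeration guard).
#' @param labels binary 0/1 non-response labels.
#' @return a [SubsetSearchResult-class]; the result table is sorted by AUC
#'   descending.
#' @export
exhaustiveSubsetSearch <- function(x, gs = irgPanel(), labels) {
  .assertLog2(x, "exhaustiveSubsetSearch()")
  if (length(gs@members) > 20L)
    stop("gene set has ", length(gs@members), " members; exhaustive ",
         "enumeration is limited to 20 (consider a greedy search, ",
         "not implemented)")
  m <- exprs(x)
  missing <- setdiff(gs@members, rownames(m))
  if (length(missing))
    stop("gene set members missing from the cohort: ",
         paste(missing, collapse = ", "))
  labels <- .checkBinaryLabels(labels, ncol(m))
  sub <- m[gs@members, , drop = FALSE]
  g <- length(gs@members)
  subsets <- unlist(lapply(seq_len(g), function(sz)
    combn(gs@members, sz, simplify = FALSE)), recursive = FALSE)
  auc <- vapply(subsets, function(mem) {
    .aucRank(colMeans(sub[mem, , drop = FALSE]), labels)
  }, numeric(1))
  tab <- data.frame(
    members = vapply(subsets, paste, character(1), collapse = "+"),
    size = lengths(subsets), auc = auc, stringsAsFactors = FALSE)
  tab <- tab[order(-tab$auc, tab$size), ]
  rownames(tab) <- NULL
  best <- max(auc)
  methods::new("SubsetSearchResult", table = tab, bestAuc = best,
               bestSubsets = subsets[auc == best])
}

#' Score cutoff at a specificity constraint
#'
#' Among all thresholds of an ROC curve whose specificity is at least
#' `minSpecificity`, returns the one maximizing sensitivity; ties are broken
#' toward higher specificity, then toward the higher threshold. With
#' `minSpecificity = 1` this is the rule behind "predict non-response with
#' 100% specificity".
#'
#' @param r a [RocResult-class].
#' @param minSpecificity required specificity in `[0, 1]`.
#' @return a list with `threshold`, `sensitivity`, `specificity`.
#' @export
cutoffAtSpecificity <- function(r, minSpecificity = 1) {
  stopifnot(minSpecificity >= 0, minSpecificity <= 1)
  spec <- 1 - r@fpr
  ok <- which(spec >= minSpecificity)   # non-empty: threshold Inf qualifies
  best <- ok[order(-r@sensitivity[ok], -spec[ok], -r@thresholds[ok])][1L]
  list(threshold = r@thresholds[best],
       sensitivity = r@sensitivity[best],
       specificity = spec[best])
}

#' Bootstrap confidence interval for an AUC
#'
#' Bootstrap interval for the AUC of a score/label pairing, resampling
#' patients with replacement within each label class (stratified), as is
#' standard for ROC analysis of fixed-design cohorts. The default interval
#' is bias-corrected and accelerated (BCa, with jackknife acceleration),
#' which is markedly better calibrated than the raw percentile interval for
#' a bounded, discrete statistic like the AUC on small cohorts; the plain
#' percentile interval is available as an option.
#'
#' @param scores numeric or [ScoreVector-class].
#' @param labels binary 0/1 labels.
#' @param B number of bootstrap replicates.
#' @param conf confidence level.
#' @param method `"bca"` (default) or `"percentile"`.
#' @param seed RNG seed.
#' @return a list with `auc` (point estimate), `lower`, `upper`.
#' @export
bootstrapAucCi <- function(scores, labels, B = 2000L, conf = 0.95,
                           method = c("bca", "percentile"), seed = 1L) {
  method <- match.arg(method)
  al <- .alignScoreLabels(scores, labels)
  s <- al$scores; y <- al$labels
  iPos <- which(y == 1L); iNeg <- which(y == 0L)
  a <- .aucRank(s, y)
  boot <- .withSeed(seed, {
    vapply(seq_len(B), function(b) {
      idx <- c(sample(iPos, replace = TRUE), sample(iNeg, replace = TRUE))
      .aucRank(s[idx], y[idx])
    }, numeric(1))
  })
  alpha <- (1 - conf) / 2
  probs <- c(alpha, 1 - alpha)
  if (method == "bca" && stats::sd(boot) > 0) {
    jack <- vapply(seq_along(y), function(i) .aucRank(s[-i], y[-i]),
                   numeric(1))
    jm <- mean(jack)
    denom <- 6 * sum((jm - jack)^2)^1.5
    acc <- if (denom > 0) sum((jm - jack)^3) / denom else 0
    pLess <- mean(boot < a) + 0.5 * mean(boot == a)
    pLess <- min(max(pLess, 1 / (B + 1)), B / (B + 1))
    z0 <- stats::qnorm(pLess)
    zq <- stats::qnorm(probs)
    probs <- stats::pnorm(z0 + (z0 + zq) / (1 - acc * (z0 + zq)))
  }
  ci <- stats::quantile(boot, probs, names = FALSE)
  list(auc = a, lower = ci[1L], upper = ci[2L])
}

#' Write ROC results as tab-separated text
#'
#' Writes the curve points (threshold, sensitivity, 1 - specificity)
#' preceded by a one-line comment summary with the AUC and class sizes.
#'
#' @param r a [RocResult-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeRocResult <- function(r, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# auc=%.6f n_pos=%d n_neg=%d", r@auc, r@nPos,
                     r@nNeg), con)
  df <- data.frame(threshold = r@thresholds, sensitivity = r@sensitivity,
                   fpr = r@fpr)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeRocResult
#' @param x a [SubsetSearchResult-class].
#' @export
writeSubsetSearchResult <- function(x, path) {
  write.table(x@table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname rocAccessors
#' @export
setGeneric("auc", function(x) standardGeneric("auc"))

#' Accessors for RocResult
#'
#' @param x a [RocResult-class].
#' @return `auc()`: the area under the curve.
#' @export
setMethod("auc", "RocResult", function(x) x@auc)
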