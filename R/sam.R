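# SAM-style two-class permutation analysis. No maintained SAM implementation
# ships with the supported dependency set, so the d statistic, the fudge
# constant and the permutation FDR are implemented here directly.

# relative difference statistic: d = (mean1 - mean0) / (s + s0), with s the
# pooled-variance standard error of the difference (gene-specific scatter).
# labels may be a 0/1 vector or a matrix of label columns sharing one class
# size (permutations); results then have one column per labeling.
.samD <- function(m, m2, labels, s0) {
  L <- as.matrix(labels)
  n1 <- sum(L[, 1L]); n0 <- nrow(L) - n1
  S1 <- m %*% L; Q1 <- m2 %*% L
  tot <- rowSums(m); tot2 <- rowSums(m2)
  mu1 <- S1 / n1; mu0 <- (tot - S1) / n0
  ss <- pmax(Q1 - n1 * mu1^2, 0) + pmax((tot2 - Q1) - n0 * mu0^2, 0)
  a <- (1 / n1 + 1 / n0) / (n1 + n0 - 2)
  s <- sqrt(a * ss)
  list(d = drop((mu1 - mu0) / (s + s0)), s = drop(s))
}

# Tusher-style automatic fudge constant: candidate s0 over percentiles of s,
# minimizing the coefficient of variation of the d statistic's scale (MAD)
# across s-quantile windows
.samS0Cv <- function(m, m2, labels, s) {
  cand <- stats::quantile(s, probs = seq(0, 1, 0.05), names = FALSE)
  bins <- cut(rank(s, ties.method = "first"), breaks = 10L)
  cvs <- vapply(cand, function(s0) {
    d <- .samD(m, m2, labels, s0)$d
    mads <- tapply(d, bins, stats::mad)
    stats::sd(mads) / abs(mean(mads))
  }, numeric(1))
  cand[which.min(cvs)]
}

#' SAM two-class differential expression
#'
#' Computes the SAM relative-difference statistic
#' `d = (mean_1 - mean_0) / (s + s0)` per gene — `s` the pooled standard
#' error of the group-mean difference, `s0` a small "fudge" constant
#' stabilizing low-variance genes — and estimates per-gene false discovery
#' rates from the permutation distribution of `d` over label permutations.
#' The q value of a gene is the estimated FDR of the gene list called at its
#' `|d|`, monotonized so that q is non-increasing in `|d|` (step-up). All
#' distinct label assignments are enumerated exactly when there are no more
#' of them than `nPermutations`; otherwise `nPermutations` uniform draws are
#' used.
#'
#' @param x a log2-scale [IFNCohort-class].
#' @param labels binary 0/1 per patient (e.g. non-response); both classes
#'   must have at least 2 members.
#' @param nPermutations number of label permutations (>= 100).
#' @param fdrThreshold FDR used for calling genes.
#' @param s0 the fudge constant; `NULL` selects it by `s0Method`.
#' @param s0Method `"quantile"` (default: the 5th percentile of the per-gene
#'   standard errors) or `"cv"` (coefficient-of-variation minimization).
#' @param seed RNG seed for sampled permutations.
#' @return a [SamResult-class].
#' @examples
#' cohort <- simulateCohort(simulationConfig(nPatients = 20, nGenes = 200))
#' sam <- samTwoClass(cohort, responseLabels(cohort), nPermutations = 200)
#' sam
#' @export
samTwoClass <- function(x, labels, nPermutations = 1000L,
                        fdrThreshold = 0.05, s0 = NULL,
                        s0Method = c("quantile", "cv"), seed = 1L) {
  .assertLog2(x, "samTwoClass()")
  m <- exprs(x)
  labels <- .checkBinaryLabels(labels, ncol(m))
  n1 <- sum(labels); n0 <- length(labels) - n1
  if (min(n1, n0) < 2L) stop("each class must have at least 2 patients")
  nPermutations <- as.integer(nPermutations)
  if (nPermutations < 100L) stop("nPermutations must be >= 100")
  s0Method <- match.arg(s0Method)

  m2 <- m^2
  sObs <- .samD(m, m2, labels, 0)$s
  if (is.null(s0)) {
    s0 <- switch(s0Method,
      quantile = stats::quantile(sObs, 0.05, names = FALSE),
      cv = .samS0Cv(m, m2, labels, sObs))
  }
  dObs <- .samD(m, m2, labels, s0)$d

  nDistinct <- choose(length(labels), n1)
  exact <- nDistinct <= nPermutations
  if (exact) {
    idx <- combn(length(labels), n1)
    permLabels <- matrix(0, length(labels), ncol(idx))
    permLabels[cbind(as.vector(idx), rep(seq_len(ncol(idx)), each = n1))] <- 1
  } else {
    permLabels <- .withSeed(seed,
      replicate(nPermutations, sample(labels)))
  }
  B <- ncol(permLabels)

  # all permuted |d| pooled; exceedance counts by binary search
  absNull <- sort(abs(.samD(m, m2, permLabels, s0)$d))
  absObs <- abs(dObs)
  sortedObs <- sort(absObs)
  nGE_null <- length(absNull) -
    findInterval(absObs, absNull, left.open = TRUE)
  nGE_obs <- length(sortedObs) -
    findInterval(absObs, sortedObs, left.open = TRUE)
  qRaw <- pmin((nGE_null / B) / nGE_obs, 1)

  # step-up monotonization: q non-increasing in |d|
  ord <- order(absObs, decreasing = TRUE)
  qMono <- numeric(length(qRaw))
  qMono[ord] <- rev(cummin(rev(qRaw[ord])))

  names(dObs) <- names(qMono) <- rownames(m)
  methods::new("SamResult",
    d = dObs, q = qMono, called = rownames(m)[qMono <= fdrThreshold],
    nPermutations = B, s0 = unname(s0), fdrThreshold = fdrThreshold,
    exact = exact)
}

#' Write a SAM result as tab-separated text
#'
#' @param x a [SamResult-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeSamResult <- function(x, path) {
  df <- data.frame(gene_id = names(x@d), d = unname(x@d),
                   q_value = unname(x@q),
                   called = as.integer(names(x@d) %in% x@called))
  df <- df[order(-abs(df$d)), ]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
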