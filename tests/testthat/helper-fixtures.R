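# shared fixtures and independent oracles used across test files

# build a cohort straight from a matrix (optionally with labels in clinical)
makeCohort <- function(m, labels = NULL, scaleTag = "log2") {
  if (is.null(rownames(m))) rownames(m) <- paste0("g", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("p", seq_len(ncol(m)))
  clin <- if (!is.null(labels))
    data.frame(patient_id = colnames(m), nonresponse_das28 = labels)
  IFNCohort(m, clinical = clin, scaleTag = scaleTag)
}

makeScore <- function(values, ids = paste0("p", seq_along(values))) {
  new("ScoreVector", scores = setNames(values, ids), geneSet = "g",
      centered = FALSE)
}

# brute-force Mann-Whitney AUC: loop over every positive/negative pair,
# half credit for ties (independent of the package's rank/trapezoid paths)
aucBruteForce <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (n in neg)
    total <- total + (p > n) + 0.5 * (p == n)
  total / (length(pos) * length(neg))
}

# brute-force fold-change filter: explicit double loop over genes/patients
filterBruteForce <- function(m, fold = 2, minPatients = 3) {
  passing <- character()
  for (g in rownames(m)) {
    med <- median(m[g, ])
    count <- 0
    for (p in colnames(m))
      if (abs(m[g, p] - med) >= log2(fold)) count <- count + 1
    if (count >= minPatients) passing <- c(passing, g)
  }
  passing
}
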