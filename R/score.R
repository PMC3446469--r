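#' Construct a gene set
#'
#' @param members character vector of unique gene identifiers.
#' @param name label for the set.
#' @return a [GeneSet-class].
#' @export
geneSet <- function(members, name = "gene set") {
  methods::new("GeneSet", name = name, members = as.character(members))
}

#' The shipped interferon-response gene panels
#'
#' `irgPanel()` returns the eight-gene type I interferon response panel of
#' the rituximab-response signature (LY6E, HERC5, IFI44L, ISG15, MxA, MxB,
#' EPSTI1, RSAD2); `irgPanel3()` returns the published three-gene subset
#' (EPSTI1, RSAD2, MxA) that maximized validation AUC. Both are read from
#' plain-text fixtures under `inst/extdata/`.
#'
#' @return a [GeneSet-class].
#' @examples
#' irgPanel()
#' irgPanel3()
#' @export
irgPanel <- function() {
  readGeneSet(system.file("extdata", "irg_panel8.txt", package = "ifnscore"),
              name = "IRG8")
}

#' @rdname irgPanel
#' @export
irgPanel3 <- function() {
  readGeneSet(system.file("extdata", "irg_panel3.txt", package = "ifnscore"),
              name = "IRG3")
}

#' Read / write a gene set as plain text (one identifier per line)
#'
#' @param path file to read or write.
#' @param name label for the set read.
#' @return `readGeneSet`: a [GeneSet-class].
#' @export
readGeneSet <- function(path, name = basename(path)) {
  members <- readLines(path)
  members <- members[nzchar(trimws(members))]
  geneSet(trimws(members), name = name)
}

#' @rdname readGeneSet
#' @param gs a [GeneSet-class] to write.
#' @export
writeGeneSet <- function(gs, path) {
  writeLines(gs@members, path)
  invisible(path)
}

#' @rdname computeIfnScore
#' @export
setGeneric("computeIfnScore",
  function(x, gs = irgPanel(), centered = FALSE)
    standardGeneric("computeIfnScore"))

#' Compute the composite IFN score
#'
#' The IFN score of a patient is the arithmetic mean of the log2 expression
#' levels of the gene-set members (by default the eight interferon response
#' genes). Higher scores indicate stronger type I interferon activity and
#' predict non-response to rituximab.
#'
#' @param x a log2-scale [IFNCohort-class] containing every set member. For
#'   qPCR panels stored on the linear scale, apply [log2Transform()] first.
#' @param gs a [GeneSet-class] (default [irgPanel()]).
#' @param centered provenance flag recorded on the result; set by
#'   [combineCohorts()].
#' @return a [ScoreVector-class], one finite score per patient.
#' @examples
#' cohort <- simulateCohort(simulationConfig(nPatients = 10, nGenes = 20))
#' computeIfnScore(cohort)
#' @export
setMethod("computeIfnScore", "IFNCohort",
  function(x, gs = irgPanel(), centered = FALSE) {
  .assertLog2(x, "computeIfnScore()")
  m <- exprs(x)
  missing <- setdiff(gs@members, rownames(m))
  if (length(missing))
    stop("gene set members missing from the cohort: ",
         paste(missing, collapse = ", "))
  scores <- colMeans(m[gs@members, , drop = FALSE])
  methods::new("ScoreVector", scores = scores, geneSet = gs@members,
               centered = centered)
})

#' Combine two cohorts into one centered score
#'
#' To pool cohorts measured on different platforms (microarray test cohort,
#' qPCR validation cohort), each cohort's gene rows are median-centered
#' independently (removing platform-specific per-gene offsets), the centered
#' matrices are concatenated, and the IFN score is computed on the combined
#' matrix.
#'
#' @param test,validation log2-scale [IFNCohort-class] objects with disjoint
#'   patient identifiers, each containing every gene-set member.
#' @param gs a [GeneSet-class].
#' @return a [ScoreVector-class] over all patients of both cohorts, flagged
#'   `centered`.
#' @export
combineCohorts <- function(test, validation, gs = irgPanel()) {
  .assertLog2(test, "combineCohorts()")
  .assertLog2(validation, "combineCohorts()")
  overlap <- intersect(colnames(test), colnames(validation))
  if (length(overlap))
    stop("overlapping patient identifiers: ",
         paste(overlap, collapse = ", "))
  ct <- medianCenterGenes(test)
  cv <- medianCenterGenes(validation)
  keep <- gs@members
  for (co in list(ct, cv)) {
    missing <- setdiff(keep, rownames(exprs(co)))
    if (length(missing))
      stop("gene set members missing from a cohort: ",
           paste(missing, collapse = ", "))
  }
  m <- cbind(exprs(ct)[keep, , drop = FALSE],
             exprs(cv)[keep, , drop = FALSE])
  combined <- IFNCohort(m, scaleTag = "log2")
  computeIfnScore(combined, gs, centered = TRUE)
}

#' Compare scores between response groups
#'
#' Unpaired equal-variance Student t test of the IFN score between
#' non-responders (label 1) and responders (label 0).
#'
#' @param s a [ScoreVector-class].
#' @param labels binary 0/1 labels in the order of `s`'s patients (or named
#'   by patient identifier).
#' @return a list with `t`, `df`, `p`, and `groupMeans` (named: responder,
#'   nonresponder).
#' @export
scoreGroupTest <- function(s, labels) {
  sc <- s@scores
  if (!is.null(names(labels))) {
    if (!all(names(sc) %in% names(labels)))
      stop("labels are missing some scored patients")
    labels <- labels[names(sc)]
  }
  labels <- .checkBinaryLabels(labels, length(sc))
  if (min(table(labels)) < 2L)
    stop("each response group must have at least 2 patients")
  tt <- stats::t.test(sc[labels == 1L], sc[labels == 0L], var.equal = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value,
       groupMeans = c(responder = mean(sc[labels == 0L]),
                      nonresponder = mean(sc[labels == 1L])))
}

#' Write a score vector as tab-separated text
#'
#' @param s a [ScoreVector-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeScoreVector <- function(s, path) {
  df <- data.frame(patient_id = names(s@scores), score = unname(s@scores))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname scoreVectorAccessors
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))

#' Accessors for ScoreVector
#'
#' @param x a [ScoreVector-class].
#' @return `scores()`: the named numeric score vector.
#' @export
setMethod("scores", "ScoreVector", function(x) x@scores)
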