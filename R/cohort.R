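#' Construct an IFNCohort
#'
#' @param exprs numeric matrix, genes in rows (unique rownames) and patients
#'   in columns (unique colnames).
#' @param clinical optional data.frame of per-patient clinical variables,
#'   one row per patient in the same order as `colnames(exprs)` (or with a
#'   `patient_id` column used for matching).
#' @param scaleTag `"log2"` (default) or `"linear"`.
#' @return an [IFNCohort-class] object.
#' @examples
#' m <- matrix(rnorm(8), 2, 4,
#'             dimnames = list(c("g1", "g2"), paste0("p", 1:4)))
#' cohort <- IFNCohort(m)
#' scaleTag(cohort)
#' @export
IFNCohort <- function(exprs, clinical = NULL, scaleTag = c("log2", "linear")) {
  scaleTag <- match.arg(scaleTag)
  exprs <- as.matrix(exprs)
  storage.mode(exprs) <- "double"
  if (is.null(clinical)) {
    cd <- S4Vectors::DataFrame(row.names = colnames(exprs))
  } else {
    clinical <- as.data.frame(clinical)
    if ("patient_id" %in% names(clinical)) {
      idx <- match(colnames(exprs), clinical$patient_id)
      if (anyNA(idx))
        stop("clinical table is missing patients: ",
             paste(colnames(exprs)[is.na(idx)], collapse = ", "))
      clinical <- clinical[idx, setdiff(names(clinical), "patient_id"),
                           drop = FALSE]
    } else if (nrow(clinical) != ncol(exprs)) {
      stop("clinical table must have one row per patient")
    }
    cd <- S4Vectors::DataFrame(clinical, row.names = colnames(exprs))
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = exprs), colData = cd,
    metadata = list(scaleTag = scaleTag))
  methods::new("IFNCohort", se)
}

#' @rdname scaleTag
#' @export
setGeneric("scaleTag", function(x) standardGeneric("scaleTag"))

#' @rdname scaleTag
#' @export
setGeneric("scaleTag<-", function(x, value) standardGeneric("scaleTag<-"))

#' Get or set the expression scale tag
#'
#' Every cohort carries a tag stating whether its values are raw linear
#' intensities or log2 units. Statistical operations refuse linear input.
#'
#' @param x an [IFNCohort-class].
#' @param value `"linear"` or `"log2"`.
#' @return the tag, or the modified object.
#' @export
setMethod("scaleTag", "IFNCohort", function(x) {
  S4Vectors::metadata(x)$scaleTag
})

#' @rdname scaleTag
#' @export
setReplaceMethod("scaleTag", "IFNCohort", function(x, value) {
  stopifnot(value %in% c("linear", "log2"))
  S4Vectors::metadata(x)$scaleTag <- value
  methods::validObject(x)
  x
})

#' @rdname exprs
#' @export
setGeneric("exprs", function(x) standardGeneric("exprs"))

#' Extract the expression matrix of a cohort
#'
#' @param x an [IFNCohort-class].
#' @return the genes x patients numeric matrix.
#' @export
setMethod("exprs", "IFNCohort", function(x) {
  SummarizedExperiment::assay(x, "exprs")
})

#' @rdname clinicalTable
#' @export
setGeneric("clinicalTable", function(x) standardGeneric("clinicalTable"))

#' Extract the clinical table of a cohort
#'
#' @param x an [IFNCohort-class].
#' @return a data.frame with a leading `patient_id` column.
#' @export
setMethod("clinicalTable", "IFNCohort", function(x) {
  cd <- as.data.frame(SummarizedExperiment::colData(x))
  cbind(patient_id = colnames(x), cd, stringsAsFactors = FALSE,
        row.names = NULL)
})

#' Binary non-response labels of a cohort
#'
#' @param x an [IFNCohort-class] whose clinical data carry the requested
#'   criterion.
#' @param criterion `"delta_das28"` (non-response = DAS28 improvement
#'   < 1.2, column `nonresponse_das28`) or `"eular"` (non-response = EULAR
#'   category `"none"`; good and moderate responders form the negative
#'   class).
#' @return named integer vector of 0/1 labels (1 = non-responder).
#' @export
responseLabels <- function(x, criterion = c("delta_das28", "eular")) {
  criterion <- match.arg(criterion)
  cd <- SummarizedExperiment::colData(x)
  if (criterion == "delta_das28") {
    if (!"nonresponse_das28" %in% names(cd))
      stop("cohort has no 'nonresponse_das28' clinical column")
    lab <- as.integer(cd$nonresponse_das28)
  } else {
    if (!"eular_category" %in% names(cd))
      stop("cohort has no 'eular_category' clinical column")
    lab <- as.integer(cd$eular_category == "none")
  }
  stats::setNames(lab, colnames(x))
}

.assertLog2 <- function(x, what = "this operation") {
  if (!identical(scaleTag(x), "log2"))
    stop(what, " requires log2-scale expression; call log2Transform() first")
  invisible(TRUE)
}

.checkBinaryLabels <- function(labels, n) {
  labels <- as.integer(labels)
  if (length(labels) != n)
    stop("labels must have one entry per patient")
  if (!all(labels %in% c(0L, 1L)))
    stop("labels must be binary 0/1")
  if (length(unique(labels)) < 2L)
    stop("both label classes must be non-empty")
  labels
}

setMethod("show", "IFNCohort", function(object) {
  cat("IFNCohort:", nrow(object), "genes x", ncol(object), "patients",
      sprintf("[%s scale]\n", scaleTag(object)))
  cd <- SummarizedExperiment::colData(object)
  if (ncol(cd))
    cat("clinical columns:", paste(names(cd), collapse = ", "), "\n")
})

setMethod("show", "GeneSet", function(object) {
  cat(sprintf("GeneSet '%s' (%d genes): %s\n", object@name,
              length(object@members),
              paste(object@members, collapse = ", ")))
})

setMethod("show", "ScoreVector", function(object) {
  cat(sprintf("IFN ScoreVector: %d patients, %d-gene set%s\n",
              length(object@scores), length(object@geneSet),
              if (object@centered) " (median-centered)" else ""))
  print(head(object@scores, 6))
})

setMethod("show", "RocResult", function(object) {
  cat(sprintf(
    "ROC (positive class: %s): AUC = %.4f  [%d positives, %d negatives]\n",
    object@positiveClass, object@auc, object@nPos, object@nNeg))
})

setMethod("show", "FilterResult", function(object) {
  cat(sprintf(
    "Fold-change filter (fold >= %g in >= %d patients): %d of %d genes pass\n",
    object@fold, object@minPatients, length(object@passing),
    length(object@exceedCount)))
})

setMethod("show", "SamResult", function(object) {
  cat(sprintf(
    "SAM two-class (%d permutations%s, s0 = %.4g): %d genes at q <= %g\n",
    object@nPermutations, if (object@exact) ", exact" else "",
    object@s0, length(object@called), object@fdrThreshold))
})

setMethod("show", "ClusterAssignment", function(object) {
  cat(sprintf("Hierarchical clustering of %d genes into k = %d clusters\n",
              length(object@clusters), object@k))
  print(table(cluster = object@clusters))
})

setMethod("show", "SubsetSearchResult", function(object) {
  cat(sprintf(
    "Exhaustive subset search: %d subsets, best AUC = %.4f (%d tied)\n",
    nrow(object@table), object@bestAuc, length(object@bestSubsets)))
  for (s in object@bestSubsets)
    cat("  ", paste(s, collapse = "+"), "\n")
})

setMethod("show", "LogisticFit", function(object) {
  cat(sprintf("Logistic fit (n = %d, Nagelkerke R2 = %.3f)\n",
              object@n, object@nagelkerkeR2))
  tab <- object@table
  tab$or <- sprintf("%.3f", tab$or)
  tab$p <- format.pval(tab$p, digits = 3)
  print(tab[, c("term", "or", "ciLow", "ciHigh", "p")], row.names = FALSE)
})
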