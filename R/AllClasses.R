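#' @import methods
#' @import stats
#' @importFrom utils combn read.delim write.table head
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors metadata DataFrame
NULL

#' IFNCohort: expression matrix plus clinical annotation
#'
#' `IFNCohort` extends [SummarizedExperiment::SummarizedExperiment] and is the
#' central container of the package: a genes x patients expression matrix in
#' the single assay `"exprs"`, per-patient clinical variables in `colData`,
#' and a scale tag (`"linear"` or `"log2"`) in the object metadata. All
#' statistical operations require `scaleTag(x) == "log2"`.
#'
#' Clinical columns used downstream (all optional at construction):
#' `delta_das28` (change in the 28-joint disease activity score; negative
#' values are improvement), `nonresponse_das28` (0/1; 1 iff the DAS28
#' improvement is < 1.2), `eular_category` (`"good"`, `"moderate"`,
#' `"none"`), and covariates such as `seropositivity`,
#' `n_prior_tnf_blockers`, `lipid_lowering`, `erosions`, `prednisolone`,
#' `methotrexate`, `age`, `gender`.
#'
#' @slot .. inherits all slots from `SummarizedExperiment`.
#' @seealso [IFNCohort()] constructor, [scaleTag()], [exprs()]
#' @export
setClass("IFNCohort", contains = "SummarizedExperiment")

setValidity("IFNCohort", function(object) {
  msg <- character()
  m <- SummarizedExperiment::assay(object, "exprs")
  if ((nrow(m) && is.null(rownames(m))) || anyDuplicated(rownames(m)))
    msg <- c(msg, "gene identifiers (rownames) must be present and unique")
  if ((ncol(m) && is.null(colnames(m))) || anyDuplicated(colnames(m)))
    msg <- c(msg, "patient identifiers (colnames) must be present and unique")
  if (!all(is.finite(m)))
    msg <- c(msg, "expression values must all be finite")
  tag <- S4Vectors::metadata(object)$scaleTag
  if (is.null(tag) || !tag %in% c("linear", "log2"))
    msg <- c(msg, "scaleTag must be 'linear' or 'log2'")
  if (length(msg)) msg else TRUE
})

#' An ordered set of gene identifiers
#'
#' A named, ordered, duplicate-free collection of gene identifiers, typically
#' the eight type I interferon response genes (IRGs) of the rituximab
#' response signature. See [irgPanel()] for the shipped defaults.
#'
#' @slot name single character label.
#' @slot members character vector of unique gene identifiers.
#' @export
setClass("GeneSet",
  representation(name = "character", members = "character"))

setValidity("GeneSet", function(object) {
  msg <- character()
  if (length(object@members) == 0L) msg <- c(msg, "members must be non-empty")
  if (anyDuplicated(object@members)) msg <- c(msg, "members must be unique")
  if (length(object@name) != 1L) msg <- c(msg, "name must be a single string")
  if (length(msg)) msg else TRUE
})

#' Per-patient composite IFN score
#'
#' One finite score per patient (mean log2 expression over a gene set),
#' with provenance: the gene set used and whether per-cohort median centering
#' was applied before scoring.
#'
#' @slot scores named numeric, one value per patient.
#' @slot geneSet character vector of the gene identifiers averaged.
#' @slot centered logical flag.
#' @export
setClass("ScoreVector",
  representation(scores = "numeric", geneSet = "character",
                 centered = "logical"))

setValidity("ScoreVector", function(object) {
  msg <- character()
  if (is.null(names(object@scores)) || anyDuplicated(names(object@scores)))
    msg <- c(msg, "scores must be named by unique patient identifiers")
  if (!all(is.finite(object@scores)))
    msg <- c(msg, "scores must all be finite")
  if (length(msg)) msg else TRUE
})

#' Fold-change filter result
#'
#' @slot passing gene identifiers passing the filter.
#' @slot maxAbsDeviation named per-gene maximum absolute log2 deviation from
#'   the gene median.
#' @slot exceedCount named per-gene number of patients whose deviation is at
#'   least `log2(fold)`.
#' @slot fold,minPatients the filter parameters used.
#' @export
setClass("FilterResult",
  representation(passing = "character", maxAbsDeviation = "numeric",
                 exceedCount = "integer", fold = "numeric",
                 minPatients = "integer"))

#' SAM two-class result
#'
#' @slot d named per-gene SAM d statistic.
#' @slot q named per-gene permutation q value in `[0, 1]`.
#' @slot called genes with `q <= fdrThreshold`.
#' @slot nPermutations number of label permutations used.
#' @slot s0 the fudge constant added to each gene's standard error.
#' @slot fdrThreshold the FDR used for calling.
#' @slot exact TRUE if all distinct label permutations were enumerated.
#' @export
setClass("SamResult",
  representation(d = "numeric", q = "numeric", called = "character",
                 nPermutations = "integer", s0 = "numeric",
                 fdrThreshold = "numeric", exact = "logical"))

#' Hierarchical cluster assignment of genes
#'
#' @slot clusters named integer vector: gene identifier -> cluster index in
#'   `1..k`.
#' @slot tree the underlying [stats::hclust] object (merge list + heights).
#' @slot k number of clusters the tree was cut to.
#' @export
setClass("ClusterAssignment",
  representation(clusters = "integer", tree = "ANY", k = "integer"))

setValidity("ClusterAssignment", function(object) {
  msg <- character()
  if (is.null(names(object@clusters)))
    msg <- c(msg, "clusters must be named by gene identifiers")
  if (!all(object@clusters %in% seq_len(object@k)))
    msg <- c(msg, "cluster indices must lie in 1..k")
  if (inherits(object@tree, "hclust") && is.unsorted(object@tree$height))
    msg <- c(msg, "merge heights must be non-decreasing")
  if (length(msg)) msg else TRUE
})

#' Empirical ROC curve with integrated AUC
#'
#' The positive class is always non-response. Curve points run from (0, 0)
#' to (1, 1) in (1 - specificity, sensitivity) coordinates; the AUC is the
#' trapezoidal integral of the empirical curve, which equals the
#' Mann-Whitney probability with half credit for ties.
#'
#' @slot thresholds score thresholds (a score >= threshold is called
#'   positive); `Inf` gives the (0, 0) point.
#' @slot sensitivity,fpr curve coordinates per threshold.
#' @slot auc area under the curve in `[0, 1]`.
#' @slot positiveClass fixed to `"non-response"`.
#' @slot nPos,nNeg class sizes.
#' @export
setClass("RocResult",
  representation(thresholds = "numeric", sensitivity = "numeric",
                 fpr = "numeric", auc = "numeric", positiveClass = "character",
                 nPos = "integer", nNeg = "integer"))

setValidity("RocResult", function(object) {
  msg <- character()
  if (object@auc < 0 || object@auc > 1) msg <- c(msg, "auc must be in [0,1]")
  if (is.unsorted(object@sensitivity) || is.unsorted(object@fpr))
    msg <- c(msg, "curve points must be monotone non-decreasing")
  if (length(msg)) msg else TRUE
})

#' Exhaustive gene-subset AUC search result
#'
#' @slot table data.frame with one row per non-empty subset (columns
#'   `members`, `size`, `auc`), sorted by AUC descending.
#' @slot bestAuc the maximal AUC.
#' @slot bestSubsets list of character vectors: every subset tied at
#'   `bestAuc`.
#' @export
setClass("SubsetSearchResult",
  representation(table = "data.frame", bestAuc = "numeric",
                 bestSubsets = "list"))

#' Logistic regression fit with odds ratios and Nagelkerke R-squared
#'
#' @slot table data.frame with one row per predictor: `term`, `estimate`
#'   (log odds), `se`, `or`, `ciLow`, `ciHigh` (95% Wald), `p`.
#' @slot logLik0,logLik1 log likelihood of the intercept-only and fitted
#'   model.
#' @slot nagelkerkeR2 rescaled likelihood-ratio pseudo R-squared.
#' @slot n number of observations used.
#' @export
setClass("LogisticFit",
  representation(table = "data.frame", logLik0 = "numeric",
                 logLik1 = "numeric", nagelkerkeR2 = "numeric",
                 n = "integer"))

setValidity("LogisticFit", function(object) {
  msg <- character()
  if (object@nagelkerkeR2 < -1e-8 || object@nagelkerkeR2 > 1 + 1e-8)
    msg <- c(msg, "nagelkerkeR2 must be in [0,1]")
  tab <- object@table
  if (nrow(tab) && !all(tab$ciLow <= tab$or & tab$or <= tab$ciHigh))
    msg <- c(msg, "confidence bounds must bracket the odds ratio")
  if (length(msg)) msg else TRUE
})
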