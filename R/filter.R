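#' @rdname foldChangeFilter
#' @export
setGeneric("foldChangeFilter",
  function(x, fold = 2, minPatients = 3L) standardGeneric("foldChangeFilter"))

#' Fold-change candidate gene filter
#'
#' Selects genes whose expression differs at least `fold`-fold from the
#' gene's median expression level in at least `minPatients` patients. On the
#' log2 scale a patient "exceeds" for a gene iff
#' `|x - median(gene row)| >= log2(fold)`; a deviation exactly equal to the
#' threshold counts as exceeding ("at least" fold change). The published
#' signature derivation used `fold = 2`, `minPatients = 3` on 14 arrays,
#' yielding 124 candidate genes.
#'
#' @param x a log2-scale [IFNCohort-class].
#' @param fold linear fold-change threshold (> 1).
#' @param minPatients minimum number of exceeding patients.
#' @return a [FilterResult-class].
#' @examples
#' cohort <- simulateCohort(simulationConfig(nPatients = 14, nGenes = 100))
#' foldChangeFilter(cohort)
#' @export
setMethod("foldChangeFilter", "IFNCohort", function(x, fold = 2,
                                                    minPatients = 3L) {
  .assertLog2(x, "foldChangeFilter()")
  stopifnot(fold > 1)
  minPatients <- as.integer(minPatients)
  m <- exprs(x)
  if (minPatients > ncol(m))
    stop("minPatients (", minPatients, ") exceeds the number of patients (",
         ncol(m), ")")
  med <- apply(m, 1L, stats::median)
  dev <- abs(m - med)
  thr <- log2(fold)
  cnt <- as.integer(rowSums(dev >= thr))
  names(cnt) <- rownames(m)
  methods::new("FilterResult",
    passing = rownames(m)[cnt >= minPatients],
    maxAbsDeviation = apply(dev, 1L, max),
    exceedCount = cnt, fold = fold, minPatients = minPatients)
})

#' Write a filter result as tab-separated text
#'
#' @param x a [FilterResult-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeFilterResult <- function(x, path) {
  df <- data.frame(gene_id = names(x@exceedCount),
                   max_abs_log2_deviation = unname(x@maxAbsDeviation),
                   exceed_count = unname(x@exceedCount),
                   pass = as.integer(names(x@exceedCount) %in% x@passing))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
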