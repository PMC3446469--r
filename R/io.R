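#' Read an expression matrix
#'
#' Reads a genes x patients expression table from tab-separated text or from
#' the GEO series-matrix dialect (the numeric block between the
#' `!series_matrix_table_begin` and `!series_matrix_table_end` markers).
#'
#' @param path file to read.
#' @param format `"tsv"` (header row: `gene_id` followed by patient
#'   identifiers) or `"geo_series_matrix"`.
#' @param scaleTag scale of the stored values; GEO series matrices of
#'   summarized bead arrays are typically already log2.
#' @return an [IFNCohort-class] with no clinical data.
#' @export
readExpression <- function(path, format = c("tsv", "geo_series_matrix"),
                           scaleTag = c("log2", "linear")) {
  format <- match.arg(format)
  scaleTag <- match.arg(scaleTag)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") {
    df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    genes <- as.character(df[[1L]])
    m <- as.matrix(df[, -1L, drop = FALSE])
    offset <- 1L   # header line precedes data rows
  } else {
    lines <- readLines(path)
    beg <- grep("^!series_matrix_table_begin", lines)
    end <- grep("^!series_matrix_table_end", lines)
    if (length(beg) != 1L)
      stop("parse error: missing '!series_matrix_table_begin' marker in ",
           path)
    if (length(end) != 1L || end <= beg + 1L)
      stop("parse error: missing or misplaced '!series_matrix_table_end' ",
           "marker (line ", if (length(end)) end else NA, ")")
    block <- lines[(beg + 1L):(end - 1L)]
    con <- textConnection(block)
    on.exit(close(con))
    df <- read.delim(con, check.names = FALSE, stringsAsFactors = FALSE)
    genes <- gsub('^"|"$', "", as.character(df[[1L]]))
    m <- as.matrix(df[, -1L, drop = FALSE])
    offset <- beg + 1L
  }
  if (anyDuplicated(genes)) {
    dup <- genes[duplicated(genes)][1L]
    stop("parse error: duplicated gene identifier '", dup, "' (line ",
         which(genes == dup)[2L] + offset, ")")
  }
  if (!is.numeric(m)) {
    badRow <- which(apply(m, 1L, function(r) anyNA(suppressWarnings(
      as.numeric(r)))))[1L]
    stop("parse error: non-numeric expression value for gene '",
         genes[badRow], "' (line ", badRow + offset, ")")
  }
  rownames(m) <- genes
  colnames(m) <- gsub('^"|"$', "", colnames(m))
  IFNCohort(m, scaleTag = scaleTag)
}

#' Write an expression matrix as tab-separated text
#'
#' @param x an [IFNCohort-class].
#' @param path output file; header row is `gene_id` followed by the patient
#'   identifiers.
#' @return `path`, invisibly.
#' @export
writeExpression <- function(x, path) {
  m <- exprs(x)
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a clinical table
#'
#' One row per patient, tab-separated, with a `patient_id` column.
#'
#' @param path file to read or write.
#' @return `readClinical`: a data.frame.
#' @export
readClinical <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"patient_id" %in% names(df))
    stop("clinical table must have a 'patient_id' column")
  if (anyDuplicated(df$patient_id))
    stop("duplicated patient identifier: ",
         df$patient_id[duplicated(df$patient_id)][1L])
  df
}

#' @rdname readClinical
#' @param clinical data.frame to write.
#' @export
writeClinical <- function(clinical, path) {
  write.table(clinical, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname log2Transform
#' @export
setGeneric("log2Transform", function(x) standardGeneric("log2Transform"))

#' Log2-transform a linear-scale cohort
#'
#' @param x an [IFNCohort-class] with `scaleTag == "linear"` and strictly
#'   positive values.
#' @return the cohort on the log2 scale.
#' @export
setMethod("log2Transform", "IFNCohort", function(x) {
  if (!identical(scaleTag(x), "linear"))
    stop("log2Transform() expects a linear-scale cohort")
  m <- exprs(x)
  if (any(m <= 0)) {
    idx <- which(m <= 0, arr.ind = TRUE)[1L, ]
    stop("non-positive expression value for gene '", rownames(m)[idx[1L]],
         "', patient '", colnames(m)[idx[2L]], "'")
  }
  SummarizedExperiment::assay(x, "exprs") <- log2(m)
  scaleTag(x) <- "log2"
  x
})

#' @rdname quantileNormalize
#' @export
setGeneric("quantileNormalize", function(x) standardGeneric("quantileNormalize"))

#' Quantile-normalize a cohort
#'
#' Makes every patient's value distribution identical: rank r in each column
#' is replaced by the mean of the rank-r values across columns, preserving
#' within-column ranks; ties within a column receive the mean of their rank
#' span. Delegates to [limma::normalizeQuantiles()] with `ties = TRUE`.
#'
#' @param x a log2-scale [IFNCohort-class] with at least one gene and
#'   patient.
#' @return the normalized cohort.
#' @export
setMethod("quantileNormalize", "IFNCohort", function(x) {
  .assertLog2(x, "quantileNormalize()")
  m <- exprs(x)
  if (nrow(m) == 0L || ncol(m) == 0L)
    stop("cannot quantile-normalize an empty matrix")
  norm <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(norm) <- dimnames(m)
  SummarizedExperiment::assay(x, "exprs") <- norm
  x
})

#' @rdname medianCenterGenes
#' @export
setGeneric("medianCenterGenes", function(x) standardGeneric("medianCenterGenes"))

#' Median-center every gene row
#'
#' Subtracts from each gene its median across patients (midpoint of the two
#' central values for even patient counts), so that each row has median 0.
#' This is the per-cohort centering applied before combining cohorts
#' measured on different platforms.
#'
#' @param x a log2-scale [IFNCohort-class].
#' @return the centered cohort.
#' @export
setMethod("medianCenterGenes", "IFNCohort", function(x) {
  .assertLog2(x, "medianCenterGenes()")
  m <- exprs(x)
  med <- apply(m, 1L, stats::median)
  SummarizedExperiment::assay(x, "exprs") <- m - med
  x
})
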