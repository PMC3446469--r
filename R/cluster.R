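#' @rdname hierarchicalCluster
#' @export
setGeneric("hierarchicalCluster",
  function(x, k, distance = c("pearson", "euclidean"),
           linkage = "average") standardGeneric("hierarchicalCluster"))

#' Hierarchical clustering of gene rows
#'
#' Agglomerative clustering of genes with distance 1 - Pearson correlation
#' (across patients) and average linkage — the canonical configuration of
#' the Eisen-style clustering used to group co-regulated genes — cut to
#' exactly `k` clusters. Both distance and linkage are exposed as options.
#'
#' @param x a log2-scale [IFNCohort-class] with at least `k` genes.
#' @param k number of clusters to cut the tree into (the published analysis
#'   used 5).
#' @param distance `"pearson"` (1 - centered Pearson correlation) or
#'   `"euclidean"`.
#' @param linkage any method accepted by [stats::hclust()].
#' @return a [ClusterAssignment-class].
#' @examples
#' cohort <- simulateCohort(simulationConfig(nPatients = 30, nGenes = 40))
#' hierarchicalCluster(cohort, k = 3)
#' @export
setMethod("hierarchicalCluster", "IFNCohort",
  function(x, k, distance = c("pearson", "euclidean"),
           linkage = "average") {
  .assertLog2(x, "hierarchicalCluster()")
  distance <- match.arg(distance)
  m <- exprs(x)
  k <- as.integer(k)
  if (nrow(m) < k) stop("need at least k = ", k, " genes, have ", nrow(m))
  if (distance == "pearson") {
    sds <- apply(m, 1L, stats::sd)
    if (any(sds == 0))
      stop("constant gene row (undefined correlation): ",
           paste(rownames(m)[sds == 0], collapse = ", "))
    d <- stats::as.dist(1 - stats::cor(t(m)))
  } else {
    d <- stats::dist(m)
  }
  tree <- stats::hclust(d, method = linkage)
  cl <- stats::cutree(tree, k = k)
  methods::new("ClusterAssignment", clusters = cl, tree = tree, k = k)
})

#' Associate per-cluster average expression with clinical response
#'
#' For each cluster, averages the member genes per patient and compares the
#' averages between the two label groups with the unpaired equal-variance
#' Student t test.
#'
#' @param x a log2-scale [IFNCohort-class] containing the clustered genes.
#' @param assignment a [ClusterAssignment-class] from
#'   [hierarchicalCluster()].
#' @param labels binary 0/1 non-response labels, one per patient.
#' @return a data.frame with one row per cluster: `cluster`, `n_genes`,
#'   `mean_label0`, `mean_label1`, `t`, `p`. The per-patient cluster means
#'   are attached as the `"clusterMeans"` attribute (clusters x patients).
#' @export
clusterResponseAssociation <- function(x, assignment, labels) {
  .assertLog2(x, "clusterResponseAssociation()")
  m <- exprs(x)
  labels <- .checkBinaryLabels(labels, ncol(m))
  cl <- assignment@clusters
  missing <- setdiff(names(cl), rownames(m))
  if (length(missing))
    stop("clustered genes absent from the cohort: ",
         paste(missing, collapse = ", "))
  means <- t(vapply(split(names(cl), cl), function(genes) {
    colMeans(m[genes, , drop = FALSE])
  }, numeric(ncol(m))))
  rownames(means) <- paste0("cluster", sort(unique(cl)))
  res <- do.call(rbind, lapply(seq_len(nrow(means)), function(i) {
    v <- means[i, ]
    tt <- stats::t.test(v[labels == 1L], v[labels == 0L],
                        var.equal = TRUE)
    data.frame(cluster = i, n_genes = sum(cl == i),
               mean_label0 = mean(v[labels == 0L]),
               mean_label1 = mean(v[labels == 1L]),
               t = unname(tt$statistic), p = tt$p.value)
  }))
  attr(res, "clusterMeans") <- means
  res
}

#' Write cluster assignments as tab-separated text
#'
#' @param assignment a [ClusterAssignment-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeClusterAssignment <- function(assignment, path) {
  df <- data.frame(gene_id = names(assignment@clusters),
                   cluster = unname(assignment@clusters))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a clustered expression heatmap ordering
#'
#' Writes the expression submatrix of the clustered genes, genes ordered by
#' the dendrogram and patients ordered by increasing ΔDAS28 (most improved
#' first), as tab-separated text suitable for generic heatmap tools.
#'
#' @param x a log2-scale [IFNCohort-class] whose clinical table has
#'   `delta_das28`.
#' @param assignment a [ClusterAssignment-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeHeatmapMatrix <- function(x, assignment, path) {
  m <- exprs(x)
  cd <- SummarizedExperiment::colData(x)
  geneOrder <- assignment@tree$labels[assignment@tree$order]
  patOrder <- if ("delta_das28" %in% names(cd))
    order(cd$delta_das28) else seq_len(ncol(m))
  sub <- m[geneOrder, patOrder, drop = FALSE]
  df <- data.frame(gene_id = rownames(sub), sub, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
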