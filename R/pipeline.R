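#' Build a pipeline run configuration
#'
#' A run takes its cohort either from files (`expressionPath` +
#' `clinicalPath`) or from a [SimulationConfig-class] — exactly one of the
#' two.
#'
#' @param expressionPath,clinicalPath TSV inputs (see [readExpression()],
#'   [readClinical()]).
#' @param simulation a [SimulationConfig-class] for synthetic runs.
#' @param fold,minPatients fold-change filter parameters.
#' @param k number of gene clusters.
#' @param geneSetPath plain-text gene set used by the validation stage;
#'   defaults to the shipped eight-gene panel.
#' @param responseCriterion `"delta_das28"` or `"eular"` (primary label).
#' @param subsetSearch run the exhaustive subset search in validation.
#' @param quantileNormalize apply quantile normalization before analysis.
#' @param alpha per-family significance level for cluster association
#'   (Bonferroni-corrected across the k clusters).
#' @param seed global seed; per-stage seeds are derived from it.
#' @param outDir output directory (created if absent).
#' @return a validated `ifnscoreRunConfig` list.
#' @export
runConfig <- function(expressionPath = NULL, clinicalPath = NULL,
                      simulation = NULL, fold = 2, minPatients = 3L,
                      k = 5L, geneSetPath = NULL,
                      responseCriterion = c("delta_das28", "eular"),
                      subsetSearch = TRUE, quantileNormalize = TRUE,
                      alpha = 0.05, seed = 1L, outDir = tempfile("ifnrun")) {
  responseCriterion <- match.arg(responseCriterion)
  fromFiles <- !is.null(expressionPath)
  if (fromFiles == !is.null(simulation))
    stop("provide exactly one of {expressionPath + clinicalPath, simulation}")
  if (fromFiles && is.null(clinicalPath))
    stop("clinicalPath is required with expressionPath")
  if (!is.null(simulation)) methods::validObject(simulation)
  cfg <- list(expressionPath = expressionPath, clinicalPath = clinicalPath,
              simulation = simulation, fold = fold,
              minPatients = as.integer(minPatients), k = as.integer(k),
              geneSetPath = geneSetPath,
              responseCriterion = responseCriterion,
              subsetSearch = isTRUE(subsetSearch),
              quantileNormalize = isTRUE(quantileNormalize),
              alpha = alpha, seed = as.integer(seed), outDir = outDir)
  class(cfg) <- "ifnscoreRunConfig"
  cfg
}

#' Read a run configuration from a YAML / key-value file
#'
#' Flat YAML mapping of the [runConfig()] arguments; simulation parameters
#' are given under a `simulation:` block with [simulationConfig()] argument
#' names.
#'
#' @param path YAML file.
#' @return an `ifnscoreRunConfig` list.
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$simulation))
    y$simulation <- do.call(simulationConfig, y$simulation)
  do.call(runConfig, y)
}

# deterministic fan-out of the global seed into per-stage seeds (kept below
# .Machine$integer.max)
.stageSeed <- function(seed, stage) {
  (seed * 1009L + match(stage, c("simulate", "sam", "bootstrap"))) %% 2147483587L
}

.loadCohort <- function(cfg) {
  if (!is.null(cfg$simulation)) {
    sim <- cfg$simulation
    sim@seed <- as.integer(.stageSeed(cfg$seed, "simulate"))
    simulateCohort(sim)
  } else {
    x <- readExpression(cfg$expressionPath, format = "tsv")
    clin <- readClinical(cfg$clinicalPath)
    IFNCohort(exprs(x), clinical = clin, scaleTag = "log2")
  }
}

.writeManifest <- function(cfg, outDir, stage, extras = list()) {
  manifest <- c(list(stage = stage,
                     timestampless = TRUE,   # byte-identical reruns
                     fold = cfg$fold, minPatients = cfg$minPatients,
                     k = cfg$k, responseCriterion = cfg$responseCriterion,
                     subsetSearch = cfg$subsetSearch,
                     quantileNormalize = cfg$quantileNormalize,
                     alpha = cfg$alpha, seed = cfg$seed),
                if (!is.null(cfg$simulation))
                  list(simulation = list(
                    nPatients = cfg$simulation@nPatients,
                    nGenes = cfg$simulation@nGenes,
                    propIfnHigh = cfg$simulation@propIfnHigh,
                    moduleShift = cfg$simulation@moduleShift,
                    moduleRho = cfg$simulation@moduleRho,
                    noiseSd = cfg$simulation@noiseSd,
                    pNonresponseGivenHigh = cfg$simulation@pNonresponseGivenHigh,
                    pNonresponseGivenLow = cfg$simulation@pNonresponseGivenLow,
                    seed = .stageSeed(cfg$seed, "simulate")))
                else list(expressionPath = cfg$expressionPath,
                          clinicalPath = cfg$clinicalPath),
                extras)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Run the discovery stage
#'
#' Filter -> cluster -> cluster/response association -> IFN score, on one
#' cohort: selects candidate genes by the fold-change rule, runs the SAM
#' two-class analysis, clusters the candidates, tests each cluster's average
#' expression against the response label (Bonferroni-corrected across
#' clusters), derives the discovery gene set from the most significant
#' cluster, and scores all patients. All artifacts land in `cfg$outDir` as
#' tab-separated text plus a `manifest.json` recording every parameter and
#' seed; identical configurations reproduce byte-identical outputs.
#'
#' @param cfg an `ifnscoreRunConfig` from [runConfig()].
#' @return (invisibly) a list with the in-memory stage results:
#'   `cohort`, `filter`, `sam`, `clustering`, `association`,
#'   `significantClusters`, `discoveryGeneSet`, `score`, `scoreTest`.
#' @export
runDiscovery <- function(cfg) {
  stopifnot(inherits(cfg, "ifnscoreRunConfig"))
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  step <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("discovery stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  cohort <- step("load", .loadCohort(cfg))
  if (cfg$quantileNormalize)
    cohort <- step("normalize", quantileNormalize(cohort))
  labels <- step("labels", responseLabels(cohort, cfg$responseCriterion))

  filt <- step("filter",
               foldChangeFilter(cohort, cfg$fold, cfg$minPatients))
  writeFilterResult(filt, file.path(cfg$outDir, "filter_result.tsv"))

  sam <- step("sam", samTwoClass(cohort, labels,
                                 seed = .stageSeed(cfg$seed, "sam")))
  writeSamResult(sam, file.path(cfg$outDir, "sam_result.tsv"))

  sub <- cohort[filt@passing, ]
  clu <- step("cluster", hierarchicalCluster(sub, k = cfg$k))
  writeClusterAssignment(clu, file.path(cfg$outDir,
                                        "cluster_assignment.tsv"))
  writeHeatmapMatrix(sub, clu, file.path(cfg$outDir, "heatmap_matrix.tsv"))

  assoc <- step("associate", clusterResponseAssociation(sub, clu, labels))
  write.table(assoc, file.path(cfg$outDir, "cluster_association.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  sig <- assoc$cluster[assoc$p < cfg$alpha / cfg$k]

  bestCluster <- assoc$cluster[which.min(assoc$p)]
  gsDisc <- geneSet(names(clu@clusters)[clu@clusters == bestCluster],
                    name = "discovery cluster")
  writeGeneSet(gsDisc, file.path(cfg$outDir, "discovery_gene_set.txt"))

  score <- step("score", computeIfnScore(cohort, gsDisc))
  writeScoreVector(score, file.path(cfg$outDir, "ifn_score.tsv"))
  scoreTest <- step("scoreTest", scoreGroupTest(score, labels))

  .writeManifest(cfg, cfg$outDir, "discovery",
                 list(nFilteredGenes = length(filt@passing),
                      nSamCalled = length(sam@called),
                      significantClusters = as.list(sig)))
  invisible(list(cohort = cohort, filter = filt, sam = sam,
                 clustering = clu, association = assoc,
                 significantClusters = sig, discoveryGeneSet = gsDisc,
                 score = score, scoreTest = scoreTest))
}

#' Run the validation stage
#'
#' Scores an independent cohort with a gene set frozen beforehand (the gene
#' set file is read before any clinical label is touched), builds ROC curves
#' under both response criteria, optionally runs the exhaustive subset
#' search, reports the fixed-specificity cutoff, and screens covariates with
#' univariate/bivariate logistic models. Artifacts are written to
#' `cfg$outDir`.
#'
#' @param cfg an `ifnscoreRunConfig`; `geneSetPath` defaults to the shipped
#'   eight-gene panel.
#' @return (invisibly) a list with `cohort`, `geneSet`, `score`, `roc`
#'   (per criterion), `cutoff`, `subsets` (per criterion, if enabled),
#'   `screen`.
#' @export
runValidation <- function(cfg) {
  stopifnot(inherits(cfg, "ifnscoreRunConfig"))
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  step <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("validation stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  # the gene set is fixed before the cohort (and its labels) is loaded
  gs <- step("geneSet", if (is.null(cfg$geneSetPath)) irgPanel()
             else readGeneSet(cfg$geneSetPath, name = "frozen gene set"))

  cohort <- step("load", .loadCohort(cfg))
  if (identical(scaleTag(cohort), "linear"))
    cohort <- step("log2", log2Transform(cohort))
  score <- step("score", computeIfnScore(cohort, gs))
  writeScoreVector(score, file.path(cfg$outDir, "validation_score.tsv"))

  cd <- SummarizedExperiment::colData(cohort)
  criteria <- c("delta_das28",
                if ("eular_category" %in% names(cd)) "eular")
  roc <- list(); subsets <- list()
  for (cr in criteria) {
    lab <- step("labels", responseLabels(cohort, cr))
    roc[[cr]] <- step("roc", rocCurve(score, lab))
    writeRocResult(roc[[cr]], file.path(cfg$outDir,
                                        paste0("roc_", cr, ".tsv")))
    if (cfg$subsetSearch) {
      subsets[[cr]] <- step("subsetSearch",
                            exhaustiveSubsetSearch(cohort, gs, lab))
      writeSubsetSearchResult(subsets[[cr]], file.path(
        cfg$outDir, paste0("subset_search_", cr, ".tsv")))
    }
  }
  primary <- roc[[cfg$responseCriterion]]
  cutoff <- step("cutoff", cutoffAtSpecificity(primary, 1))
  write.table(data.frame(criterion = cfg$responseCriterion,
                         threshold = cutoff$threshold,
                         sensitivity = cutoff$sensitivity,
                         specificity = cutoff$specificity),
              file.path(cfg$outDir, "cutoff_table.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  screen <- step("covariateScreen",
                 covariateScreen(clinicalTable(cohort), score))
  writeAssociationReport(screen, file.path(cfg$outDir,
                                           "association_report.tsv"))

  .writeManifest(cfg, cfg$outDir, "validation",
                 list(geneSet = as.list(gs@members),
                      auc = lapply(roc, function(r) r@auc)))
  invisible(list(cohort = cohort, geneSet = gs, score = score, roc = roc,
                 cutoff = cutoff, subsets = subsets, screen = screen))
}
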