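#' Simulation configuration for synthetic rituximab-response cohorts
#'
#' Holds all parameters of the synthetic-cohort generator. The generator
#' embeds an 8-gene interferon-response module in a background of
#' independent noise genes: a per-patient latent "IFN-high" state elevates
#' all module genes by `moduleShift` log2 units, a shared per-patient latent
#' factor induces the module's mutual correlation, and the binary clinical
#' non-response label is drawn conditionally on the latent state.
#'
#' @slot nPatients,nGenes cohort size and number of background genes.
#' @slot irgNames the 8 module gene identifiers.
#' @slot propIfnHigh fraction of IFN-high patients in `[0, 1]`.
#' @slot moduleShift log2-unit elevation of the module in IFN-high patients.
#' @slot moduleRho latent-factor loading parameter in `[0, 1)`; within the
#'   IFN-high (or IFN-low) stratum the pairwise correlation of two module
#'   genes is exactly `moduleRho`.
#' @slot noiseSd residual standard deviation in log2 units (> 0).
#' @slot pNonresponseGivenHigh,pNonresponseGivenLow probability of clinical
#'   non-response given the latent state.
#' @slot seed integer RNG seed; identical configurations reproduce
#'   bit-identical cohorts.
#' @slot exactCounts if TRUE, exactly `round(nPatients * propIfnHigh)`
#'   patients are IFN-high (useful to realize fixed class sizes such as the
#'   9 responder / 17 non-responder validation design).
#' @slot eularDiscordance fraction of DAS28 non-responders whose EULAR
#'   category is nevertheless `"moderate"`, emulating the weaker EULAR
#'   association.
#' @seealso [simulationConfig()], [simulateCohort()]
#' @export
setClass("SimulationConfig",
  representation(nPatients = "integer", nGenes = "integer",
                 irgNames = "character", propIfnHigh = "numeric",
                 moduleShift = "numeric", moduleRho = "numeric",
                 noiseSd = "numeric", pNonresponseGivenHigh = "numeric",
                 pNonresponseGivenLow = "numeric", seed = "integer",
                 exactCounts = "logical", eularDiscordance = "numeric"))

setValidity("SimulationConfig", function(object) {
  bad <- function(field, why) sprintf("invalid '%s': %s", field, why)
  msg <- character()
  if (object@nPatients < 2L) msg <- c(msg, bad("nPatients", "must be >= 2"))
  if (object@nGenes < 0L) msg <- c(msg, bad("nGenes", "must be >= 0"))
  if (length(object@irgNames) != 8L || anyDuplicated(object@irgNames))
    msg <- c(msg, bad("irgNames", "must be exactly 8 unique identifiers"))
  if (object@propIfnHigh < 0 || object@propIfnHigh > 1)
    msg <- c(msg, bad("propIfnHigh", "must be in [0,1]"))
  if (object@moduleRho < 0 || object@moduleRho >= 1)
    msg <- c(msg, bad("moduleRho", "must be in [0,1)"))
  if (object@noiseSd <= 0) msg <- c(msg, bad("noiseSd", "must be > 0"))
  for (f in c("pNonresponseGivenHigh", "pNonresponseGivenLow")) {
    v <- methods::slot(object, f)
    if (v < 0 || v > 1) msg <- c(msg, bad(f, "must be in [0,1]"))
  }
  if (object@eularDiscordance < 0 || object@eularDiscordance > 1)
    msg <- c(msg, bad("eularDiscordance", "must be in [0,1]"))
  if (length(msg)) msg else TRUE
})

#' The eight interferon response genes of the signature
#' @keywords internal
.IRG8 <- c("LY6E", "HERC5", "IFI44L", "ISG15", "MxA", "MxB",
           "EPSTI1", "RSAD2")

#' Build a simulation configuration
#'
#' Defaults mirror the study conditions the signature was derived under:
#' 40 patients (14 test + 26 validation), ~20,000 background genes, half the
#' patients IFN-high, and module parameters (`moduleShift = 2`,
#' `noiseSd = 0.35`, `moduleRho = 0.2`) chosen so the implied pairwise
#' correlation of the module genes is about 0.91 (see
#' [impliedIrgCorrelation()]).
#'
#' @param nPatients,nGenes,irgNames,propIfnHigh,moduleShift,moduleRho,noiseSd
#'   see [SimulationConfig-class].
#' @param pNonresponseGivenHigh,pNonresponseGivenLow,seed,exactCounts,eularDiscordance
#'   see [SimulationConfig-class].
#' @return a validated [SimulationConfig-class].
#' @examples
#' cfg <- simulationConfig(nPatients = 20, nGenes = 50, seed = 7)
#' impliedIrgCorrelation(cfg)
#' @export
simulationConfig <- function(nPatients = 40, nGenes = 20000,
                             irgNames = .IRG8, propIfnHigh = 0.5,
                             moduleShift = 2, moduleRho = 0.2,
                             noiseSd = 0.35,
                             pNonresponseGivenHigh = 0.8,
                             pNonresponseGivenLow = 0.2,
                             seed = 1L, exactCounts = FALSE,
                             eularDiscordance = 0.15) {
  methods::new("SimulationConfig",
    nPatients = as.integer(nPatients), nGenes = as.integer(nGenes),
    irgNames = as.character(irgNames), propIfnHigh = propIfnHigh,
    moduleShift = moduleShift, moduleRho = moduleRho, noiseSd = noiseSd,
    pNonresponseGivenHigh = pNonresponseGivenHigh,
    pNonresponseGivenLow = pNonresponseGivenLow, seed = as.integer(seed),
    exactCounts = exactCounts, eularDiscordance = eularDiscordance)
}

# evaluate expr under a seed without disturbing the caller's RNG stream
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# latent states, labels and clinical table shared by both simulators
.simulateClinical <- function(cfg) {
  n <- cfg@nPatients
  if (cfg@exactCounts) {
    nHigh <- round(n * cfg@propIfnHigh)
    high <- sample(rep(c(1L, 0L), c(nHigh, n - nHigh)))
  } else {
    high <- stats::rbinom(n, 1L, cfg@propIfnHigh)
  }
  pNon <- ifelse(high == 1L, cfg@pNonresponseGivenHigh,
                 cfg@pNonresponseGivenLow)
  nonresp <- stats::rbinom(n, 1L, pNon)
  # continuous DAS28 improvement consistent with the drawn label
  # (improvement < 1.2 defines non-response); stored as a signed change,
  # negative = improvement
  improvement <- ifelse(nonresp == 1L,
                        1.2 - abs(stats::rnorm(n, 0.8, 0.6)),
                        1.2 + abs(stats::rnorm(n, 0.8, 0.6)))
  eular <- ifelse(nonresp == 1L,
                  ifelse(stats::runif(n) < cfg@eularDiscordance,
                         "moderate", "none"),
                  ifelse(stats::runif(n) < 0.5, "good", "moderate"))
  data.frame(
    patient_id = sprintf("P%03d", seq_len(n)),
    delta_das28 = -improvement,
    nonresponse_das28 = nonresp,
    eular_category = eular,
    latent_ifn_high = high,
    seropositivity = stats::rbinom(n, 1L, 0.7),
    n_prior_tnf_blockers = sample(0:3, n, TRUE, prob = c(.2, .4, .3, .1)),
    lipid_lowering = stats::rbinom(n, 1L, 0.2),
    erosions = stats::rbinom(n, 1L, 0.6),
    prednisolone = stats::rbinom(n, 1L, 0.7),
    methotrexate = stats::rbinom(n, 1L, 0.7),
    age = round(stats::rnorm(n, 55, 12)),
    gender = sample(c("F", "M"), n, TRUE, prob = c(.75, .25)),
    stringsAsFactors = FALSE)
}

# IRG module rows: shift * latent state + shared factor + residual noise
.simulateIrgRows <- function(cfg, high, baseline) {
  n <- cfg@nPatients
  f <- stats::rnorm(n)                               # shared latent factor
  eps <- matrix(stats::rnorm(8L * n), 8L, n)
  shift <- cfg@moduleShift * rep(high, each = 8L)
  m <- baseline + matrix(shift, 8L, n) +
    cfg@noiseSd * (sqrt(cfg@moduleRho) * rep(f, each = 8L) +
                     sqrt(1 - cfg@moduleRho) * eps)
  rownames(m) <- cfg@irgNames
  m
}

#' Simulate a microarray-like cohort
#'
#' Draws a whole-transcriptome log2 expression cohort with an embedded
#' 8-gene interferon module and a clinical table probabilistically linked to
#' the latent module state. Background genes are independent Gaussian noise
#' around gene-specific baselines and carry no association with the label.
#'
#' @param config a [SimulationConfig-class].
#' @return an [IFNCohort-class] on the log2 scale with `nGenes + 8` rows;
#'   the clinical data include the ground-truth `latent_ifn_high` flag.
#' @examples
#' cohort <- simulateCohort(simulationConfig(nPatients = 12, nGenes = 30))
#' cohort
#' @export
simulateCohort <- function(config) {
  methods::validObject(config)
  if (any(config@irgNames %in% .backgroundGeneNames(config@nGenes)))
    stop("invalid 'irgNames': must be disjoint from background gene names")
  .withSeed(config@seed, {
    clin <- .simulateClinical(config)
    nBg <- config@nGenes
    baselines <- stats::rnorm(nBg + 8L, mean = 8, sd = 1.5)
    irg <- .simulateIrgRows(config, clin$latent_ifn_high, baselines[1:8])
    bg <- matrix(stats::rnorm(nBg * config@nPatients, sd = config@noiseSd),
                 nBg, config@nPatients) + baselines[-(1:8)]
    rownames(bg) <- .backgroundGeneNames(nBg)
    m <- rbind(irg, bg)
    colnames(m) <- clin$patient_id
    IFNCohort(m, clinical = clin, scaleTag = "log2")
  })
}

.backgroundGeneNames <- function(nGenes) {
  if (nGenes == 0L) character() else sprintf("BG%05d", seq_len(nGenes))
}

#' Simulate a qPCR-style relative-expression panel
#'
#' Emulates quantitative PCR measurement of the 8 module genes normalized
#' to a housekeeping gene: the returned expression table holds relative
#' levels (target / housekeeping) on a linear scale, whose log2 has exactly
#' the same module structure as [simulateCohort()] (baselines centred at a
#' relative level of 1, i.e. 0 on the log2 scale).
#'
#' @param config a [SimulationConfig-class]; `nGenes` is ignored (the panel
#'   has only the 8 module genes).
#' @return an [IFNCohort-class] with `scaleTag == "linear"` and 8 rows.
#' @export
simulateQpcrPanel <- function(config) {
  methods::validObject(config)
  .withSeed(config@seed, {
    clin <- .simulateClinical(config)
    log2rel <- .simulateIrgRows(config, clin$latent_ifn_high, baseline = 0)
    m <- 2^log2rel
    colnames(m) <- clin$patient_id
    IFNCohort(m, clinical = clin, scaleTag = "linear")
  })
}

#' Implied pairwise correlation of the simulated module genes
#'
#' Under the latent-factor construction, a module gene's value for patient
#' p is `baseline + shift * H_p + sd * (sqrt(rho) * F_p +
#' sqrt(1 - rho) * e)`, with `H` the Bernoulli(propIfnHigh) IFN state and
#' `F` a standard normal shared factor. Across patients, two module genes
#' therefore correlate at
#' `(shift^2 * v + sd^2 * rho) / (shift^2 * v + sd^2)` where
#' `v = propIfnHigh * (1 - propIfnHigh)` is the variance of `H`. With the
#' default configuration this evaluates to about 0.91.
#'
#' @param config a [SimulationConfig-class].
#' @return the implied pairwise Pearson correlation.
#' @export
impliedIrgCorrelation <- function(config) {
  v <- config@propIfnHigh * (1 - config@propIfnHigh)
  s2 <- config@moduleShift^2 * v
  (s2 + config@noiseSd^2 * config@moduleRho) / (s2 + config@noiseSd^2)
}

#' Theoretical AUC of the module-mean score under perfect label linkage
#'
#' When the non-response label equals the latent IFN state
#' (`pNonresponseGivenHigh = 1`, `pNonresponseGivenLow = 0`), the 8-gene
#' mean score is Gaussian within each class with between-class mean
#' difference `moduleShift` and common variance
#' `noiseSd^2 * (rho + (1 - rho) / 8)`, so the population AUC is
#' `pnorm(moduleShift / (noiseSd * sqrt(2 * (rho + (1 - rho) / 8))))`.
#'
#' @param config a [SimulationConfig-class].
#' @param setSize number of module genes averaged (default 8).
#' @return the theoretical AUC.
#' @seealso [shiftForAuc()] for the inverse.
#' @export
impliedScoreAuc <- function(config, setSize = 8L) {
  v <- config@moduleRho + (1 - config@moduleRho) / setSize
  stats::pnorm(config@moduleShift / (config@noiseSd * sqrt(2 * v)))
}

#' Module shift implying a target score AUC
#'
#' Inverse of [impliedScoreAuc()]: the `moduleShift` for which the 8-gene
#' mean score attains a given population AUC under perfect label linkage.
#'
#' @param auc target AUC in (0, 1).
#' @param noiseSd,moduleRho as in [SimulationConfig-class].
#' @param setSize number of module genes averaged.
#' @return the required log2 shift.
#' @export
shiftForAuc <- function(auc, noiseSd = 0.35, moduleRho = 0.2,
                        setSize = 8L) {
  stopifnot(auc > 0, auc < 1)
  v <- moduleRho + (1 - moduleRho) / setSize
  stats::qnorm(auc) * noiseSd * sqrt(2 * v)
}
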