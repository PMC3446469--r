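---
title: "Methods: the type I interferon signature score and response prediction"
author: "ifnscore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the type I interferon signature score and response prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ifnscore)
```

## Background and scope

Roughly half of rheumatoid arthritis (RA) patients treated with rituximab
(RTX), a B-cell-depleting anti-CD20 antibody, fail to respond clinically.
Baseline whole-blood transcriptomes show that elevated activity of the type
I interferon (IFN) gene network before treatment is associated with
non-response. `ifnscore` implements the complete analysis around that
observation:

1. preprocessing of log2 expression matrices (quantile normalization,
   per-gene median centering);
2. candidate-gene selection by a fold-change rule and by a SAM-style
   permutation statistic;
3. supervised hierarchical clustering of candidates and per-cluster
   association with the clinical response label;
4. a composite **IFN score** — the per-patient mean of log2 expression over
   eight interferon response genes (IRGs): *LY6E, HERC5, IFI44L, ISG15,
   MxA, MxB, EPSTI1, RSAD2*;
5. ROC analysis of the score as a predictor of non-response, with
   exhaustive AUC optimization over all gene subsets and fixed-specificity
   cutoffs;
6. univariate and bivariate logistic association models with odds ratios,
   Wald intervals and Nagelkerke $R^2$.

Clinical non-response is defined two ways: a DAS28 improvement below 1.2
(`delta_das28` criterion), or the EULAR category `"none"` (good and
moderate responders together form the negative class). Throughout the
package the **positive class is non-response**: higher IFN scores predict
failure to respond.

Because the underlying patient-level measurements are not redistributable,
the package ships a synthetic-cohort generator that reproduces the
statistical structure the analysis assumes; every claim the test suite
makes is a claim about that structure, as discussed under *Limitations*.

## The synthetic cohort model

`simulateCohort()` draws, for each patient $p$:

* a latent IFN state $H_p \sim \mathrm{Bernoulli}(\pi)$
  (`propIfnHigh`, default 0.5);
* a shared module factor $F_p \sim N(0, 1)$;
* eight module genes
  $x_{gp} = b_g + \delta H_p + \sigma\left(\sqrt{\rho}\,F_p +
  \sqrt{1-\rho}\,\varepsilon_{gp}\right)$,
  with `moduleShift` $\delta$, `noiseSd` $\sigma$, `moduleRho` $\rho$, and
  gene baselines $b_g$;
* independent background genes $x_{gp} = b_g + \sigma \varepsilon_{gp}$,
  which carry no association with any clinical variable;
* a non-response label drawn as
  $\mathrm{Bernoulli}(p_{\mathrm{high}})$ or
  $\mathrm{Bernoulli}(p_{\mathrm{low}})$ according to $H_p$, a continuous
  DAS28 change consistent with that label, and an EULAR category derived
  from the same draw (a configurable fraction `eularDiscordance` of DAS28
  non-responders is labelled `"moderate"`, making the EULAR association
  deliberately weaker, as observed in practice).

Within a latent stratum the pairwise correlation of two module genes is
exactly $\rho$; across the whole cohort the mixture over $H$ adds
between-group variance, giving the **implied pairwise correlation**

$$ r = \frac{\delta^2 \pi (1-\pi) + \sigma^2 \rho}
            {\delta^2 \pi (1-\pi) + \sigma^2}, $$

implemented in `impliedIrgCorrelation()`. The defaults
($\delta = 2$ log2 units, $\sigma = 0.35$, $\rho = 0.2$, $\pi = 0.5$) give
$r \approx 0.91$, the mutual correlation reported for the eight IRGs in
the cohort this signature was derived from; we target the *mean* pairwise
correlation, since the summary correlation of a gene module is
conventionally reported as an average. The default cohort size (40
patients: a 14-patient discovery design plus a 26-patient validation
design) and background size (20,000 genes) mirror the study scale. The
linkage probabilities default to 0.8/0.2 — a strong but imperfect
association between IFN activity and non-response, which reproduces
validation AUCs in the low 0.8s rather than the perfect separation a
deterministic link would give.

Under perfect label linkage and `exactCounts = TRUE` the 8-gene mean score
is Gaussian within class with variance $\sigma^2(\rho + (1-\rho)/8)$, so
the population AUC has the closed form

$$ \mathrm{AUC} = \Phi\!\left(\frac{\delta}
   {\sigma\sqrt{2(\rho + (1-\rho)/8)}}\right), $$

exposed as `impliedScoreAuc()` with inverse `shiftForAuc()`. The test
suite verifies the empirical AUC against this closed form at $n = 5000$.

`simulateQpcrPanel()` emulates the validation platform: the eight module
genes measured by quantitative PCR relative to a housekeeping gene, stored
on the *linear* scale (relative level 1 = log2 value 0), with the same
latent structure after `log2Transform()`.

## Preprocessing conventions

* **Scale tag.** Every cohort is tagged `"linear"` or `"log2"`; all
  statistics require log2 and refuse linear input.
* **Quantile normalization** makes each patient's value distribution
  identical (per-rank column means). Ties within a column receive the mean
  of their rank span (`limma::normalizeQuantiles(ties = TRUE)`), which
  makes the operation permutation-equivariant and idempotent.
* **Median centering** subtracts each gene's median; with an even patient
  count the median is the midpoint of the two central values. This
  convention matters because both the fold-change filter and the
  cross-platform cohort combination are defined relative to gene medians.
* **Cohort combination** (`combineCohorts()`) median-centers each cohort's
  gene rows independently before concatenation, removing per-platform
  per-gene offsets exactly; a constant platform shift provably leaves the
  combined scores' group separation unchanged.

## Candidate-gene selection

The **fold-change filter** keeps genes whose log2 expression deviates from
the gene median by at least $\log_2(\mathrm{fold})$ in at least
`minPatients` patients; a deviation exactly at the threshold counts ("at
least" two-fold). Defaults are fold 2 in at least 3 patients, the rule
that produced the 124-gene candidate set in the original 14-array
analysis.

The **SAM two-class statistic** is
$d_g = (\bar{x}_{g1} - \bar{x}_{g0}) / (s_g + s_0)$ with $s_g$ the pooled
standard error and $s_0$ a fudge constant stabilizing low-variance genes
($s_0 = 0$ recovers the ordinary $t$ statistic exactly). $s_0$ defaults to
the 5th percentile of $\{s_g\}$; the original coefficient-of-variation
minimization is available via `s0Method = "cv"`. The comparison is the
*unpaired* two-class statistic: the responder and non-responder groups are
independent patients, so no paired variant is meaningful here. Q-values
come from the permutation distribution of $d$ over label permutations —
enumerated exactly whenever the number of distinct labelings does not
exceed `nPermutations`, otherwise uniformly sampled — as pooled exceedance
ratios, monotonized step-up so $q$ is non-increasing in $|d|$.

A calibration caveat, measured by this package's own simulations: on
complete-null cohorts (500 genes, 10 vs 10) the probability that SAM calls
*no* gene at FDR 5% is about 0.90, not 0.95+. Pooled permutation FDR is
known to be mildly anti-conservative under cross-gene dependence; when a
null cohort does produce calls it is one or two genes at $q$ just below
0.05. We report this behaviour as measured rather than adjusting the
statistic post hoc.

## Clustering and cluster-response association

Genes passing the filter are clustered agglomeratively with distance
$1 - $ Pearson correlation and average linkage — the canonical Eisen-style
configuration for co-expression grouping (both are options) — and the tree
is cut to exactly `k` clusters (`k = 5` in the published analysis; no
automatic selection is attempted because none was reported). Constant gene
rows are an error (undefined correlation), and assignments are invariant
to positive rescaling of any gene row. Agglomeration order is the
deterministic order of `stats::hclust`, so results are reproducible for
fixed input.

Each cluster's per-patient mean expression is compared between response
groups with the unpaired equal-variance Student $t$ test. The pipeline
labels a cluster "significant" at a Bonferroni-corrected level
$\alpha / k$ (default $\alpha = 0.05$), a conventional guard against the
multiplicity of $k$ cluster tests. On default synthetic cohorts exactly
the planted IFN module cluster is significant; background clusters cross
even the corrected threshold in a few percent of seeds, which is the
expected false-positive behaviour, not a defect.

## ROC analysis, cutoffs and subset search

`rocCurve()` computes sensitivity and specificity at every distinct score
threshold (score $\ge$ threshold calls non-response) and integrates the
empirical curve trapezoidally; this "integrated AUC" equals the
Mann–Whitney probability with half credit for ties, an identity the test
suite enforces to $10^{-12}$ against a brute-force pairwise count and
cross-checks against an independent ROC implementation. AUC is therefore
invariant under strictly increasing score transforms.

`cutoffAtSpecificity()` picks, among thresholds meeting a specificity
floor, the one maximizing sensitivity, breaking ties toward higher
specificity and then toward the higher threshold. The selection rule among
tied cutoffs is this package's convention; reported cutoffs should be read
with that in mind.

`exhaustiveSubsetSearch()` evaluates the mean-expression score of every
non-empty subset of the panel ($2^8 - 1 = 255$ subsets for the eight-gene
panel; enumeration is refused above 20 genes). All subsets tied at the
maximal AUC are reported — the original search found three tied subsets
(of sizes 3, 4 and 6, the three-gene one being *EPSTI1, RSAD2, MxA*,
shipped as `irgPanel3()`). On small validation cohorts AUC ties are common
and the full tied set is the honest summary of the search.

`bootstrapAucCi()` resamples patients within each class (stratified) and
returns a BCa interval by default. We measured coverage of the generating
AUC at the 9-responder/17-non-responder design: 0.97 for BCa versus 0.89
for the raw percentile interval, the latter reflecting the percentile
method's known undercoverage for a bounded, discrete statistic at
$n = 26$; the percentile interval remains available.

## Logistic association models

`logisticFit()` regresses the binary *response* (improvement $\ge$ 1.2) on
at most two predictors — matching the original analysis, where the cohort
size precluded larger models — by IRLS (`stats::glm`), reporting per-unit
odds ratios with 95% Wald intervals $\exp(\beta \pm 1.96\,\mathrm{SE})$
and Nagelkerke $R^2 = \frac{1 - (L_0/L_1)^{2/n}}{1 - L_0^{2/n}}$. The IFN
score enters per log2 unit; no per-SD standardization is applied. Perfect
separation is a hard error: on cohorts of this size a silently diverging
fit is the likely failure mode, and an unbounded odds ratio is not a
reportable result. `covariateScreen()` runs the univariate fit per
covariate and the bivariate score-plus-covariate fits, flagging collinear
pairs, sign flips and loss of nominal significance of the score under each
adjustment; a screen containing a degenerate fit reports it as such
instead of aborting the pipeline.

## Pipeline, seeds and artifact layout

`runDiscovery()` executes load → (optional) quantile normalization →
fold filter → SAM → clustering → cluster association → discovery gene set
(the most significant cluster) → IFN score, writing each result as
tab-separated text plus a `manifest.json` of every parameter and seed.
`runValidation()` reads the frozen gene set *before* loading the
validation cohort (so no validation label can influence the panel), then
scores, builds ROC curves under both response criteria, runs the subset
search, reports the specificity-1.0 cutoff, and screens covariates. A
single global seed fans out deterministically to per-stage seeds;
identical configurations reproduce byte-identical outputs.

## Problem sizes used by the tests

The test suite works at the scales the methods are designed for: oracle
equivalences on 1000 random ROC fixtures and 50-gene filter fixtures;
null calibration on 20 SAM cohorts (500 genes, 10 vs 10) and 1000-seed
$t$/logistic simulations ($n = 20$ and 100 per draw); closed-form AUC
recovery at $n = 5000$; bootstrap coverage over 200 seeds of the 9/17
validation design; subset-search recovery over 100 seeds at $n = 400$; and
one full discovery run at the default 20,008 × 40 scale. Whole-suite
runtime is a few minutes on one CPU.

## Limitations

* The generator emulates the *assumed* structure — a single correlated
  module, independent Gaussian background, a probabilistic module–label
  link. Real whole-blood arrays have correlated non-IFN modules (the other
  published clusters: cell-cycle, protein synthesis, hematopoietic and
  immune-regulation themes), batch effects, heavy-tailed noise and missing
  values; none are simulated. Passing tests demonstrate correctness of the
  computations and calibration under the assumed model, not clinical
  validity on new cohorts.
* The published patient-level results (AUC 0.82/0.87/0.78/0.83, OR 0.25)
  are not recomputable without the unpublished validation measurements;
  synthetic cohorts at the published design reproduce their *magnitudes*
  but not their exact values.
* Pooled permutation FDR anti-conservativity under the null, and the
  cutoff tie-break convention, are documented above.
* Probe-to-gene summarization, background correction and batch correction
  are out of scope: the pipeline starts from a summarized expression
  matrix.
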