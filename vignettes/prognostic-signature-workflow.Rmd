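---
title: "From condition contrast to prognosis: the prosig workflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From condition contrast to prognosis: the prosig workflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
library(prosig)
```

## The scientific problem

Solid tumours experience *cycling hypoxia* — repeated alternation of
low-oxygen and reoxygenation episodes — in addition to the chronic oxygen
deprivation of poorly vascularised regions. A transcriptional signature of
that state, derived from a panel of tumour cell lines exposed in vitro to
normoxia, cycling hypoxia, or continuous hypoxia, can be carried over to
clinical expression cohorts and asked a prognostic question: do patients
whose tumours look "cycling-hypoxic" progress earlier?

`prosig` implements that entire chain as reusable, tested components:

1. **Signature derivation** from a probesets × samples log2 matrix by
   repeated random 90/10 splits, per-split Welch t-tests with
   Benjamini–Hochberg correction, and ranking by the mean corrected p-value
   across resamplings.
2. **Cross-platform transfer** of the signature through gene identifiers.
3. A **penalized Cox risk model** on a training cohort, with a decision
   threshold that balances sensitivity and specificity at a 5-year horizon.
4. **Survival evaluation** (Kaplan–Meier, logrank, hazard ratio, Harrell's
   concordance, balanced classification rate) per cohort and pooled.
5. **Random-signature nulls** and **NPI reclassification** as the two
   reference comparisons.
6. A **synthetic-data module** that generates both the cell-line experiment
   and survival cohorts with known ground truth, so every claim above is
   testable without external downloads.

## Signature derivation

Given a design with two conditions of interest (here `normoxia` vs
`cychyp`), each resampling draws `round(0.9 * n)` samples uniformly at
random as a training split. On that split every probeset gets a two-sample
t statistic and a BH-corrected p-value; the held-out 10% is classified by
nearest class centroid on that split's top-*k* probesets, giving a per-split
estimate of discrimination. After `n_resamples` rounds (200 by default),
probesets are ranked by the arithmetic mean of their corrected p-values and
the top *k* = 100 form the signature.

Several choices here were genuinely open and are worth recording:

* **Test variant.** The derivation uses an *unpaired Welch* test by default
  even though the cell lines are paired across conditions, because random
  resampling of samples breaks pairs unpredictably; a paired mode
  (`paired = TRUE`) is available and falls back to Welch when fewer than two
  complete pairs survive a split.
* **Averaging corrected p-values** across resamplings (rather than
  re-correcting averaged raw p-values): the mean BH-corrected value is the
  quantity the ranking is defined on. The two orderings agree closely in
  practice but not exactly; only one could be the definition.
* **Tie-breaks** in the top-*k*: larger mean |t| first, then lexicographic
  probeset id, so the signature is a deterministic function of
  (data, parameters, seed) and invariant to row order.
* **Classifier.** Nearest class centroid in Euclidean distance on log2
  values — the minimal parameter-free choice; held-out accuracy is a
  *property of the derivation procedure*, not a tuned classifier benchmark.

```{r derive}
ex <- gen_cell_line_experiment(n_lines = 10, n_probes = 800, n_planted = 40,
                               overlap = 8, effect_size = 1, noise_sd = 0.5,
                               seed = 7)
d <- derive_signature(ex$expr, ex$design, c("normoxia", "cychyp"),
                      k = 40, n_resamples = 50, seed = 8)
length(intersect(d$signature$probeset_ids, ex$truth$planted_cyc))
d$summary$mean_accuracy
```

## Platform transfer

Clinical cohorts are typically measured on a different array generation
than the discovery experiment. `map_signature()` translates the signature
through probeset→gene annotation, keeping **all** destination probesets of
every mapped gene — the reference workflow's 100 discovery probesets map to
94 genes, of which 69 exist on the clinical platform as 87 probesets, so
one-to-many retention is clearly the intended semantics. Probesets lacking
a gene id are dropped with a warning (there is nothing to map through).
`restrict_platform()` handles the complementary operation of reducing a
larger platform to the probesets shared with a smaller one.

## The risk model

`fit_penalized_cox()` z-scores each signature probeset on the training
cohort and fits a Cox model under an elastic-net penalty. The penalty pair
is chosen by 5-fold cross-validation on the partial-likelihood deviance
(fold assignment is seed-controlled; folds that end up without events are
redrawn with a warning). Two parameterisations are exposed:

* the native glmnet `(alpha, lambda)` search over an `alpha_grid` with the
  internal lambda path (the default), and
* explicit independent `(l1, l2)` weights, mapped by
  `alpha = l1/(l1+l2)`, `lambda = l1+l2` so that the quadratic term is
  `l2/2 * ||beta||^2`. A zero total penalty is fitted as an unpenalized Cox
  regression.

Risk scores are linear predictors over standardized expression. Two
standardization modes exist because clinical cohorts arrive from different
summarization pipelines (MAS5 vs RMA) on incomparable scales: `"cohort"`
(the default) re-z-scores each scored cohort with its own constants, which
absorbs global location/scale differences; `"training"` reuses the training
constants and is appropriate when cohorts share one pipeline.

The decision threshold maximizes `(sensitivity + specificity)/2` for
classifying *progression within 5 years* on the training scores. Patients
censored before the horizon carry no usable 5-year label and are excluded
from threshold selection — the standard convention for a fixed-horizon
binary readout. Ties are resolved toward higher specificity, and a score
exactly at the threshold is low risk; both conventions are arbitrary but
fixed and tested.

## Evaluation

Each validation cohort is summarized by the hazard ratio of high vs low
risk (univariate Cox, Wald CI), Harrell's concordance index on the
continuous score (ties in score credit 0.5; pairs unordered under censoring
are unusable; the SE is a delete-one jackknife over patients), the balanced
classification rate at the 5-year horizon with a normal-approximation Z test
against 0.5, and the logrank test. Cohorts are pooled by fixed-effect
inverse-variance weighting on the appropriate scale (log-HR; c-index and
BCR directly); a DerSimonian–Laird random-effects option exists but is off
by default, matching the cited evaluation methodology's default.

Two stratifications of the *same* patients (e.g. the derived signature vs
an established assay plugged in through `score_external_signature()`) are
compared by `compare_paired()`: a patient-level bootstrap of the metric
difference with a normal-approximation two-sided p. This is a deliberate
methodological substitution for closed-form correlated-estimate tests: the
bootstrap is distribution-free and makes no assumption about the joint
sampling law of the two metrics.

## Random-signature nulls and NPI

A prognostic signature must outperform *random* signatures of the same
size, because much of any transcriptome correlates with outcome through
proliferation. `null_distribution()` pushes each random signature through
the identical fit/threshold/classify pipeline and reports the add-one
empirical p `(1 + #(null >= observed))/(N + 1)`, which is never 0 and
bottoms out at `1/(N+1)` — with N = 1000 this reproduces the familiar
"P < 0.001" reporting convention.

The Nottingham Prognostic Index is computed as
`0.2 * size_cm + grade + nodal_stage` (stage 1/2/3 for 0, 1–3, ≥4 positive
nodes) with closed-boundary bands good ≤ 3.4 < moderate ≤ 5.4 < poor.
These constants come from the index's source literature; they are
configurable arguments, not hard-coded. Because poor-band patients are few,
moderate and poor merge into a single high-risk group for the 2×2
reclassification table against the signature's risk groups.

## What the synthetic generators emulate — and what they do not

`gen_cell_line_experiment()` plants additive log2 shifts on chosen probeset
sets over a Gaussian noise floor, with an optional per-line intercept
(`line_sd`) reproducing the paired structure of a real panel; the default
`line_sd = 0` keeps observations independent so that null p-values are
exactly uniform. `gen_cohort()` draws a standard-normal latent activity per
patient, expresses it on the signature probesets (`loading * activity +
N(0, noise_sd)` around probe-specific baselines), and generates event times
from an exponential proportional-hazards model with linear predictor
`log(hr_per_sd) * activity`, independent exponential censoring scaled to
the requested censored fraction, and administrative censoring at the
horizon. Clinical covariates use field-typical conventions — size
lognormal(0.7, 0.4) cm, nodes Poisson(1), grade linked to activity quartile
when `clinical_link` is set, ER+ 75% / HER2+ 15% prevalence — enough
structure for subset filtering and NPI computation.

Deliberately *not* modelled: probe-level intensities and summarization
artefacts, batch effects between cohorts, non-proportional hazards,
informative censoring, and the specific marginal distributions of any real
series. Passing tests therefore demonstrate that the algorithms are correct
and well-calibrated under the stated generative model, not that the
biological signature generalises to real patients.

## Problem sizes and numerical conventions

The package's own validation uses these desk-scale conditions, chosen once
as realistic analogues of the reference design:

* derivation: 20 lines × 3 conditions, 5000 probesets, 100 planted
  (effect 1.0 log2, noise 0.5), k = 100, 200 resamplings — 20 replicate
  seeds;
* risk modelling: 344 training / 600 validation patients, design HR 2 per
  SD, 30% random censoring, 10-year administrative censoring, 5-year
  horizon — 20 replicate seeds;
* nulls: 200 random signatures (scaled from 1000) against a signature of
  87 probesets in a 10000-probeset universe, so a random draw carries < 1
  signal probe on average — the same sparsity regime as an 87-probeset
  signature on a ~22000-probeset clinical array; calibration is checked on
  no-signal cohorts over 100 replicates.

Numerical conventions worth knowing: constant probesets get unit scale
rather than dividing by zero; a t-test on two constant equal groups returns
p = 1 (no evidence) and p = 0 when the means differ; `fdr_adjust` rejects
inputs outside [0, 1]; `expand_signature(threshold = 1)` returns the whole
universe; empirical p-values are never 0; and every generator and fit is a
deterministic function of its seed, which the pipeline derives from one
master seed.

## Limitations

The elastic-net search optimizes CV deviance without a one-standard-error
rule, so selected models can be denser than strictly necessary. The pooled
logrank concatenates cohorts rather than stratifying by cohort. The
concordance SE is a jackknife, which is conservative on very small samples.
The external-assay adapter expects precomputed scores or a scoring
function; the internals of published commercial assays are not
reimplemented.

## End-to-end run

```{r pipeline, eval = FALSE}
cfg <- pipeline_config(n_null_signatures = 200, seed = 1)
report <- run_pipeline(cfg, out_dir = "prosig_run")
report
```

`run_pipeline()` writes every stage artifact as delimited text or JSON plus
an md5 manifest, and the same stages are scriptable from the shell through
`inst/cli/prosig.R`.
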