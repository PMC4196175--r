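# prosig

Resampling-derived prognostic gene signatures with penalized Cox risk
models, survival-based evaluation, random-signature nulls, and Nottingham
Prognostic Index (NPI) reclassification.

## What problem this solves

A discriminative transcriptomic signature — for example one separating
tumour cells under *cycling hypoxia* from normoxia — is only clinically
interesting if it stratifies patients by outcome better than chance and
better than established clinicopathologic scores. `prosig` implements the
complete chain from a multi-condition expression experiment to that
clinical claim, for researchers building or auditing prognostic signatures
on microarray-style expression data:

1. **Derivation** — probesets are ranked by the mean Benjamini–Hochberg
   corrected t-test p-value over 200 random 90/10 sample splits
   (`derive_signature`); each split's held-out 10% yields a nearest-centroid
   classification accuracy, estimating the signature's discrimination.
2. **Platform transfer** — the signature moves to the clinical platform
   through probeset→gene maps, keeping every destination probeset of each
   mapped gene (`map_signature`, `restrict_platform`).
3. **Risk model** — an elastic-net penalized Cox model
   (`fit_penalized_cox`, cross-validated penalty) produces per-patient
   risk scores; the high/low decision threshold maximizes
   (sensitivity + specificity)/2 for progression within 5 years on the
   training cohort (`select_threshold`, `classify`). Follow-up is
   administratively censored at 10 years (`censor_at`).
4. **Evaluation** — per cohort and pooled (fixed-effect inverse-variance):
   hazard ratio with Wald CI, Harrell concordance index, balanced
   classification rate (BCR = (sens+spec)/2) with a Z-test against 0.5, and
   the logrank test (`evaluate_cohorts`); paired bootstrap comparison of two
   stratifications of the same patients (`compare_paired`).
5. **Reference comparisons** — empirical p against random signatures of the
   same size pushed through the identical pipeline (`null_distribution`,
   add-one estimator, never 0), and reclassification against merged NPI
   risk groups (`npi_score`, NPI = 0.2·size + grade + nodal stage, bands
   good ≤ 3.4 < moderate ≤ 5.4 < poor; moderate+poor = high risk).
6. **Synthetic data** — generators with known ground truth for the
   cell-line experiment (`gen_cell_line_experiment`), annotation
   (`gen_annotation`), and survival cohorts driven by a latent activity
   under an exponential proportional-hazards law (`gen_cohort`), so the
   whole workflow is testable offline.

`run_pipeline()` orchestrates all stages from one `pipeline_config()` and
writes every artifact (delimited text / JSON, md5 manifest);
`inst/cli/prosig.R` is a thin shell wrapper.

## Worked example

```r
library(prosig)

# a 10-line experiment with 40 planted cycling-hypoxia probesets
ex <- gen_cell_line_experiment(n_lines = 10, n_probes = 800, n_planted = 40,
                               overlap = 8, effect_size = 1, noise_sd = 0.5,
                               seed = 7)
d <- derive_signature(ex$expr, ex$design, c("normoxia", "cychyp"),
                      k = 40, n_resamples = 50, seed = 8)
length(intersect(d$signature$probeset_ids, ex$truth$planted_cyc))
#> [1] 35
round(d$summary$mean_accuracy, 3)
#> [1] 1

# map to a clinical platform and fit a risk model on a training cohort
ann <- gen_annotation(800, 600, 400, seed = 9)
m   <- map_signature(d$signature, ann$src, ann$dst)
tr  <- gen_cohort(344, m$signature$probeset_ids, hr_per_sd = 2,
                  universe = ann$dst$probeset_id, seed = 10)$cohort
va  <- gen_cohort(300, m$signature$probeset_ids, hr_per_sd = 2,
                  universe = ann$dst$probeset_id, cohort_id = "V",
                  seed = 11)$cohort
mod <- fit_penalized_cox(tr, m$signature, seed = 12)
cl  <- classify(risk_score(mod, va$expr), mod)
ev  <- evaluate_stratification(cl$group, va$clinical$time_years,
                               va$clinical$event, cl$score, cohort_id = "V")
round(ev[, c("hr", "hr_p", "cindex", "bcr")], 3)
#>      hr hr_p cindex   bcr
#> 1 2.715    0  0.672 0.626
```

The derivation recovers 35 of the 40 planted probesets at this small scale
and separates the conditions perfectly on held-out samples. On the
independent validation cohort the hazard ratio of 2.7 (Wald p < 1e-3) says
high-risk patients progress about 2.7 times faster; the concordance 0.67 is
the probability that of two comparable patients the higher-scored one
progresses first; the BCR 0.63 averages sensitivity and specificity for
5-year progression.

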