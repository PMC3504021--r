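# recurSig

Prognostic gene-signature discovery and validation for disease-free
survival (DFS) after resection of colorectal liver metastases (CRLM).

Most patients relapse after curative CRLM resection; a tumour
expression signature predicting who will relapse early would guide
adjuvant therapy. Discovering such a signature from ~100 patients and
~20,000 genes is exactly the regime where overfitting masquerades as
signal, so the machinery matters as much as the data. `recurSig`
implements the full pipeline for researchers working on this (or any
structurally similar) prognostic-signature problem:

* **Risk stratification** of patients by recurrence time (high: event at
  ≤ 12 months; low: DFS > 12 months; stricter 6/24 variant), with
  early-censored patients treated as unlabelable rather than forced into
  a class.
* **Multiple-sampling discovery**: 1000 stratified 2/3 draws; per-draw
  gene ranking by signal-to-noise ratio `(x̄_h − x̄_l)/(s_h + s_l)`,
  Welch *t*, and per-gene univariate Cox Wald |z| (vectorized, verified
  against `coxph`); rank averaging across metrics and iterations;
  nearest-mean (centroid) scoring of each held-out third; a pooled
  cross-validated **combined AUC** with a stratified patient bootstrap CI.
* **Nearest-mean classification** over standardized signature genes,
  score = cor(x, c_low) − cor(x, c_high), ties to high risk; **forward
  selection** of the signature size by leave-one-out accuracy.
* **Survival validation**: Kaplan–Meier, Mantel–Cox log-rank, Cox
  hazard ratios with 95% CIs (Efron ties), Schoenfeld log-rank power,
  Benjamini–Hochberg adjustment, baseline-table comparisons (Fisher /
  Mann–Whitney), and strict training/validation split hygiene (overlap is
  a hard error).
* **Five clinical risk scores** (Fong, Nordlinger, Iwatsuki,
  Mayo/Zakaria, Basingstoke) as editable YAML rubrics dichotomized at
  their published thresholds, with missing-input handling.
* **Treatment-effect differential expression**: per-gene fixed-effects
  ANOVA on two-channel observations with a pooled-shrunken F statistic
  and a global residual-permutation null (Freedman–Lane, 5000 shuffles).
* **Two-colour preprocessing**: print-tip loess normalization, exact
  dye-swap bias decomposition and merging, and the RIN/yield →
  amplification → labelling QC exclusion cascade.
* A **synthetic cohort generator** reproducing the joint structure the
  analysis assumes — censored DFS, an optional planted signature, the
  neoadjuvant-treatment expression shift confounded with risk, centre
  batches — so every stage is testable without patient data.

## Worked example

Generate a two-centre cohort of 119 patients with a planted 40-gene
signature (1.5 log2-unit effect) plus a 200-gene neoadjuvant treatment
shift, then run the whole design end to end:

```r
library(recurSig)

spec <- cohortSpec(n_patients = 119, n_genes = 2000,
                   signature_genes = 40, signature_effect = 1.5,
                   treatment_effect_genes = 200, seed = 2024)
coh <- generateCohort(spec)

run <- runPipeline(coh, iterations = 300, top_k = 75, max_size = 75,
                   n_boot = 1000, seed = 11)
run
#> Pipeline run: 75 labeled training, 44 validation samples
#>   combined AUC 0.859; signature size 5; validation log-rank p 7.49e-08
print(run$validation$logrank)
#> Log-rank: chi-square 28.933 (1 df), p = 7.491e-08; HR 10.625 (95% CI 3.786-29.818)
#>   group  n observed expected
#> 1   low 24       11 23.13709
#> 2  high 20       20  7.86291
```

The combined AUC of 0.859 says the resampled discovery generalizes
within the training set; the validation log-rank (HR 10.6,
p = 7.5e-08) says the selected 5-gene signature separates recurrence
on the 44 held-out patients. Re-running with `signature_effect = 0`
collapses the AUC to ~0.5 and the validation p to uniform — the null
behaviour an honest pipeline must show, and the property the test suite
checks. Clinical risk scores are evaluated the same way
(`evaluateRubrics(clinicalData(coh))`); in this synthetic cohort the
clinical covariates do not drive DFS, so their log-rank p-values behave
like noise.

A thin command-line wrapper is provided at
`inst/scripts/run-pipeline.R` (expression TSV + clinical CSV in, report
files out).

## Package layout

S4 classes (`RecurrenceCohort` extends `SummarizedExperiment`;
`RiskRule`, `NearestMeanModel`, `DiscoveryResult`, `GeneSignature`,
`ScoreRubric`, `TwoChannelArray`, `NormalizedProfile`) with accessor
generics; one R file per analysis stage (`synthdata`, `preprocess`,
`discovery`, `survival-stats`, `clinscores`, `diffexp`, `pipeline`).
See `vignettes/recurSig-methods.Rmd` for the statistical methods,
modelling assumptions and known limitations.
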