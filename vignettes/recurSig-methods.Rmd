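---
title: "Methods: signature discovery and validation for CRLM recurrence"
author: "recurSig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signature discovery and validation for CRLM recurrence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recurSig)
```

## The problem

After curative resection of colorectal liver metastases (CRLM), 60--80% of
patients recur. A gene-expression signature measured in the resected
metastasis that predicted disease-free survival (DFS) would let clinicians
reserve aggressive adjuvant therapy for the patients likely to relapse.
`recurSig` implements the complete discovery-and-validation machinery for
this question — risk stratification, resampled gene ranking, centroid
classification, survival validation, clinical risk scores, treatment-effect
differential expression, and two-colour array preprocessing — together with
a synthetic-cohort generator so that every statistical property of the
pipeline can be tested without patient data. A central lesson the package
is built to expose is *honest validation*: a discovery procedure run on
noise must report no predictive power, and the package's tests hold it to
that.

## Risk stratification

Patients are dichotomized by recurrence time: **high risk** if recurrence
was observed at `dfs <= highMaxMonths` (default 12), **low risk** if
follow-up (event or censoring) exceeds `lowMinMonths` (default 12). A
stricter variant uses 6 and 24 months. Patients censored before the
high-risk cutoff satisfy neither clause; we call them *unlabelable*,
exclude them from discovery (their class is genuinely unknown) and retain
them in survival validation, where censoring is handled properly by the
Kaplan--Meier/log-rank machinery. This three-way rule is a design choice:
the alternative of forcing early-censored patients into the low-risk class
would contaminate the training labels.

## Gene ranking and the multiple-sampling engine

Three metrics score each gene on the labeled training samples:

* signal-to-noise ratio, $(\bar x_{high}-\bar x_{low})/(s_{high}+s_{low})$;
* the Welch two-sample $t$ statistic;
* the Wald $z$ of a per-gene univariate Cox regression on continuous
  expression. Using $|z|$ rather than the hazard ratio ranks protective
  and adverse genes symmetrically.

Genes are ranked by $|score|$, ties broken deterministically by gene id. A
zero-variance gene in both classes scores 0 with a warning.

`multipleSampling()` repeats, by default 1000 times: draw a stratified 2/3
of the training samples (class ratio preserved; degenerate draws are
redrawn and logged); rank all genes by each metric on the draw; average the
three within-iteration rank vectors into one combined ranking (the three
metrics are combined by rank averaging because their scales are
incomparable); fit a nearest-mean model on the draw over the top-75
combined genes; score the held-out third. Held-out scores are pooled over
all iterations into one **combined AUC**, and the per-iteration combined
rankings are averaged into the final gene ranking. The per-gene Cox fits
are vectorized (a few damped Newton steps on the partial likelihood with
Breslow tie handling, identical across genes), which keeps a full
1000-iteration run on 2,000 genes near 20 seconds; the implementation is
verified against `survival::coxph` per gene.

Our reading of the source procedure's "nearest mean classification and
LOOCV" on the held-out third is: centroids are fitted on the 2/3 draw and
applied to the 1/3 by plain prediction; leave-one-out cross-validation is
used only in forward selection on the full training set. The alternative
(re-fitting within the held-out third) would let validation samples
influence their own predictions.

## Nearest-mean classification

Signature genes are standardized by their training mean and SD; each class
is its centroid in standardized space. A sample's continuous score is
$\mathrm{cor}(x, c_{low}) - \mathrm{cor}(x, c_{high})$ (Pearson, across the
signature genes); scores $\le 0$ predict high risk — the tie goes to the
high-risk class because the clinical cost asymmetry favours
over-treatment warnings over missed recurrences. For a single-gene
signature, where correlation across genes is undefined, the signed
standardized distance $|x-c_{high}|-|x-c_{low}|$ replaces it (logged in the
documentation rather than silently). Correlation-based centroids need
signatures with mixed up/down genes; a signature whose genes all move the
same way makes both centroids near-constant vectors and the correlation
unstable. The generator plants signatures with random per-gene directions
for this reason.

## Forward selection

From the averaged ranking, signatures of size $1..k_{max}$ (default 75) are
evaluated by leave-one-out cross-validated accuracy of the nearest-mean
classifier on the full training set, adding genes in rank order; the
selected size is the smallest maximiser (ties resolve to the smallest
signature — the parsimony rule). The LOOCV loop uses exact leave-one-out
updates of the means/SDs and cumulative-sum prefix correlations, so all
sizes are evaluated in one pass per left-out sample; the tests verify it
against brute-force refitting.

## Survival machinery

Kaplan--Meier estimation, the Mantel--Cox log-rank test (with the hazard
ratio and Wald 95% CI from a companion Cox fit), and univariate /
multivariate Cox regression all delegate to the `survival` package, with
Efron tie handling (times are monthly-resolution, so ties happen). The
multivariate mode can auto-screen covariates at univariate $p<0.1$, the
usual construction of baseline risk-factor tables. Log-rank power uses the
Schoenfeld approximation
$\Phi\!\left(|\log hr|\sqrt{d\,p(1-p)} - z_{1-\alpha/2}\right)$, verified
against simulation. Benjamini--Hochberg adjustment wraps `p.adjust` behind
input validation; baseline-table comparisons use two-sided Fisher exact
tests for categorical variables (missing levels excluded and counted) and
Mann--Whitney for continuous ones. A Pearson chi-square variant (without
continuity correction) is available via `categorical_test = "chisq"`
because published baseline tables are frequently computed that way even
when their footnotes say "Fisher"; on one of the anchor tables the two
differ visibly (0.078 vs 0.052) and the package keeps both visible rather
than picking silently.

## Clinical risk scores

The five scores (Fong, Nordlinger, Iwatsuki, Mayo/Zakaria, Basingstoke)
are points-based rubrics dichotomized at their published thresholds
(3, 4, 3, 2, 10). They ship as editable YAML files under
`inst/extdata/rubrics/`; the thresholds are as published, while the
component criteria are transcribed from the scores' original publications
and should be reviewed before clinical use — they are configuration, not
code. Missing inputs (e.g. unrecorded hepatoduodenal nodal status) award 0
points and mark the score incomplete, which structurally caps the
attainable Mayo/Zakaria score at 2 — the behaviour a registry without
nodal dissection data actually exhibits. The extrahepatic-disease
criterion of the Basingstoke index ships disabled because cohorts
restricted to liver-only disease cannot score it. Iwatsuki grades start at
1 (`base_points`), so a factor-free patient is grade 1.

## Differential expression for the treatment effect

Neoadjuvant chemotherapy, given before sample collection, shifts tumour
expression and is confounded with risk (treated patients are
overrepresented among early recurrences). `permutationFTest()` fits, per
gene, a fixed-effects ANOVA on channel-level observations (array, dye and
sample-group effects; groups reference/untreated/treated) and tests the
treated-vs-untreated contrast with an F statistic whose denominator
averages the gene-specific residual mean square with the across-genes
pooled one (weight configurable, default 0.5) — the hybrid statistic
stabilises single-gene variance estimates exactly as moderated statistics
do. Significance comes from residual permutation in the Freedman--Lane
scheme: residuals of the reduced (no-treatment) model are permuted — one
shared observation permutation for all genes per shuffle, preserving
inter-gene correlation of the null — added back to the reduced fit, and
the contrast F recomputed; $p = (1+\#\{F^{perm}\ge F\})/(1+B)$ with
$B = 5000$ by default, so p-values are never 0 and are finite-sample
valid. Raw (not studentized) residuals are permuted.

Residual permutation assumes observation-level errors are exchangeable.
The design builder therefore lays out one array per sample with the dye
orientation alternating *within* each treatment group (so treatment is
never aliased with dye) and gives reference channels dispersion comparable
to the sample channels. Aliased designs — e.g. every treated sample
labelled in the same dye — are rejected with an explicit error rather
than silently producing an unidentifiable fit.

## The synthetic cohort generator

`generateCohort()` draws cohorts under a latent two-class survival model:

* each patient is destined for early recurrence with probability
  calibrated so that the expected fraction with observed recurrence within
  12 months equals `event_rate_1yr` (default 0.6, i.e. 72/119); the
  calibration anchors are $P(T\le 12)$ of 0.92 and 0.12 for the two latent
  classes, with exponential event times (log-rate linear in the latent
  indicator);
* censoring combines staggered administrative follow-up (uniform 12--60
  months, giving a mean follow-up in the mid-20s of months) with early
  dropout at rate `censor_rate` (default 0.15, a free choice — the source
  cohort's censoring fraction is not published);
* planted signature genes (default 0 — the null is the reference
  condition) shift by `signature_effect` log2 units between latent
  classes, with random per-gene sign;
* `treatment_effect_genes` (default 875) shift by `treatment_effect_size`
  (default 1 log2 unit, a typical strong-chemotherapy displacement) in
  treated patients, and treatment probability depends on the latent risk
  (0.62 vs 0.40), reproducing the neoadjuvant confound; the treated and
  planted gene sets are disjoint unless `overlap_effects` is set;
* centre B adds per-gene batch offsets (`center_batch_sd`, default 0.2);
* clinical covariates are drawn to match the marginal frequencies of a
  real two-centre CRLM cohort (65% male, 75% colon primaries, ~49%
  synchronous metastases, and so on).

All randomness flows from the single integer `seed` through a
package-owned RNG scope (`withr::with_seed`), so cohorts are byte-for-byte
reproducible and nothing touches the caller's RNG state.

What the generator does *not* emulate: probe-level intensity
distributions, gene--gene correlation beyond the planted/batch structure,
non-proportional hazards, or informative censoring. Tests passing on this
generator therefore demonstrate the *statistical correctness* of the
pipeline (calibration, recovery, split hygiene), not its performance on
any real cohort.

## What honest validation shows on null data

On cohorts where expression is independent of DFS, the pooled
cross-validated AUC of the full 1000-iteration procedure averages 0.5 —
but an individual cohort's estimate spreads with SD near 0.08 at 75
patients. That spread is not Monte-Carlo error of the resampling (1000
iterations average that away); it is the Hanley--McNeil floor of any AUC
estimate on ~75 patients: cohort-level noise genes generalize from the 2/3
draws to the held-out thirds *within the same cohort*. A bootstrap CI
computed within one cohort (half-width ~0.026 at this size) is therefore
much narrower than the seed-to-seed spread, and should not be read as a
reproducibility band across cohorts. The acceptance suite makes this
distinction measurable: the mean-level check passes, while the
seed-to-seed band implied by reading a within-cohort CI as an
across-cohort tolerance does not — by design, that check is left to fail
rather than be widened.

## Problem sizes and numerical choices

The shipped tests run the discovery engine at 2,000 genes and 75--119
patients (1000 iterations for the null calibration, 200 for recovery
runs), the log-rank type-I calibration over 2,000 null cohorts, and the
permutation-F null at 20,000 genes with 500 shuffles — sizes chosen so the
whole suite exercises cohort-scale behaviour in tens of minutes on one
core. Other fixed choices: loess for print-tip normalization is degree-1
with tricube weights, span 0.4 and three robustness iterations (the
two-colour standard; the method's source names print-tip loess but no
parameters), falling back to a global fit with a warning when a tip group
has fewer than 20 usable spots; control spots never enter fits or output;
replicate profiles per sample are averaged after dye-swap merging; the
dye-swap bias estimate is the per-gene within-pair sign-flip decomposition
(exact by construction); Cox Newton steps are damped to ±2 per iteration;
forward-selection and rank ties break deterministically (smallest size,
gene id). Where a reduced-model fit is exact (e.g. loess refit of an
already-normalized smooth bias), re-normalization changes M by less than
1e-6 — idempotence holds for the structure the fit can represent, not for
refits of pure noise, which any linear smoother perturbs slightly.

## Known limitations

* The rubric criteria for the four non-Fong clinical scores are
  transcriptions that approximate the original publications; edit the YAML
  before drawing clinical conclusions.
* The pooled-AUC bootstrap CI is conditional on the cohort (see above).
* The permutation F-test requires an exchangeable channel-noise design; it
  is not a substitute for a mixed-model analysis when technical replicates
  of the same RNA enter as independent observations.
* Nearest-mean classification with correlation scoring degrades when a
  signature's genes all move in the same direction.
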