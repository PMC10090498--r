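---
title: "Methods: differential co-expression features and SVM classification of depression in fibromyalgia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential co-expression features and SVM classification of depression in fibromyalgia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibrodep)
```

## The problem and the model

Fibromyalgia syndrome (FMS) patients have high rates of major
depression, and the diagnosis is often missed in pain clinics. The
premise of this pipeline is that the co-expression structure of
pain-pathway genes in blood is rewired in FMS, that the genes most
involved in that rewiring are informative features, and that a
soft-margin SVM on those features can separate depressed from
non-depressed FMS patients.

The pipeline has five stages, each exposed as a user-facing function
and chained by `run_pipeline()`:

1. `pairwise_correlations()` — per-group Pearson |r| for all gene pairs.
2. `ks_cutoff()` and `classify_links()` — a two-sample
   Kolmogorov–Smirnov comparison of the two |r| ECDFs locates a
   disease-specific strong/weak cutoff, which partitions pairs into
   disrupted, invoked, common-strong and common-weak links.
3. `rsum_scores()` and `select_hubs()` — per-gene Rsum connectivity
   ranks hub genes within each differential class; the top hubs are the
   classifier features.
4. `augment_dataset()` — additive Gaussian noise at a controlled SNR
   expands the labelled cohort.
5. `pca_fit()`, `grid_search_cv()`, `evaluate_scheme()` — PCA variance
   reduction, repeated stratified K-fold grid search over an RBF SVM,
   and evaluation under two schemes.

### Assumptions

* Expression values are already normalised, log-scale, with no missing
  entries; no renormalisation is performed.
* Co-expression is adequately summarised by Pearson correlation, and
  "strength" by its absolute value: a pair correlated at −0.8 is as
  strongly co-expressed as one at +0.8.
* The healthy and FMS correlation estimates are computed independently
  on each group's samples; the FMS correlations use all FMS samples by
  default (the disease-vs-health contrast does not require depression
  labels), with `fms_samples = "labelled"` as the restricted variant.
* The depression signal is carried by expression *levels* of the hub
  genes; classification operates only on FMS samples with a known
  depression label.

## Stage-by-stage notes and tunable parameters

### KS cutoff

`D` is the maximum absolute difference of the two |r| ECDFs, evaluated
at every observed |r| (sufficient, because ECDFs only jump there). The
cutoff is the *smallest* |r| attaining `D` — a deliberate tie rule so
that equal deviations resolve deterministically toward including more
links. The asymptotic two-sample p-value is computed from the
Kolmogorov series, and the critical deviation from
`c(alpha) * sqrt((n1 + n2)/(n1 * n2))` with
`c(alpha) = sqrt(-log(alpha/2)/2)` (1.36 at alpha = 0.05). With 6441
pairs per group this critical value is ≈ 0.024; note that pair-level
ECDF points are not independent samples (they share genes), so the
p-value and critical bound are descriptive rather than exact.

"Strong" is boundary-inclusive (|r| ≥ cutoff). Zero-variance genes are
an error, not r = 0: silently scoring a flat gene would distort both
CDFs.

One structural caveat found while validating on synthetic data: when
the two groups hold the *same number* of strong pairs (a symmetric
planted design), the two |r| distributions coincide even though the
identity of the strong pairs differs completely — the KS deviation is
then pure noise and the derived cutoff is arbitrary. The KS stage
detects distributional rewiring, not pair-identity rewiring. The
package's property tests for hub recovery therefore classify at a fixed
cutoff between the noise bulk and the planted correlation; on real
cohorts, where rewiring is asymmetric, the KS cutoff is meaningful, and
`run_pipeline(cutoff = ...)` allows a manual override in either case.

### Link classes and the imbalance test

Disrupted = strong in health only; invoked = strong in disease only.
The chi-square test is a one-degree-of-freedom goodness-of-fit of the
(disrupted, invoked) counts against a 50/50 null — under "rewiring has
no preferred direction", a rewired pair is equally likely to fall on
either side.

### Rsum and hub selection

Two interpretation choices are built in and documented rather than
hidden:

* Rsum sums over *class links only*, using the *class-defining group's*
  |r|: a gene's disrupted Rsum sums |r|\_healthy over its disrupted
  links (connectivity it loses), its invoked Rsum sums |r|\_FMS over
  its invoked links (connectivity it gains). This keeps the two scores
  on the scale of the correlations that define each class.
* Ties break by gene name; a gene topping both lists stays in the class
  where its Rsum is larger (disrupted on an exact tie) and the other
  class takes its next candidate, so `k_disrupted + k_invoked` distinct
  features always result. Requesting more hubs than there are
  positive-score genes is an error reporting the achievable counts.

Defaults are 10 + 10 hubs. On the 20-gene synthetic fixtures that would
consume the whole panel, so fixture-scale analyses in the tests and the
acceptance script use 5 + 5; the selection machinery is identical.

### Augmentation

`G' = G + N` with one noise sigma per sample:
`sigma^2 = P_signal / 10^(snr_db/10)`. Signal power defaults to the
mean square of the profile entries (selectable: profile variance).
Because log-scale expression sits around 7–9 units, mean-square power
is dominated by the mean level, which makes the 32 dB default a gentle
perturbation (for a profile at level 8, sigma ≈ 0.2 expression units) —
replicates explore a patient's neighbourhood without crossing patients.
Defaults: `snr_db = 32`, `replicates = 3` (a 61-patient cohort becomes
a pool of 244, comfortably above the ~200 samples a stable grid search
wants). `fidelity_report()` verifies the achieved SNR (tests require
±0.5 dB at ≥ 100 replicates) and exports the 2-D PCA cloud for visual
QC.

### PCA

Centred on the training mean only, never on test data; components kept
until the cumulative explained-variance ratio reaches the threshold
(default 0.90). At threshold 1.0 only positive-variance components are
kept so downstream code never sees numerically-zero directions.

### SVM and grid search

Labels are +1 (depressed) / −1 (not depressed). The grid is powers of
two, `C in 2^-m1..2^m1`, `gamma in 2^-m2..2^m2`, defaults
`m1 = m2 = 8`; accuracy is estimated by stratified K-fold
cross-validation (default 6 splits × 6 repeats) with the *same* fold
assignments for every grid point, so pairs compete on identical splits.
Ties resolve to the smallest C, then the smallest gamma — the least
regularising, smoothest model among equals. Stratification exists
because at 61-patient scale unstratified folds can lose a class
entirely; a one-class fold is an error, not a silent skip.

A practical note on the grid bounds: for p ≈ 20 features on log-scale
data the useful gamma sits near 2^-4 to 2^-6, so a truncated grid
(small `m2`) can cripple *generalisation* while leaving the
memorisation-friendly Scheme-2 landscape intact. The package's fast
test configurations use `m2 = 4` wherever true generalisation is being
measured; the default `m2 = 8` covers the useful range with margin.
The libsvm decision function is re-oriented internally so positive
decision values always mean the +1 class regardless of sample order.

### Evaluation schemes

* **Scheme 1**: stratified random split of the combined
  original+replicate pool (default 30 % test). As specified, the split
  is at sample level, so replicates of a test patient can sit in
  training; `group_by_source = TRUE` provides the leakage-free variant
  that keeps each patient's samples on one side.
* **Scheme 2**: train on replicates only, test on the originals.

In both schemes the PCA basis and the grid search see only the training
portion; the winning (C, gamma) is refit on the whole training portion
and scored once on the held-out portion, repeated over derived seeds.

An honest caveat the package makes explicit: Scheme 2 tests each
patient against a model trained on that same patient's noise
replicates. It therefore measures *label-consistent reconstruction*,
not out-of-patient generalisation — under a null (no-signal) simulation
Scheme 2 still scores near 100 %. For this reason the pipeline's null
control (in the tests and the acceptance script) uses the patient-level
Scheme-1 split, where no-signal data correctly falls back to the
majority-class rate, and any claim of generalisation should come from
`group_by_source = TRUE` evaluation.

## The synthetic-data generator

`sim_config()` plants compound-symmetry correlation blocks (identity
off-block) that are active in one group or both; within-block target
correlation rho in (0, 1) guarantees positive semidefiniteness by
construction and makes the ground-truth disrupted/invoked link set
unambiguous (`true_links()`). Depression is a mean shift of
`effect_size` SD units on `effect_genes` for the depressed fraction of
FMS samples.

Defaults mirror the motivating cohort: 70 healthy vs 61 FMS with a
25/61 depressed fraction, a 20-gene panel (the hub-feature dimension),
baseline level 8 with unit SD, blocks of five genes at rho 0.8 (one
healthy-only, one FMS-only), effect genes 6–15. `fixture_configs()`
packages the four standard conditions (null, disrupted-only,
invoked-only, mixed with `effect_size = 2`) and `make_fixture_suite()`
writes them with a ground-truth manifest.

What the generator does **not** emulate: platform noise and probe-level
structure, non-Gaussian marginals, batch effects, correlation-based
(rather than mean-based) depression signals, and realistic effect
sizes — a 2-SD shift on ten genes is deliberately strong so that
classifier-recovery tests have a known, comfortable Bayes rate. Passing
tests on these fixtures demonstrate that the machinery is correct and
leak-free, not that real cohorts reach any particular accuracy.

## Numerical choices and degenerate inputs

* KS cutoff ties: smallest |r|, tolerance 1e-12 on the deviation.
* Identical |r| samples: D = 0, p = 1, cutoff = smallest observed |r|.
* Two-sample t comparison of hub Rsum values uses the pooled-variance
  form; all-constant equal-mean input returns t = 0, p = 1 instead of
  erroring, since that degenerate case is a well-defined null.
* Probe collapse: max-mean-expression probe by default ("mean of
  probes" selectable); panel genes missing from the data are reported
  in an attribute and a message, never silently dropped.
* All-zero profiles are an error in `noise_sigma()` (signal power 0).
* Artifact round-trips (expression TSV, edge lists, rankings, CV
  reports) preserve numbers to ≥ 10 significant digits.
* Every stochastic step is seeded; `run_pipeline()` derives stage seeds
  from one master seed, and all derived seeds stay below 2^31.

## Problem sizes used by the tests and acceptance script

The test-suite and `scripts/acceptance.R` run at the cohort scale
(70 + 61 samples, 20-gene panels, 190 pairs) with fast grid settings
(`m1 = m2 = 2`, 3 splits × 2 repeats) where memorisation-style Scheme-2
accuracy is measured, and `m2 = 4` where generalisation is measured;
correlation-recovery and SNR-fidelity checks use n = 500 samples and
120 replicates respectively. These sizes are the package's choice of a
fixture family that exercises every failure mode the method has at
full scale while keeping the whole suite quick to run routinely.

## Known limitations

* The KS-derived cutoff is undefined-by-noise on symmetric rewiring
  (above) and, like all ECDF statistics on pair data, treats dependent
  pairs as exchangeable observations.
* Scheme 2's optimism (above) means its accuracy should be read as an
  upper bound.
* Hub selection is greedy per class with a fixed overlap rule; it does
  not optimise the joint feature set.
* No alias resolution in gene-symbol matching; panels must use the
  platform's symbols.
* The augmentation model is additive Gaussian only — no resampling,
  mixup or covariance-matched generation.
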