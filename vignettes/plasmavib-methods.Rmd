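---
title: "Dual-modality plasma spectroscopy diagnostics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-modality plasma spectroscopy diagnostics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plasmavib)
```

## The problem

Vibrational spectroscopy of blood plasma — mid-infrared absorption
(ATR-FTIR) and Raman scattering — fingerprints the biochemical composition
of a patient's plasma in a single, minimally invasive measurement. The
question this package addresses is whether such spectra can separate
endometrial-cancer patients from controls, where the control population
deliberately includes women with polycystic ovary syndrome (PCOS), a
metabolically distinct high-risk group. The pipeline covers the full
chemometrics workflow: pre-processing of raw spectra per modality,
low-level fusion of the two modalities, repeated patient-level supervised
evaluation, spectral biomarker-region selection, and group-level
statistics. Because no raw clinical spectra are distributable, the package
also ships a synthetic plasma-spectrum generator with the statistical
structure the analysis assumes, so every stage is testable end to end.

## Pre-processing model

Each modality has its own operator stack, applied in a fixed order.

**ATR-FTIR** (wet or dried films): truncation to the 1800–900 cm⁻¹
bio-fingerprint region; optional atmospheric reference subtraction;
asymmetric-least-squares (AsLS) baseline correction; vector normalisation
to unit Euclidean norm.

**Raman** (wet): truncation to 1800–750 cm⁻¹; rubber-band baseline
correction; then either CH₂ band-area normalisation (single-modality
models) or vector normalisation (when rows feed the fused model).

### AsLS baseline

The baseline $z$ minimises

$$\sum_i w_i (y_i - z_i)^2 + \lambda \sum_i (\Delta^2 z_i)^2,
\qquad w_i = \begin{cases} p & y_i > z_i \\ 1 - p & y_i \le z_i\end{cases}$$

iterated from $w \equiv 1$ to a weight fixed point or the iteration cap
(Eilers–Boelens scheme). Defaults are $\lambda = 1000$, $p = 0.05$, 10
iterations. The pentadiagonal system is solved sparsely; the test suite
proves equivalence to a dense direct solve at $10^{-8}$.

Two numerical properties of AsLS at this smoothing constant are worth
knowing. First, peak-shape preservation is width-dependent: a sharp band
(SD ≈ 2 grid steps) on a linear drift keeps its apex position to one step
and its height to 5%, but broader bands are attenuated appreciably because
the baseline bends into them; the subsequent normalisation makes the
classifiers insensitive to this common attenuation. Second, the FTIR stack
is not idempotent: re-running AsLS on an already corrected spectrum
re-estimates a small baseline under broad band clusters. The Raman stack
*is* exactly idempotent — a rubber-band-corrected spectrum is non-negative
with its hull on the zero line, so a second correction subtracts nothing.

### Rubber-band baseline

The baseline is the lower convex hull of the spectrum (Andrew monotone
chain, linear interpolation between hull vertices). The corrected spectrum
is non-negative everywhere and exactly zero at hull vertices. The tests
compare the hull against a brute-force $O(n^2)$ gift-wrapping oracle,
exactly.

### Normalisations

Vector normalisation divides by the Euclidean norm over the truncated
range. CH₂ band-area normalisation scales a Raman spectrum so its
trapezoidal integral over 1378.1–1490.1 cm⁻¹ equals 1 (the target value is
a convention; only its constancy across spectra matters). Both are
scale-invariant and idempotent.

### Atmospheric correction

Instrument platforms correct residual water-vapour and CO₂ lines
internally; here a minimal, testable substitute is provided: non-negative
reference subtraction with coefficients minimising the first-difference
roughness of the corrected spectrum (vapour lines are sharp, so the
smoothest result is the cleanest). It is optional and skipped for
synthetic data, which plants no atmospheric lines.

## Fusion

Low-level fusion concatenates each patient's vector-normalised mean
ATR-FTIR spectrum (451 features) with their vector-normalised mean Raman
spectrum (526 features) into one 977-feature row, FTIR block first. The
two wet acquisitions per modality are averaged per patient before
concatenation: the acquisition protocol gives no natural pairing between
an FTIR replicate and a Raman replicate, and averaging avoids inflating
the patient count. Each block keeps unit norm, so neither modality
dominates by scale.

## Supervised evaluation

Patients are split 70/30 (train/test) at the *patient* level, stratified
by class with `|train| = round(0.7 n)` enforced exactly by
largest-remainder apportionment (38/16 for the default 54-patient cohort).
The split is repeated ten times from a master seed; every dataset in a
study uses the identical patient partitions. Within each iteration, PCA is
fitted on training rows only and the smallest number of components whose
cumulative explained variance reaches 95% is retained; fitting PCA per
iteration on training rows (rather than once on everything) is the
stricter reading of the design and guarantees no test-patient spectrum
influences any fitted quantity. Four classifiers run on the scores — SVM
(RBF, cost 1, γ = 1/(p·var)), random forest (100 trees), kNN (k = 5) and
ridge-penalised logistic regression (λ = 1/n) — hyperparameters are
platform-style defaults, overridable. A stratified 10-fold
cross-validation inside the training set guards against overfitting;
headline metrics always come from the held-out 30%.

Metrics use cancer as the positive class; AUC is the rank (Mann–Whitney)
statistic with ties counting one half, proven equal to the pairwise oracle
and to the trapezoidal ROC area in tests. Per-iteration metrics aggregate
to mean, SD, t-based confidence interval and coefficient of variation.
Every run records a provenance audit listing exactly which patients' rows
entered PCA fitting and training, and the test suite asserts the
train/test intersection is empty everywhere.

The unsupervised view fits PCA to all rows without labels and draws
per-group 95% normal confidence ellipses on the PC1–PC2 scores (group
covariance scaled by the χ²₂ 0.95 quantile).

## Biomarker regions

Per split iteration, a seeded random forest is fitted on the training rows
at the *original wavenumbers* (not PCA scores) and each wavenumber is
scored by mean impurity decrease; the ten highest-scoring wavenumbers form
that iteration's panel (ties break toward the lower wavenumber). Panels
are pooled into an occurrence histogram with fixed 12.6 cm⁻¹ bins anchored
at the truncation lower edge (900 cm⁻¹ FTIR, 750 cm⁻¹ Raman). One-way
ANOVA (cancer vs control, classical equal-variance F) is computed per
selected wavenumber on the full pre-processed dataset — the panels are
per-iteration but significance is a property of the wavenumber, so a
single pooled p per wavenumber is reported. Regions of interest are
occupied bins restricted to members with p < 0.05, reported with their
center, occurrence count and p-value range. Fused analyses tag each region
with its source modality block.

## Group statistics

Control-group consistency (PCOS vs healthy) is tested by MANOVA on
PCA-reduced spectra: PCA on the pooled rows retaining 95% variance, then
Wilks' Λ with Rao's F approximation on the scores; with one retained
component this reduces exactly to the one-way ANOVA F, which is how the
degenerate case is computed. Demographic comparisons replicate the
standard tools for published summary tables: a two-sample t-test computed
directly from means/SDs/sizes (Welch by default; both variants agree to
far beyond any decision threshold on the motivating cohort), and Pearson's
χ² of independence with no continuity correction, dropping categories
unobserved in every group before computing df — both choices are required
to reproduce printed table statistics exactly.

## The synthetic study generator

The generator emulates a 54-patient cohort: 22 endometrial cancer, 18
PCOS, 14 healthy. Each patient carries a latent disease score $d \in
[0,1]$: 1 for cancer, 0 for healthy, uniform for PCOS — the simplest
mechanism that reproduces the intermediate, overlapping position of PCOS
in unsupervised score space. A spectrum is a sum of Gaussian bands at
biochemically meaningful positions (Amide I/II, lipid ester carbonyl at
1733 cm⁻¹, CH₂/CH₃ deformations, carotenoid C–C at 1525 cm⁻¹,
nucleic-acid PO₂⁻ bands, phenylalanine ring at 1003 cm⁻¹) with amplitude
$(\text{base} + d\cdot\text{effect}\cdot\text{effect\_scale})$, times a
per-patient, per-band log-normal factor (SD 0.10) representing
between-patient biochemistry, plus a random low-order polynomial baseline,
plus additive Gaussian noise (SD 0.025), clipped at zero. Wet ATR-FTIR
adds a broad water band (center 1637 cm⁻¹, SD 60 cm⁻¹, amplitude 1.0)
attenuated 5% per successive acquisition (dehydration drift); dried-film
replicates are scaled by a per-site factor (SD 0.08) emulating coffee-ring
heterogeneity. Replicate structure: 2 wet acquisitions per modality and 20
dried-film sites per patient.

Effect directions are fixed conventions (e.g. carotenoids depleted with
disease); magnitudes are calibration knobs, chosen once so the pipeline
lands in a realistic diagnostic regime — best-classifier accuracies around
0.75–0.82 for single wet modalities and a clear fusion gain — and not
revisited. The per-patient band variability is what keeps classifiers off
the ceiling: without it the cohort is perfectly separable and every
comparative property degenerates.

What the generator does *not* emulate: Mie scattering and fluorescence
backgrounds, cosmic rays, detector nonlinearity, wavenumber-calibration
drift, atmospheric lines, or any real covariance structure between bands
beyond the single latent score. Passing tests therefore demonstrate the
pipeline's correctness and its behaviour under a plausible statistical
structure — not clinical performance on real plasma spectra.

## Problem sizes and numerical choices

The shipped tests exercise ten study seeds of the default 54-patient
cohort for the comparative properties (ordering, null calibration,
biomarker recovery), 500 replicates for the MANOVA null-uniformity check,
and 100 random instances per oracle-equivalence check; these sizes give
stable Monte-Carlo estimates while keeping the suite quick. Unsupervised
overlap (PCOS centroid between healthy and cancer) is asserted on the
fused patient-level representation, where replicate averaging lets the
latent structure dominate PC1–PC2; on single per-acquisition datasets,
acquisition noise can dominate the first two components.

Degenerate inputs are handled explicitly: zero-norm vectors and
non-positive band integrals refuse to normalise (a non-positive CH₂
integral signals a failed baseline upstream); constant matrices refuse
PCA; classes absent from a split, fold or test set raise errors rather
than producing silent NaNs; all-zero contingency categories are dropped
before df are counted; zero-variance ANOVA inputs with equal means return
p = 1 by convention.

## Known limitations

- AsLS attenuation of broad bands (above) means absolute band intensities
  after FTIR pre-processing are not quantitative; only relative,
  cross-spectrum comparisons are meaningful.
- The latent single-score disease model makes all effect bands perfectly
  correlated across patients; real biochemistry is higher-dimensional.
- Classifier hyperparameters are fixed defaults; no tuning or nested
  cross-validation is performed, by design.
- The atmospheric correction is a deliberately minimal roughness-based
  subtraction, not a full vapour-line model.

## A minimal run

```{r, eval = FALSE}
st  <- synth_study(synth_config(seed = 1))
pp  <- preprocess_params()
fw  <- preprocess_modality(st$ftir_wet, pp, "single")
rw  <- preprocess_modality(st$raman_wet, pp, "single")
fu  <- concatenate_modalities(preprocess_modality(st$ftir_wet, pp, "fused"),
                              preprocess_modality(st$raman_wet, pp, "fused"))
study <- run_supervised_study(list(ftir_wet = fw, raman_wet = rw, fused = fu),
                              eval_config(master_seed = 1))
print(study)
bio <- run_biomarker_study(fw, study$plan, ranking_config(seed = 1))
print(bio)
```
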