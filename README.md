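# plasmavib

Dual-modality vibrational-spectroscopy diagnostics for blood plasma, in R.

Mid-infrared absorption (ATR-FTIR) and Raman scattering of a plasma
droplet fingerprint a patient's circulating biochemistry. `plasmavib`
implements the complete chemometrics workflow for evaluating such spectra
as a diagnostic for endometrial cancer against a control group that
includes both healthy women and women with polycystic ovary syndrome
(PCOS):

- **Spectral I/O and validation** — wide delimited-text tables (one row
  per acquisition, wavenumber columns), with an ascending-grid convention
  and a reporting validator.
- **Pre-processing** — per modality, in fixed order. ATR-FTIR: truncation
  to 1800–900 cm⁻¹, optional atmospheric reference subtraction,
  asymmetric-least-squares baseline (λ = 1000, p = 0.05, 10 iterations,
  sparse pentadiagonal solve), vector normalisation. Raman: truncation to
  1800–750 cm⁻¹, rubber-band (lower convex hull) baseline, CH₂ band-area
  normalisation (∫ over 1378.1–1490.1 cm⁻¹ ≡ 1) or vector normalisation
  for fusion.
- **Low-level fusion** — per-patient concatenation of the unit-norm mean
  ATR-FTIR and Raman spectra (451 + 526 = 977 features).
- **Supervised evaluation** — ten seeded, class-stratified, patient-level
  70/30 splits; PCA retaining 95% variance fitted on training rows only;
  SVM, random forest, kNN and ridge logistic regression; stratified
  10-fold cross-validation inside the training set; held-out sensitivity,
  specificity, accuracy and rank-formulation AUC (cancer positive),
  aggregated as mean / SD / t-based CI / CV, with a structural
  train-test leakage audit.
- **Biomarker regions** — per-iteration random-forest wavenumber ranking,
  top-10 panels, 12.6 cm⁻¹ occurrence binning, per-wavenumber one-way
  ANOVA, significant region-of-interest reporting.
- **Group statistics** — MANOVA (Wilks' Λ, Rao's F) on PCA scores for
  control-group consistency; t-tests from published summary statistics;
  Pearson χ² of independence without continuity correction.
- **Synthetic study generator** — a seeded statistical emulation of the
  54-patient dual-modality design (22 cancer / 18 PCOS / 14 healthy, two
  wet acquisitions per modality, 20 dried-film sites with coffee-ring
  heterogeneity, broad 1637 cm⁻¹ water band with dehydration drift in wet
  ATR-FTIR), driven by a latent disease score that places PCOS between
  healthy and cancer.

The AUC is the Mann–Whitney statistic
AUC = P(score⁺ > score⁻) + ½·P(score⁺ = score⁻); the AsLS baseline z
minimises Σᵢ wᵢ(yᵢ − zᵢ)² + λ Σ (Δ²z)² with asymmetric weights
wᵢ ∈ {p, 1 − p}. Both are verified in the test suite against independent
brute-force oracles (pairwise comparison; dense direct solve), as is the
rubber-band hull (O(n²) gift wrapping).

## Worked example

```r
library(plasmavib)

st  <- synth_study(synth_config(seed = 1))          # three raw datasets
pp  <- preprocess_params()
fw  <- preprocess_modality(st$ftir_wet,  pp, "single")
rw  <- preprocess_modality(st$raman_wet, pp, "single")
fu  <- concatenate_modalities(
         preprocess_modality(st$ftir_wet,  pp, "fused"),
         preprocess_modality(st$raman_wet, pp, "fused"))

study <- run_supervised_study(
  list(ftir_wet = fw, raman_wet = rw, fused = fu),
  eval_config(master_seed = 1, compute_cv = FALSE))
print(study)
#> supervised_study: 3 datasets x 4 classifiers x 10 iterations
#>   ftir_wet   best: svm accuracy 77.8% (SD 7.9)
#>   fused      best: svm accuracy 86.2% (SD 5.7)
#>   raman_wet  best: svm accuracy 77.8% (SD 6.3)

bio <- run_biomarker_study(fw, study$plan, ranking_config(seed = 1))
print(bio)
#> biomarker_study: 10 iterations x 10-wavenumber panels
#>   21 significant region(s), alpha = 0.05:
#>     1082.7 cm^-1 (ftir)  count 19  p range [1.84e-06, 1.99e-02]
#>     1737.9 cm^-1 (ftir)  count 12  p range [2.43e-07, 4.23e-03]
#>     ...
```

Single-modality wet spectra classify at about 78% held-out accuracy and
the fused representation at about 86% — fusing the two modalities beats
either alone. The biomarker regions recover the planted effect bands: the
12-occurrence region at 1737.9 cm⁻¹ is the generator's lipid
ester-carbonyl effect at 1733 cm⁻¹, caught within half a 12.6 cm⁻¹ bin.
On published demographic tables:

```r
print(pearson_chi2(rbind(cancer = c(6, 16), control = c(19, 13))))
#> chi-squared test: statistic = 5.404, df = 1, p = 0.02009
```

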