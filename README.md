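# ramanbc

Chemometric analysis of blood-plasma Raman spectra for early (stage-Ia)
breast-cancer subtype classification.

Raman spectroscopy of dried blood plasma in the 500–1600 cm⁻¹ fingerprint
region reports the composition of plasma proteins, lipids and carotenoids.
Differences in specific bands — 941 cm⁻¹ (C–C stretching in proteins),
1158 and 1518 cm⁻¹ (β-carotene-associated modes), 1448 cm⁻¹ (CH₂ bending
in lipids and proteins), among others — distinguish healthy controls from
the four intrinsic breast-cancer subtypes defined by hormone-receptor (HR)
and HER2 status: Luminal A (`HR+HER2-`), Luminal B (`HR+HER2+`),
HER2-enriched (`HR-HER2+`) and triple-negative (`HR-HER2-`).

The package implements the full workflow such a study needs, for
spectroscopists and chemometricians who want a tested, reproducible
reference implementation:

- **Preprocessing** (`preprocess_spectra()`), five stages in fixed order:
  PCA-score outlier rejection at the 2.58-SD / 99% level, rolling-ball
  baseline correction (63-channel morphological opening, 21-channel
  smoothing), mean-centering with one global standardization scalar,
  cosmic-ray despiking by modified z-scores of first differences
  (threshold 4), and Whittaker smoothing, solving
  (I + λDᵀD) z = y exactly with λ = 10 000.
- **Classification** (`pcalda()`, `loocv_train()`, `validate_ensemble()`):
  PCA-LDA with 5 principal components, a stratified 70:30 sample-grouped
  split, a leave-one-out cross-validation ensemble, and frozen-eigenvector
  validation — held-out spectra are projected with the training
  eigenvectors, never refit.
- **Evaluation** (`roc_one_vs_rest()`): one-vs-rest ROC with per-class,
  micro-averaged and macro-averaged AUCs, Youden operating points, and
  sensitivity/specificity tables.
- **Band statistics** (`band_analysis()`): difference spectra against the
  control mean and per-wavenumber two-sided Mann–Whitney–Wilcoxon tests
  (exact for small untied groups), with contiguous significant channels
  merged into annotated bands.
- **Clustering** (`complete_linkage()`): complete-linkage hierarchical
  clustering of per-sample discriminant coordinates, Newick/JSON dendrogram
  export, and tree-cut purity.
- **Synthetic data** (`plasma_preset()`, `simulate_spectra()`): a generator
  emulating the study design — 24 samples (12 control, 3 per subtype),
  5 replicate spectra each, fluorescence baseline, detector noise, cosmic
  rays, occasional outlier spectra, and signed subtype-specific band shifts
  — with ground truth returned for recovery testing. Patient spectra of
  this kind are not public; the generator makes the entire pipeline
  testable without any download.

## Worked example

```r
library(ramanbc)

cfg     <- plasma_preset(seed = 42)      # the study-design preset
spectra <- simulate_spectra(cfg)
spectra
#> <spectra_set> 120 spectra x 1101 channels (500-1600 cm^-1)
#> classes: control=60, HR-HER2-=15, HR-HER2+=15, HR+HER2-=15, HR+HER2+=15

pp <- preprocess_spectra(spectra)        # five-stage preprocessing
sp <- split_train_validation(pp$set, 0.7, "sample", seed = 42)

ens <- loocv_train(sp$train, n_pcs = 5)  # LOOCV ensemble, frozen PCA
ens
#> LOOCV ensemble: 78 folds, 5 PCs, LOOCV accuracy 0.987

val <- validate_ensemble(ens, sp$validation)
val$summary
#>        metric mean sd
#> 1    accuracy    1  0
#> 2          f1    1  0
#> 3 sensitivity    1  0
#> 4 specificity    1  0

roc_one_vs_rest(val$posterior, val$labels)
#> One-vs-rest ROC analysis
#>   control    AUC = 1.000
#>   HR+HER2-   AUC = 1.000
#>   HR+HER2+   AUC = 1.000
#>   HR-HER2+   AUC = 1.000
#>   HR-HER2-   AUC = 1.000
#>   micro-average AUC = 1.000
#>   macro-average AUC = 1.000
```

Every preserved fold model classifies every held-out validation spectrum
perfectly here (mean accuracy 1, zero cross-model SD): the preset's effect
sizes put the pipeline in the high-separation regime. Band analysis then
explains *which* wavenumbers drive the separation — for the HER2-enriched
subtype the injected decreases are recovered with their assignments:

```r
band_analysis(pp$set, "HR-HER2+")
#> Band report: 326/1101 channels significant at alpha = 0.05 (raw p)
#>    878 cm^-1  decrease p = 0.000134  proline and hydroxyproline in collagen
#>   1158 cm^-1  decrease p = 7.48e-09  C-C/C-N stretching in proteins (beta-carotene)
#>   1448 cm^-1  decrease p = 7.48e-09  CH2 bending in lipids and proteins
#>   ...
```

(The 1448 band run extends to 1518 cm⁻¹: both injected decreases merge
into one contiguous significant region.) Finally, clustering the
per-sample discriminant coordinates recovers the HER2-status structure at
a k = 3 cut — controls, HER2− subtypes and HER2+ subtypes form disjoint
clusters:

```r
mod <- pcalda(sp$train, n_pcs = 5)
sc  <- sample_discriminant_coords(mod, pp$set)
cluster_purity(complete_linkage(sc$coords), sc$classes, k = 3)$composition
#>        label
#> cluster control HR-HER2- HR-HER2+ HR+HER2- HR+HER2+
#>       1      12        0        0        0        0
#>       2       0        3        0        3        0
#>       3       0        0        3        0        3
```

`run_pipeline(pipeline_config(seed = 1), "out/")` executes all six stages
(simulate → preprocess → train → evaluate → features → cluster), writes
CSV/JSON artefacts for each, and records a manifest with MD5 hashes —
identical config and seed reproduce every file byte-for-byte.

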