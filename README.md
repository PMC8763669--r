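# osteotexture

Dual-modality texture analysis of vertebral bodies for osteoporotic
fracture differentiation, as a tested R package plus a reproducible
analysis workflow.

## The problem

Average volumetric bone mineral density (vBMD) from quantitative CT only
partly separates patients with prevalent osteoporotic vertebral fractures
from those without: the spatial *arrangement* of density and marrow
composition inside the vertebral body carries additional information.
This package implements the complete analysis chain for testing that idea
with two routine modalities:

* **CT**: Hounsfield units converted to vBMD by a linear calibration
  (`vBMD = slope * HU + intercept`), aggregated per vertebra over integral
  and trabecular segmentation masks.
* **Water–fat MRI (CSE-MRI)**: the proton density fat fraction
  `PDFF = 100 * F/(F + W)` and T2\* maps, aggregated the same way.
* **Texture features** on both: global histogram moments (variance,
  skewness, kurtosis), 8 features of the 3D gray-level co-occurrence matrix
  (GLCM), and — for CT — 13 features of the 3D gray-level run-length matrix
  (GLRLM). Both matrices are built over the 13 direction classes of the
  26-neighborhood (offsets `d` and `-d` identified), merged with optional
  `1/||d||` length weighting: the GLCM by averaging, the GLRLM by
  summation. The 13-direction set is closed under all 48 lattice
  symmetries, making every feature rotation invariant.
* **Inference**: Mann–Whitney group comparisons (exact by enumeration for
  small samples, tie-corrected normal approximation otherwise) and
  stepwise ordinary-least-squares regression with forced adjustment
  covariates (entry p < 0.05, removal p ≥ 0.10), applied per vertebra and
  per patient, with binary fracture status fitted as a linear probability
  model and adjusted R² = 1 − (1 − R²)(n − 1)/(n − k − 1) as the headline
  statistic.

Since no patient data ship with the package, a **synthetic cohort
generator** is a first-class component: Gaussian-random-field phantoms
with group-structured density, marrow fat, and texture heterogeneity,
written as NIfTI volumes with nested integral/trabecular label masks, so
the whole pipeline is testable end to end against known ground truth. See
`vignettes/methods.Rmd` for the model, parameter meanings and design
choices.

## Worked example

The analysis workflow is three numbered scripts over the package API:

```sh
Rscript analysis/01_simulate.R          # cohort -> results/cohort/
Rscript analysis/02_extract_features.R  # maps + texture -> results/features.csv
Rscript analysis/03_fit_models.R        # stepwise suite -> results/model_report.*
```

Output of a run (seed 1):

```
Simulated 182 vertebrae from 26 patients (12 with fracture).
Integral vBMD, fracture vs control: 154.5 +- 35.9 vs 233.3 +- 37.3 mg/cm^3
  (Mann-Whitney p = 1.1e-23)

Adjusted R^2, quantitative-only vs texture-augmented:
     level r2adj_quant r2adj_texture r2adj_gain
1 vertebra       0.781             1      0.219
2  patient       0.750             1      0.250
```

The fracture group's extracted vBMD is markedly lower, and adding texture
features to the fracture model raises the adjusted R² at both analysis
levels — on the phantom the texture model saturates near 1 because a
global-variance feature reads the simulated heterogeneity contrast almost
directly (the vignette discusses why in-vivo gains are large but not
perfect). The same steps are available programmatically:

```r
library(osteotexture)
cfg <- cohort_config(seed = 1)           # 26 patients x 7 levels
res <- run_pipeline(cfg, "results")      # simulate + extract + model + report
res$suite$comparison                     # paired adjusted-R^2 table
```

Single-vertebra building blocks:

```r
pdff  <- compute_pdff(fat_volume, water_volume)      # percent, clipped [0,100]
vbmd  <- hu_to_vbmd(ct_volume, slope = 0.8, intercept = 0)
mask_mean(vbmd, mask, "trabecular")                  # level-wise aggregation
extract_feature_vector(ct_volume, mask, "CT")        # 24 named features
extract_feature_vector(pdff, mask, "PDFF")           # 11 named features
```

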