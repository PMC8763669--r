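---
title: "Dual-modality vertebral texture analysis: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-modality vertebral texture analysis: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osteotexture)
```

## The problem

Osteoporotic vertebral fractures are only partly explained by volumetric
bone mineral density (vBMD): two vertebrae with the same average density can
differ substantially in trabecular microarchitecture, and that difference
carries fracture-relevant information. Two routinely available modalities
see complementary aspects of this: CT attenuation (convertible to vBMD via a
linear phantom calibration) reflects mineral content, while chemical shift
encoding-based water–fat MRI (CSE-MRI) quantifies bone-marrow composition
through the proton density fat fraction (PDFF) and T2\*. This package
implements the full analysis chain for asking whether *texture* features —
statistical descriptors of the spatial arrangement of gray levels inside the
vertebral body, computed on both modalities — improve the separation of
patients with and without prevalent vertebral fractures beyond the
quantitative means alone.

Because no patient images ship with the package, a synthetic cohort
generator is a first-class, tested component: it produces phantom volumes
with exactly the statistical structure the downstream analysis is sensitive
to, so every stage is verifiable end to end.

## Quantitative maps

Three voxelwise operations precede any aggregation:

* **PDFF** (percent): `100 * F / (F + W)` from the fat and water signal
  volumes. Voxels with `F + W = 0` carry no information; they are set to 0%
  and counted in an attribute rather than propagating `NaN`. Results are
  clipped to the physical range [0, 100].
* **vBMD** (mg/cm^3): the linear asynchronous calibration
  `slope * HU + intercept`. The coefficients are scanner properties supplied
  in the configuration, not estimated here.
* **Mask means**: per-vertebra values are unweighted arithmetic means over
  the selected compartment of the label mask — the whole vertebral body
  ("integral", labels >= 1) or the trabecular interior (label 2). An empty
  selection excludes the vertebra from downstream tables with a logged
  reason; nothing is imputed. Masks that touch the volume boundary are
  excluded the same way, since a clipped vertebra would bias both means and
  texture.

Note that PDFF is computed voxelwise *before* averaging; because the ratio
is nonlinear in (F, W), averaging the signals first gives a different answer
whenever the total signal varies across the mask. The test suite pins this
down with an explicit counterexample.

## Texture features

The feature menu has three tiers, computed inside the vertebral-body mask:

* **Global** (3): variance, skewness, and excess kurtosis of the raw
  in-mask intensities, with population moments (denominator `N_v`). A
  constant region scores (0, 0, 0) by convention.
* **GLCM** (8): Energy, Contrast, Entropy, Homogeneity, Correlation,
  SumAverage, Variance, Dissimilarity of the gray-level co-occurrence
  matrix.
* **GLRLM** (13): SRE, LRE, GLN, RLN, RP, LGLRE, HGLRE, SRLGLE, SRHGLE,
  LRLGLE, LRHGLE, GLV, RLV of the gray-level run-length matrix.

CT-based analysis carries all 24; the PDFF-based analysis carries the 11
global + GLCM features. Feature names are prefixed `CT_` / `PDFF_` in every
table.

### Quantization

GLCM and GLRLM require discrete gray levels. Radiomics pipelines almost
universally use fixed-bin-count min–max binning, and that is what
`quantize()` does: the in-mask range [min, max] is split into `N_g`
equal-width bins (default `N_g = 32`, configurable), the maximum falls in
the top bin, and a constant region maps to level 1. This makes every
GLCM/GLRLM-derived feature invariant under affine rescaling of the raw
intensities — deliberate, since absolute HU offsets differ by scanner. The
global features, by contrast, are computed on the *raw* intensities and are
not scale-invariant; that is their point.

### The 13-direction geometry

On a 3D lattice each voxel has 26 neighbors; identifying each offset `d`
with `-d` (a co-occurrence pair or a run is the same object read in either
direction) leaves 13 direction classes: 3 axis-aligned of length 1, 6 face
diagonals of length sqrt(2), 4 space diagonals of length sqrt(3) (voxel
units). Per direction, the GLCM counts all in-mask voxel pairs at that
offset, is symmetrized by transpose addition, and normalized. The 13
matrices are then *averaged into one matrix* before features are computed;
the GLRLM run counts are *summed* across directions. Averaging matrices
rather than features is the default; per-direction feature averaging is
available as `glcm_mode = "average_features"` for sensitivity analysis.
Because the 13-direction set is closed under the 48 lattice symmetries
(axis permutations and reflections), every feature is invariant under them;
the acceptance suite verifies this to 1e-10 relative.

Diagonal steps are physically longer than axis steps. When directions are
merged, each direction's contribution is weighted by `1/||d||` (default,
switchable), which equalizes contribution per unit physical length rather
than per lattice step. With weighting off, the merge is uniform.

Pairs and runs never cross the mask boundary and there is no padding:
vertebral ROIs are closed regions and boundary bleed would mix tissue
classes. Offsets are taken in voxel units on the native grid; anisotropic
voxels are not resampled, since interpolation would manufacture texture.

### Numerical conventions

Several conventions must be fixed for reproducibility and are all
configurable where noted: GLCM entropy in bits (`log2`; `entropy_base`),
excess kurtosis (Gaussian = 0), population (biased) moments, GLCM
Correlation defined as 0 when a marginal is degenerate, and GLV/RLV as
run-probability-weighted variances (the matrix-cell-normalized variant used
by some toolboxes is available as `glv_variant = "count_normalized"`). Run
percentage divides the (possibly weighted) run count by `N_v` times the
total direction weight, so an unweighted single-direction matrix keeps
RP in (0, 1].

## The synthetic cohort generator

`generate_cohort()` emulates the *statistical* structure of a two-group
thoracolumbar cohort, not vertebral anatomy. Defaults describe the study
conditions the analysis targets:

| parameter | default | meaning |
|---|---|---|
| `n_patients`, `levels_per_patient` | 26, 7 | 182 vertebrae |
| `fracture_fraction` | 11/26 | patient-level fracture prevalence |
| `mean_vbmd_by_group` | 153.1 / 218.5 mg/cm^3 | fracture vs control |
| `patient_sd`, `vertebra_sd` | 40, 15 mg/cm^3 | within-group spread (combined ~43) |
| `mean_pdff_by_group` | 55 / 40 % | marrow fat, higher with fracture |
| `pdff_patient_sd`, `pdff_vertebra_sd` | 8, 3 pp | realistic marrow-fat variation |
| `mean_t2star_by_group` | 18 / 14 ms | longer T2\* with less trabecular bone |
| `texture_sd_by_group` | 45 / 25 HU | heterogeneity, higher with fracture |
| `correlation_length_mm` | 4 mm | spatial scale of the texture field |
| `hu_calibration` | slope 0.8, intercept 0 | vBMD = 0.8 HU |
| `noise_sd` | 10 HU | voxelwise white noise |
| `volume_shape`, `voxel_spacing_mm` | 18x18x14, 1.8 mm | one vertebra per volume |

Fracture status is a patient-level Bernoulli draw; all of a patient's
vertebrae inherit the group's field parameters, mirroring a patient-level
binary outcome analyzed per vertebra. Each scalar field is a group mean
plus patient and vertebra random effects, plus a stationary correlated
texture field, plus white noise. The texture field is white noise smoothed
by a separable Gaussian kernel of width `correlation_length_mm`, then
centered within the mask and rescaled to the group's `texture_sd` — the
simplest stationary field with tunable heterogeneity, which is precisely
the property texture features must detect. The same construction drives the
PDFF map with a fixed scale of 0.1 percent points per HU of texture sd,
keeping PDFF inside [0, 100]. Water and fat signal volumes are constructed
from the PDFF field against a constant total signal, so
`100 * F / (F + W)` reproduces it exactly; T2\* is simulated directly as a
map. The phantom is an ellipsoid (integral label) whose two-step 6-connected
morphological interior forms the trabecular label; vertebra "levels" are
separate volumes because the analysis is strictly per-vertebra after
segmentation.

Group contrasts for vBMD and its within-group spread are anchored to the
two-group summary statistics the analysis is meant to reproduce; PDFF, T2\*
and texture contrasts have no published quantitative anchor and were fixed
once at values a musculoskeletal imaging scientist would call realistic
(marrow fat higher and more variable in fracture patients; heterogeneity
nearly twice as high). An earlier draft used a 2-pp within-group PDFF
spread, which made PDFF an almost perfect group classifier and pushed the
quantitative-only fracture model toward an adjusted R^2 of 0.95 —

unrealistically separable; the current 8-pp patient-level spread restores
overlap typical of in-vivo cohorts.

What the phantom deliberately does *not* model: vertebral shape and
cortical-shell geometry, fracture deformity, scanner physics and k-space
artifacts, field-of-view truncation, and any CT–MRI misregistration (both
modalities share one grid per vertebra). Consequently, passing tests show
that the pipeline measures what it claims on fields with known structure —
not that the synthetic effect sizes match any in-vivo population. In
particular, on the phantom the texture-augmented fracture models reach
adjusted R^2 near 1, because a global-variance feature reads the group's
heterogeneity parameter almost directly; in vivo the corresponding gain is
large but far from perfect separation. The tests therefore assert
*direction* (texture adds explanatory power) and operating characteristics,
never the printed effect sizes.

## Statistical pipeline

Group comparisons use a Mann–Whitney U test with midrank ties. For combined
sample sizes up to 12 the two-sided p-value is exact by enumeration of all
group assignments (valid under ties); beyond that, a normal approximation
with tie-corrected variance and continuity correction is used. At two
samples of size 8 the approximation stays within 0.011 of the exact
enumeration; at smaller sizes the exact branch is always taken, which is
why the crossover is placed at 12.

The regression engine is ordinary least squares with stepwise selection
around *forced* adjustment covariates (age, sex, and — for vertebra-wise
models — the vertebral level as a single ordinal 1–17 covariate; 17 dummies
would be unstable at ~170 observations, and a categorical option exists).
Candidates enter by smallest partial-t p-value below `p_enter = 0.05`; the
removal threshold `p_remove = 0.10` follows the common stepwise convention
and is configurable (only the entry rule has a stated precedent). Ties
break by smaller p, then larger |t|, then name order, making the final
model independent of candidate ordering. Binary fracture status is fitted
as a *linear probability model* — the analysis this package reproduces
explicitly used linear regression on the binary outcome — with logistic
regression available but off by default. Perfectly collinear candidates are
skipped and logged; an exact fit reports adjusted R^2 = 1 with p-values
flagged undefined. Adjusted R^2 is the closed form
`1 - (1 - R^2)(n - 1)/(n - k - 1)` with `k` the number of estimated
regressors excluding the intercept; "the number of independent variables"
as an adjustment factor is interpreted as exactly this penalty, not as a
fittable covariate.

The model suite fits three families: (1) integral vBMD on the CSE-MRI
predictors (PDFF, T2\*, PDFF texture) at vertebra level; fracture status on
(2) the quantitative triple and (3) the quantitative triple plus all 35
texture features, each at vertebra level (every vertebra a data point,
patient covariates replicated, no clustering correction — a deliberate
replication of the source design, flagged here) and at patient level (all
quantitative columns averaged per patient first). The headline comparison
is the paired adjusted R^2 of (2) vs (3) at each level.

Vertebra-level replication of a patient-level outcome inflates the
effective sample size; a mixed-effects or cluster-robust treatment is the
statistically stricter choice and is intentionally out of scope, because
the target analysis pools vertebrae as independent points.

## Problem sizes and reproducibility

The default cohort (26 x 7 vertebrae, 18x18x14 voxels) runs the full
simulate–extract–model pipeline in about two minutes on one core.
Property-style checks use smaller, faster configurations chosen as the
package's own test sizes: texture oracles on 200 random lattices up to 4^3
with 4 gray levels (where exhaustive pair enumeration and run scanning are
feasible as independent oracles); rotation invariance over all 48
symmetries of a 7^3 masked volume; stepwise operating characteristics at
n = 200 with 100/500/1000 replicates (recovery, CI coverage, null entry
rate); and the texture-augmentation direction on 20 replicate cohorts of
16 patients x 4 levels on 14x14x12 grids. All randomness flows from
explicit seeds: the cohort generator derives a per-vertebra substream from
the master seed, so regenerating any vertebra is order-independent, and
identical configurations reproduce byte-identical artifacts. Every run
directory carries a provenance file with the configuration echo, its hash,
the seed and the package version; two runs with different texture settings
never share a hash.

## Known limitations

* The phantom's texture contrast is a free parameter; no published value
  constrains it, so synthetic effect sizes are illustrative.
* Texture features are computed on the native grid; strongly anisotropic
  voxels make the diagonal directions anisotropic too, mitigated but not
  removed by 1/length weighting.
* The linear probability model can predict outside [0, 1]; it is kept for
  fidelity to the reproduced design.
* `N_g` and the exact GLV/RLV normalization of the original toolbox are
  unknown; both are configurable and the defaults follow the dominant
  radiomics conventions.
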