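# bagpipe

Brain-age-gap (BAG) estimation and explanation for volumetric brain
images, as a tested, reusable R pipeline.

## The problem

Structural brain aging can be summarized by training a regression model
that predicts chronological age from a T1-weighted brain volume in
healthy subjects, then applying it to a patient cohort. The **brain age
gap**

&nbsp;&nbsp;&nbsp;&nbsp; *BAG = predicted age − chronological age*

is positive for an "older-appearing" brain and behaves as a compact
neurodegeneration biomarker: in relapsing-remitting multiple sclerosis
(MS), mean BAG is several years above that of healthy controls. Beyond
the scalar gap, clinicians want to know *where* the model looks:
SmoothGrad saliency maps, aggregated per anatomical region against a
parcellation, identify the ventricles and peri-ventricular structures as
the drivers of the prediction.

`bagpipe` implements the full analysis:

1. **Phantom generator** — synthetic, skull-stripped, template-space
   brain phantoms whose morphology (ventricle size, cortical thickness)
   is a deterministic function of *effective age = age + offset*, with an
   MS condition that adds a known brain-age offset and focal
   white-matter lesions at CSF-like intensity. Because the offset is
   known exactly, model recovery is verifiable end to end without any
   clinical data.
2. **Preprocessing** — zero-mean intensity rescaling over the brain
   mask and population-wide background cropping (bounds frozen on the
   training split), plus QC-exclusion bookkeeping.
3. **Age model** — a 3D CNN regressor:
   `[conv 3×3×3 → batch-norm → max-pool 2×2×2 → ReLU] × B` (default
   filters 32/64/128/256/256), a 1×1×1 conv block (64 filters), global
   average pooling, dropout 0.5 and a linear head. Trained with Adam
   (lr 0.001, weight decay 0.0003, batch 8), ±5-voxel translation
   augmentation on 50% of samples, 75/22.5/2.5 stratified splitting by
   (age bin × sex), best-validation-MAE checkpointing. The forward /
   backward / input-gradient engine is implemented in
   RcppArmadillo (im2col + BLAS) and validated against finite
   differences.
4. **BAG statistics** — MAE, mean BAG ± SD, Bland-Altman limits of
   agreement (mean ± 1.96 SD), exact-enumeration and
   normal-approximation Mann-Whitney U, Spearman ρ (t approximation, or
   exact permutation for n ≤ 10), partial Spearman ρ (rank
   residualization, controlling e.g. age and sex), Bonferroni
   correction, and the grouped clinical-variable tables.
5. **Saliency analysis** — SmoothGrad (mean |∂ŷ/∂x| over noisy copies),
   linear [0, 255] mapping, bottom-5% denoising, **weighted regional
   saliency scores** (coverage % × min-max-scaled mean intensity),
   sex-balanced group-averaged binary maps per age band, Dice overlap,
   and per-region Mann-Whitney comparisons at the Bonferroni-corrected
   threshold.
6. **Pipeline** — configuration-driven orchestration with derived
   per-stage seeds, NIfTI-1 + TSV artifacts and a JSON run manifest.

## Worked example (desk scale, ~5 minutes on 1 CPU)

```r
library(bagpipe)
st <- run_study(study_config("tiny", seed = 1))
print(st)
```

```
<bag_study preset=tiny seed=1>
  healthy test: MAE 0.82 y, mean BAG -0.68 (SD 0.84), n=6
  disease:      MAE 7.77 y, mean BAG 7.77 (SD 2.46), n=60
  MS vs healthy BAG Mann-Whitney p = 6.23e-05
```

The tiny protocol trains the small CNN (filters 8/8/16/16, 40 epochs) on
300 healthy phantoms (ages 20–89, 32³ voxels) and applies it to 60 MS
phantoms whose true injected offset is ~Normal(8, 2) years. The model
recovers the offset: mean MS BAG 7.77 y against a true mean offset of
7.85 y, while the healthy test split stays near zero — the synthetic
analogue of an MS cohort appearing ~7 years older than its chronological
age. `st$region_comparison` ranks regions by mean weighted saliency
score; the lateral ventricles dominate and differ between cohorts at the
Bonferroni threshold (right lateral ventricle p ≈ 3.5e-4 < 0.05/10), and
`st$dice_table` shows each MS band overlapping older healthy bands more
than its own age band. File-based runs with on-disk artifacts:

```r
run_pipeline(study_config("tiny", seed = 1), "out/")
```

## Layout

```
R/                 phantom.R, preprocess.R, model.R, bag_stats.R,
                   saliency.R, pipeline.R, nifti.R, volume.R
src/cnn3d.cpp      3D CNN engine (im2col + BLAS, full backprop)
tests/testthat/    unit + property tests, test-acceptance.R
scripts/acceptance.R
vignettes/methods.Rmd
```
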