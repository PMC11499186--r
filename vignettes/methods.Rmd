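---
title: "Brain-age-gap estimation with bagpipe: models, phantoms, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Brain-age-gap estimation with bagpipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model and its assumptions

`bagpipe` estimates a subject's *biological brain age* with a 3D
convolutional regressor trained on healthy subjects only, under the
assumption that for healthy subjects biological age equals chronological
age. The **brain age gap** is

$$\mathrm{BAG} = \hat{y} - y,$$

predicted minus chronological age, so positive values mean an
older-appearing brain. (Some texts verbally define the gap the other way
around while still reporting disease cohorts with *positive* gaps; we fix
the sign by the reported numbers and state it everywhere.)

The architecture is the SFCN-style stack: $B$ blocks of
[conv $3^3$ (same padding) → batch-norm → max-pool $2^3$ → ReLU], a
$1\times1\times1$ conv block, global average pooling, dropout 0.5 and a
linear head. The full-scale default uses filters 32/64/128/256/256 with a
64-filter projection block ("seven blocks" = 5 conv-pool + projection +
head). The description we follow lists six filter counts for "the first
five blocks"; we resolve that internal inconsistency in favor of five
conv-pool blocks, with the counts configurable. Training follows the
reference protocol: Adam, learning rate $10^{-3}$, weight decay
$3\times10^{-4}$, batch size 8, 300 epochs, mean-absolute-error loss
(the loss is unstated in the source; MAE matches the validation-MAE
selection criterion; MSE is available), ±5-voxel random translations
applied to 50% of training samples and re-drawn every epoch, and the
checkpoint
with the best validation MAE is kept. "Weight decay" is implemented as
decoupled (AdamW-style) decay on convolution/dense weights only, since
the original framework's variant is unstated.

Splits are stratified by (10-year age bin × sex) at 75/22.5/2.5% with
largest-remainder rounding per stratum (ties to the larger fraction, so a
singleton stratum trains).

There is no deep-learning framework in the supported R stack, so the
engine (forward, backward, input gradients) is written in RcppArmadillo
with im2col + BLAS convolutions. Every gradient path is tested against
central finite differences to $<10^{-5}$ relative error; all randomness
(initialization, shuffling, dropout masks, augmentation shifts, SmoothGrad
noise) is drawn on the R side from configured seeds, so runs are exactly
reproducible and independent of thread count.

# The phantom generator: a stated world

Real brain-age studies need thousands of T1-weighted MRIs that cannot be
shipped with a package. The generator replaces them with template-space
phantoms whose aging signal is known *exactly*:

* geometry: an outer brain ellipsoid, a cortical ribbon, bilateral
  lateral-ventricle ellipsoids, midline third/fourth ventricles,
  bilateral subcortical nuclei; T1-like contrast CSF (40) < GM (100) <
  subcortical (110) < WM (140), arbitrary units;
* aging: a single **effective age** $a_e = a + \Delta$ (chronological age
  plus disease offset) drives morphology — ventricle radius
  $2.0 + 0.04\,a_e$ reference voxels (strictly increasing), cortical
  thickness $\max(3.2 - 0.02\,a_e,\,0.8)$ (non-increasing). The rates are
  artifact conventions chosen so the morphology range over ages 20–90 is
  well resolved on a $32^3$ grid; no quantitative atrophy-rate claim is
  inherited from the literature;
* disease: the MS condition adds the offset $\Delta \sim$
  Normal(8, 2) years truncated at 0 and $\mathrm{round}(0.75\,\Delta)$
  focal white-matter lesions at CSF-like intensity ("black holes");
* noise: additive Gaussian, sd = 5% of WM intensity, inside the brain
  only (background stays exactly 0, as for skull-stripped inputs);
* cohorts: healthy ages uniform 20–89, MS ages uniform 20–60 (the
  patient cohorts this emulates are working-age adults); sexes alternate
  within cohorts so age bands stay sex-balanced. Sex affects metadata
  only, not morphology.
* covariates: documented generative equations give lesion volume
  increasing in $\Delta$, BPF decreasing in $a_e$, EDSS noisily
  increasing in $\Delta$, disease duration $\approx 1.1\Delta$ with
  onset = age − duration — the qualitative correlation structure of a
  real MS cohort table, with magnitudes matched to its medians.

What a green test does **not** establish: anything about MRI physics
(bias fields, motion, scanner effects), registration error, real
atrophy rates, or sex dimorphism — none of which are modeled. The
phantoms exist to verify the *pipeline machinery*: that the CNN recovers
a known offset, that saliency localizes a known signal, and that the
statistics behave as specified.

Because morphology is deterministic given effective age, voxelized
ventricle volume is non-decreasing at fine (2-year) steps, strictly
increasing across decades, and Spearman-correlates with age at ≈ 0.998
across a cohort — the "monotone encoding" invariant.

The parcellation is built from reference geometry: ventricular parcels
use the oldest (effective age 90) extent and the cortical ribbon the
youngest, so each subject's structures nest inside their parcel across
the whole modeled age range. Label 0 is background; labels partition the
grid.

# Preprocessing

Intensity rescaling subtracts the mean over the brain mask (non-zero
voxels of the skull-stripped volume); variance scaling is off by default
(`scale_unit_sd` exists) because the reference protocol states zero-mean
only. Population cropping takes the tightest box containing the union of
non-zero voxels; bounds are computed on the *training* split and applied
frozen to validation/test/disease volumes (the source does not state
which population defined its crop; freezing on training data avoids
leakage and shape mismatch). Indexing is 0-based, half-open.

# Saliency analysis

SmoothGrad averages $|\partial\hat{y}/\partial x|$ over `n_samples = 25`
noisy copies with noise sd = 10% of the volume's intensity range
(hyperparameters unstated in the source; these are common SmoothGrad
practice and are exposed as arguments). Maps are linearly mapped to
[0, 255] (constant maps become zeros), denoised, and scored per region:
coverage% (non-zero voxels / region voxels) × a min-max-scaled weight of
the region's mean intensity. If all region means are equal, all weights
are set to 1 so coverage information survives the degenerate min-max.

**The "bottom 5%" decision.** "Thresholding out the bottom 5% of voxel
intensity values" admits two readings: (a) the 5th percentile of voxel
values, or (b) 5% of the intensity range. Gradient maps are heavy-tailed:
reading (a) removes only 5% of voxels, leaving ~dense maps whose
binarized group averages cover the whole brain and push every Dice
overlap to ≈ 0.99 — no band structure can emerge, contradicting the
reference report of Dice 0.83–0.93 with a clear age ordering. Reading
(b) removes the large mass of near-zero voxels, leaving the sparse
salient support (~20% of brain voxels in our runs) from which the
reported Dice range and ordering actually reproduce. We therefore
default to the **range** reading and keep the percentile reading
available (`denoise_threshold(mode = "percentile")`); both are
scale-invariant.

Group maps average the thresholded maps of a sex-balanced random sample
per cohort × age band (<30, 30–39, 40–49, 50–59) and binarize (non-zero
→ 1). The reference sizes are 10 per sex (5 per sex for the <30 band);
the desk-scale protocol uses 5 per sex in every band because a 60-subject
disease cohort cannot fill 10+10 inside one decade. The order
(threshold each subject map → average → binarize) is the package
default; thresholding after averaging is reachable by composing the
exported operations.

The per-region group comparison (two-sided Mann-Whitney on weighted
scores at the $\alpha/\#\text{regions}$ Bonferroni threshold, regions
ranked by healthy-group mean score) restricts the healthy group to the
disease cohort's chronological age range, as in the reference analysis.
At desk scale the held-out split alone (≈ 45 subjects under 60) is
underpowered for this comparison, so the protocol draws the healthy
comparison group from *all* healthy subjects in that age window
(n ≈ 175); saliency is computed with the same trained model either way,
so no label information leaks into the comparison. Localization
("ventricle parcel in the top 3 weighted scores"), in contrast, is
evaluated on held-out subjects only, and "ventricle parcel" means the
better-ranked of the two lateral-ventricle parcels.

# Statistics

* Mann-Whitney U: exact mode enumerates all $\binom{n+m}{n}$ label
  assignments over pooled midranks, two-sided p = probability mass with
  $|U - nm/2|$ at least as extreme as observed (ties handled by
  enumeration); auto-selected for $n+m \le 16$. The approximation uses
  the tie-corrected normal with continuity correction and agrees with
  the exact test to $|\Delta p| < 0.01$ at $n = m = 20$.
* Spearman ρ uses midranks; p from the t approximation with $n-2$ df;
  exact permutation p available for $n \le 10$.
* Partial Spearman: ranks for x, y and numeric covariates (binary
  covariates, e.g. sex, enter as 0/1), least-squares residualization
  with intercept, Pearson correlation of residuals, t test with
  $n - k - 2$ df. With no covariates this reduces to Spearman at machine
  precision. The construction is stated explicitly because "partial
  Spearman" is not standardized.
* Bland-Altman: limits = mean ± 1.96 × sample SD of (predicted −
  chronological); Monte-Carlo coverage 95% ± 0.7% at n = 10,000.
* IQR is reported as Q3 − Q1 with linear-interpolation quantiles.
* Bonferroni: threshold $\alpha/m$; with 102 atlas regions this is the
  0.05/102 ≈ 0.00049 threshold of the reference analysis.

Age-bias correction of the BAG (over/underestimation at extreme ages) is
deliberately not implemented, matching the reference analysis' own
omission.

# The desk-scale ("tiny") protocol

The full-scale protocol (5,294 subjects, $162\times198\times164$ voxels,
GPU training) is not reproducible on one CPU, so acceptance is
property-based at desk scale: 300 healthy + 60 MS phantoms at $32^3$,
filters 8/8/16/16 with a 16-filter projection block, 40 epochs,
max shift 2 voxels (±5 would push brain tissue out of a ~28-voxel
cropped frame), learning rate 0.003. The learning rate is the one tiny
hyperparameter not inherited: $10^{-3}$ with MAE loss undertrains the
small model within 40 epochs (validation MAE still falling linearly);
0.003 converges smoothly, 0.01 oscillates — a standard convergence
check, fixed before the acceptance outcomes were evaluated.

Expected behavior (asserted in `test-acceptance.R`): healthy-test mean
BAG within ±2 y; MS mean BAG in [5, 11] y (true mean offset 8 y);
MS > healthy by Mann-Whitney at p < 0.01; ventricle parcel in the top 3
weighted scores for ≥ 80% of held-out phantoms; a lateral-ventricle
region significant at the Bonferroni threshold; and
dice(MS 30–39, healthy 50–59) > dice(MS 30–39, healthy <30) in ≥ 4 of 5
replicates at pre-registered seeds (1, 101, 201, 301, 401). Replicates
2–5 retrain from scratch; their saliency stage computes only the band
maps that the Dice criterion uses, to respect the suite's runtime
budget. Which individual region carries the significance varies with
the training seed (the small CNN may attend more to the left or right
ventricle); the protocol's fixed seed makes the assertion reproducible.

# Numerical choices and degenerate inputs

* Batch-norm: biased batch variance, eps $10^{-5}$, momentum 0.1;
  inference uses running statistics, dropout is disabled — predictions
  are batch-composition invariant (asserted to $10^{-4}$).
* Max-pool uses floor semantics (trailing odd slices dropped), matching
  the reference down-sampling arithmetic (162 → 81 → 40 → 20 → 10 → 5).
* MAE loss at zero residual uses sign(0) = 0.
* The head bias initializes to the mean training age; with MAE loss and
  sign gradients the bias would otherwise take hundreds of epochs to
  reach the age scale.
* Constant saliency maps rescale to all-zero (not all-255): an
  uninformative map should not claim full coverage.
* Thin midline phantom structures clamp their semi-axes to ≥ 0.75 voxel
  so they remain representable on small test grids.
* `mann_whitney_u` on zero-variance pooled data returns p = 1.

# Known limitations

* The phantom world is geometric; regional findings are artifact
  analogues of the ventricular/peri-ventricular findings, not anatomical
  claims, and the synthetic parcellation (10 regions) only approximates
  the granularity of a 102-region atlas.
* The full-scale preset is provided but untested at scale in this
  repository (no data, no GPU); its arithmetic (shapes, parameter
  counts, split fractions) is tested.
* Non-linear warping of saliency maps to atlas space is a no-op for
  phantoms generated in template space; real data would need a
  resampling step in its place.
* Exact Mann-Whitney enumeration is exponential; it is auto-capped at
  pooled n ≤ 16.
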