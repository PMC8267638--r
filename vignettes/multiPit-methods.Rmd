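---
title: "Morpho-molecular classification of pituitary tissue with multiPit"
author: "multiPit authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morpho-molecular classification of pituitary tissue with multiPit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multiPit)
```

## The problem

Pituitary adenomas must be distinguished from healthy gland tissue during
surgery, and their hormone-lineage subtype (lactotroph, null cell,
gonadotroph, somatotroph/mammosomatotroph, corticotroph) informs treatment.
Label-free optical imaging offers a two-level route:

1. **First level (morphological/textural):** co-registered OCT, TPEF, SHG
   and MPM image planes are described by radiomic texture features and a
   binary gland-vs-adenoma classifier.
2. **Second level (molecular):** line-scan Raman microspectra are
   preprocessed and fed to a PCA-SVM classifier for six-class subtyping,
   with band-intensity ratios as interpretable biomarkers.

A metabolic axis — the corrected optical redox ratio NADH/(NADH+FAD) from
the two TPEF channels — and the Raman ratios are combined with the binary
classification score into a five-axis "fingerprint" per tissue class.

Real biopsy data of this kind are not openly distributed, so the package
ships a synthetic cohort generator that emulates the documented structure
of such cohorts and carries full ground truth. Every downstream stage is
exercised and tested against that generator.

## The synthetic cohort generator

`generateCohort()` produces the default study composition: 174 image
planes — 25 gland planes from 5 biopsies and 149 adenoma planes from 25
biopsies (5 subtypes x 5 biopsies) — plus one Raman line-scan map per
biopsy. Each `TissueClassSpec` holds the per-class ground truth:

* **Morphology.** Gland planes contain a Poisson-distributed number of
  cell nests (default mean 12): clusters of bright TPEF cell discs
  enclosed by annular SHG connective rims (default 3 px). Adenoma planes
  are a homogeneous point process of single-cell discs, lightly blurred,
  with no scaffold; the gonadotroph-like class adds elongated anisotropic
  SHG ridges (elongation factor 4) mimicking papillary connective
  structures. The OCT channel is a smoothed density map of the TPEF+SHG
  content with multiplicative unit-mean gamma speckle (shape 16),
  reflecting refractive-index-driven contrast. Planes default to
  128 x 128 pixels.
* **Metabolism.** Each plane draws a ground-truth redox ratio from
  N(redox_mean, redox_sd), with per-class means/sds
  0.40/0.11 (gland), 0.74/0.08 (lactotroph), 0.85/0.08 (null cell),
  0.57/0.05 (gonadotroph), 0.77/0.09 (somatotroph/mammosomatotroph),
  0.86/0.10 (corticotroph). The clean TPEF signal is split into NADH and
  FAD channels at exactly that ratio, so at zero noise the masked-mean
  estimator recovers it exactly.
* **Molecular content.** Raman spectra are sums of Gaussian bands at the
  catalog centers (width 8 cm^-1; 12 cm^-1 for the 2873/2940 C-H
  stretches) on a positive degree-5 polynomial fluorescence baseline,
  with class-dependent amplitudes chosen so that the three diagnostic
  ratios order as reported for this tissue system: proteins/collagen
  I(1660)/I(1335) elevated in every adenoma subtype, lipids/DNA
  I(1445)/I(720) elevated in all subtypes except the corticotroph-like
  one (which matches gland), and lipids/carotenoids I(1445)/I(1520)
  lower in adenomas.

**Identities.** By construction MPM = SHG + TPEF and TPEF = NADH + FAD
hold exactly on every plane, and identical (spec, seed) pairs give
bit-identical output.

**Noise models.** Image channels receive signal-scaled Gaussian noise
(sd = noise_sd x sqrt(intensity), shot-noise-like, as appropriate for
photon-counting detectors). This choice matters: additive noise of fixed
sd on a dim channel (e.g. FAD at high redox ratios) combined with
clipping at zero would inflate that channel's mean and bias the redox
ratio toward 0.5; with signal-scaled noise the clipping shift is
negligible and recovery is unbiased. Raman spectra use additive Gaussian
noise clipped at zero plus a per-position log-normal intensity factor;
their fluorescence baseline keeps intensities far from zero, so clipping
is immaterial there. The default noise_sd of 0.05 is an easy,
well-separated regime — passing classification tests on it demonstrates
pipeline correctness, not expected clinical performance.

**What the generator does not emulate.** No optics (PSFs, speckle
statistics beyond the gamma model, depth attenuation), no co-registration
error, no intra-class biological heterogeneity beyond the sampled
parameters, no label noise. Real-data performance cannot be inferred from
synthetic accuracies.

**Depth sampling** is configuration: the default composition records
planes at 30 um increments per biopsy, as the number of planes per biopsy
at specific depths is a free cohort parameter.

## Raman preprocessing

Per spectrum, in this order:

1. **Baseline removal** by iterative polynomial peak stripping
   (modified polyfit): fit a degree-5 polynomial, replace the working
   spectrum by the pointwise minimum of itself and the fit, refit until
   the maximum relative change drops below 1e-6 (cap 100 iterations).
   Order, tolerance and cap are configuration; degree 5 matches typical
   tissue fluorescence curvature. Two numerical properties are worth
   knowing: (a) the stripped baseline rides the lower noise envelope, so
   recovered peak heights carry a positive bias of roughly two noise
   standard deviations; (b) even on a spectrum with zero true baseline
   the algorithm subtracts its best-fit polynomial, leaving a relative
   bias of about 0.5% on normalized band intensities. Both are inherent
   to the standard algorithm and are asserted in the tests at their
   measured magnitudes.
2. **Savitzky-Golay smoothing** (window 9, order 3; endpoints by the
   filter's polynomial edge fits), which reproduces polynomials up to its
   order exactly.
3. **0-1 normalization to the C-H band**: subtract the spectrum minimum
   and divide by the minimum-subtracted mean intensity within +/-5 cm^-1
   of 2945 cm^-1, so min = 0 and the C-H window mean = 1. The divide-by-
   C-H reading (rather than divide-by-max) follows from anchoring the
   normalization to a named band; it makes the operation idempotent and
   scale/shift invariant. Degenerate spectra (C-H intensity at the
   minimum, e.g. all-zero rows) are excluded with their position indices
   logged, never fatal.

Band intensities anywhere in the package are means over +/-5 cm^-1
windows, not single samples, for robustness to grid alignment.

## Radiomic features

* **Masks.** `makeMask()` log-compresses intensities, median-smooths,
  separates the void background with a two-threshold Otsu rule (taking
  the lower cut), keeps the largest connected component and fills holes.
  A single Otsu threshold fails on gland planes: their histograms are
  trimodal (void / tissue / bright nests) and the single threshold lands
  inside the tissue; the lower of the two three-class cuts is the
  background boundary. Constant or threshold-emptied images fall back to
  an all-true mask with a warning.
* **Discretization.** Fixed bin width, per-image masked minimum as
  origin (shift-invariant), cohort-global width per modality chosen as
  the largest candidate at which no masked image in the cohort becomes
  single-bin. n_bins = ceiling(range/width) with the top edge clamped
  into the last bin — the convention under which a masked range exactly
  equal to the width counts as homogeneous.
* **Catalog.** 17 first-order, 21 GLCM and 16 GLSZM features per
  modality image (216 per plane across OCT/TPEF/SHG/MPM), including the
  six prominent ones for this tissue problem: GLCM joint entropy (OCT,
  TPEF) and GLSZM zone-size and gray-level non-uniformities (TPEF, MPM,
  OCT). GLCM pools the four unique distance-1 directions, symmetrized
  and normalized; GLSZM zones are 8-connected components of equal-bin
  masked pixels (labelled via the 8-neighbour adjacency graph).
  Entropies use log base 2. Both matrices are validated bit-exactly
  against brute-force oracles on all 19,683 ternary 3 x 3 images.
* **Redundancy reduction.** Greedy elimination at |Pearson r| >= 0.85:
  visit pairs by descending |r| (ties by column order), drop the member
  with the larger mean absolute correlation to the remaining features
  (ties: the later column). Constant columns are dropped first and
  logged. Fully deterministic.

## Binary classification

100-fold balanced Monte-Carlo cross-validation. The validation size
derives from the minority class: N_Minority = round(0.2 x 25) = 5, and
each fold's validation set holds exactly 5 planes from each of the six
subgroups (30 planes; 25 adenoma, 5 gland), the rest training. Folds are
unique as validation-ID sets. Per fold, strictly on training data:
R-squared (squared point-biserial correlation) ranking selects 10
features; Tomek links (opposite-class mutual nearest neighbours) remove
borderline majority samples; SMOTE balances the minority class by convex
interpolation between minority nearest neighbours; features are
z-scored with training statistics; and a soft-voting ensemble of three
random forests (depth-limited, depth-free, feature-subsampled; 100 trees
each) is trained. The untouched validation split is scored and confusion
counts are pooled across folds. Sensitivity refers to adenoma detection.

Two fold-stratification modes exist. The default draws N_Minority per
*subtype* (the composition above). The "binary" mode draws N_Minority
per binary class (5 gland + 5 adenoma), giving label-balanced validation
sets. The distinction matters for null calibration: under label
permutation any label-independent classifier scores the validation base
rate, which is ~0.86 in the subtype-stratified mode but exactly 0.5 in
the binary mode — so permutation-null tests run in binary mode. Folds
default to plane-level sampling (5 planes per subgroup cannot be a whole
6-plane biopsy); a biopsy-grouped mode is provided that samples whole
biopsies into validation and excludes surplus planes from training,
guaranteeing no biopsy straddles the split. Plane-level splits are
optimistic when planes within a biopsy are correlated; on real data the
grouped mode is the defensible choice.

## Redox and statistics

Channel intensities are masked means corrected by
laser_power^exponent x gain x detector_response, with exponent 2 by
default (two-photon excitation scales quadratically with power; a linear
mode is available). The ratio NADH/(NADH+FAD) is invariant to factors
common to both channels. Group statistics follow the field's protocol:
Shapiro-Wilk normality per class, then two-tailed Welch's t-tests of each
adenoma class against gland at alpha = 0.05; one-way ANOVA for the Raman
ratios. Degenerate inputs (identical constant groups) return the p = 1
convention with a log message rather than erroring.

## PCA-SVM subtyping

PCA retains the smallest number of components reaching 95% cumulative
explained variance (cap 20). The SVM is linear one-vs-one (the scores
are low-dimensional; an RBF kernel is available), cost 10, deterministic.
Reporting uses stratified 5-fold cross-validation at spectrum level with
the PCA refitted inside each training fold; a biopsy-grouped option
exists for the same leakage reason as above. One-vs-rest
accuracy/sensitivity/specificity are computed from the pooled confusion
matrix.

## Fingerprint

Per class: mean validated adenoma-probability from the MC folds, mean
redox ratio, and the three Raman ratio means. Axes are normalized by
their maximum over classes for the spider plot; raw values are stored
alongside, since axis scaling is a display choice. Report bundles embed
a config hash and the seed; equal inputs give byte-identical JSON.

## Problem sizes and determinism

The test-suite and acceptance-script runs use: the full 174-plane
cohort at 128 x 128; 50 Raman positions per biopsy map (1,500 spectra
per cohort) for ratio/ANOVA work; 500 spectra per class on a 2 cm^-1
grid for the six-class recovery benchmark; 100 MC folds for the headline
metrics and 20 folds x 20 permutations for null calibration; and 4
replicate cohorts of 25 planes/class for redox recovery (a single
cohort's class mean carries sampling noise of sd/5 ~ 0.022, so the
+/-0.03 recovery band is assessed on the replicate mean). All stages
take explicit integer seeds and derive child seeds arithmetically; equal
seeds give equal outputs to the byte.

## Known limitations

* Synthetic separability is by design; accuracies near 100% on the
  default regime validate mechanics, not clinical performance.
* The peak-stripping baseline has the documented ~0.5% normalized-
  intensity floor and a positive noise-scale bias on recovered peaks.
* The Welch-test power for the smallest class gap (gonadotroph vs gland
  at n = 5 per group, 0.57 +/- 0.05 vs 0.40 +/- 0.11) is 0.72 — a
  property of the test at those parameters, independent of any
  implementation.
* The feature catalog is a documented 216-feature set, not a clone of
  any proprietary radiomics engine; feature values are comparable only
  within this package.
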