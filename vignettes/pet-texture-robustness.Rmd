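---
title: "Methods: segmentation and observer robustness of PET texture indices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segmentation and observer robustness of PET texture indices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(pettex)
```

## The question the package answers

Texture indices computed on FDG PET tumor volumes summarize the spatial
arrangement of uptake — candidate markers of intratumoral heterogeneity in
head-and-neck squamous cell carcinoma. Their values, however, are conditioned
on two choices made before any biology enters: the delineation method that
produced the volume of interest (VOI), and the reader who produced it.
`pettex` implements the full measurement chain — image, VOI, gray-level
matrices, indices, agreement statistics — so that the sensitivity of each
index to those two choices can be quantified on simulated data whose ground
truth is known.

Because no public image archive accompanies the clinical problem, the package
treats the synthetic cohort as a first-class module: every distributional
choice made by the generator is documented here, and everything downstream of
it is tested against hand-computable oracles.

## The phantom model

A phantom (`phantom_spec()`, `generate_phantom()`) is built in a fixed order:

1. an ellipsoidal tumor indicator with semi-axes scaled to a target volume
   (`radii_for_volume()`), embedded in a background plateau;
2. a multiplicative textured component `1 + amp * G`, where `G` is a Gaussian
   random field (white noise filtered with a Gaussian kernel of the texture
   correlation length, then standardized over tumor voxels), floored at 0.1
   and rescaled so its maximum is 1;
3. an optional necrotic core: uptake inside a central scaled copy of the
   ellipsoid is pulled to 15% of its excess over background;
4. Gaussian partial-volume blur, after which the lesion excess over
   background is rescaled so the post-blur peak equals `suv_peak`;
5. additive Gaussian noise in SUV units, clamped at zero.

The post-blur rescaling in step 4 deserves a word: a clinical
signal-to-background ratio (SBR) is measured on the reconstructed image, so
the simulation targets the *measured* peak, not the underlying activity. The
homogeneous, unblurred limit is exact (every tumor voxel equals `suv_peak`),
which the tests use as an anchor.

Defaults and why:

| parameter | default | rationale |
|---|---|---|
| spacing | 4.07 × 4.07 × 2 mm | clinical PET reconstruction grid |
| background SUV | 1.0 | soft-tissue plateau |
| target SBR | 23.5 (cohort SD 7.4, floor 5) | reported head-and-neck lesion contrast |
| `heterogeneity_amp` | 0.6 | yields SUVmax/SUVmean ≈ 2 in the simulated lesions, the typical published HNSCC range |
| `texture_corr_len_mm` | 8 mm | heterogeneity structures larger than the PSF but smaller than the tumor |
| `blur_fwhm_mm` | 6 mm | total effective PET resolution; the clinical 2 mm post-filter alone would not produce realistic partial-volume behavior, and threshold methods only differ on blurred lesions |
| `noise_sd` | 0.15 SUV | ~15% background noise |
| necrotic core | fraction 0.4, probability 0.3 for tumors ≥ 8 ml | necrosis is a large-lesion phenomenon |
| grid | 36 × 36 × 56 | holds a 60 ml lesion plus the background shell used for SBR estimation |

A cohort (`generate_cohort()`, default n = 43) draws tumor volumes
log-uniformly over 1–60 ml, with a configurable fraction (default 0.3) drawn
below the 64-voxel analyzability floor so the exclusion accounting of a
clinical series — where a quarter to a third of lesions are too small for
texture analysis — is reproduced structurally. All per-patient seeds derive
from the cohort seed; regenerating with the same seed is bit-identical.

What the generator does **not** emulate: reconstruction (sinogram/OSEM)
noise correlations, respiratory motion, dental artifacts, nodal disease, or
any specific clinical SUVmax distribution. Passing tests therefore
demonstrate internal consistency and the direction of method effects on
smooth textured lesions, not clinical effect sizes.

## The three delineation methods

All methods operate inside a search sphere (default radius 60 mm) around the
observer's seed click, and all end with `select_representative_cluster()`:
26-connected labeling, keep the component holding the hottest voxel, ties to
the larger component, residual ties to the lowest label — a deterministic
reading of an operator choosing "by uptake intensity and volume".

**Fixed threshold.** Voxels with SUV ≥ 0.40 · SUVmax of the search region
(inclusive comparison). On lesions whose SUVmax sits well above the uptake of
the tumor bulk — i.e. on heterogeneous lesions — this cut lands above the rim
uptake and the method under-segments, which is exactly the clinically
reported behavior.

**Adaptive SBR threshold.** Starting from the 40% provisional mask, iterate:
estimate the SBR (mask SUVmax over the mean of a background shell 4–14 mm
beyond the mask), map it to a fraction `t = a/SBR + b` clamped to
[0.2, 0.8], re-threshold at `t ·` *mean VOI uptake*, re-select the cluster,
stop at a fixed point (or a 2-cycle, or after 10 iterations with a warning).

The reference intensity is the design decision that required genuine thought.
Calibrating any fraction-of-SUVmax law on noiseless uniform blurred spheres
forces the asymptotic fraction to ~0.5 — the half-maximum crossing of a
blurred step edge — and a 0.5 · SUVmax threshold applied to a *heterogeneous*
lesion sits above the 0.40 · SUVmax cut, making the "adaptive" method
systematically smaller than the fixed one. That contradicts how adaptive
methods behave on real tumors. Referencing the fraction to the mean uptake of
the current mask resolves the contradiction self-consistently: on uniform
calibration spheres mean ≈ max, so calibration still recovers true volumes;
on peaked lesions the mean sits well below SUVmax, the effective threshold
drops below 0.40 · SUVmax, and the adaptive VOI grows past the fixed one —
the sign observed clinically. This mean-referenced form is the package's own
design choice and is what `calibrate_adaptive_thresholds()` calibrates: for
each (volume, SBR) sphere phantom it bisects for the fraction whose fixed
point recovers the true volume, then fits fraction against 1/SBR by least
squares. Calibration residuals stay below 0.05 and held-out spheres of
8–40 ml are recovered within a few percent.

**Gradient edge.** Smooth (default 2 mm Gaussian), cast `n_rays` (default
256) quasi-uniform Fibonacci-lattice rays from the search region's hottest
voxel, sample radial profiles by trilinear interpolation at 0.5 mm steps, and
place the boundary on each ray at the *outermost* local minimum of the radial
derivative whose depth is at least half the strongest drop on that ray.
Taking the global extremum instead would lock onto internal texture
gradients, which on heterogeneous lesions can exceed the rim gradient; the
outermost-strong-edge rule recovers clean sphere radii within one voxel while
remaining usable on textured lesions. Rays without a falling edge fail; more
than 20% failures abort (a constant image has no boundary). Boundary radii
are interpolated over directions (inverse angular distance over the three
nearest rays), the interior is voxelized, closed morphologically (one
26-neighborhood dilation–erosion), and cluster-selected.

**Observer dependence.** Simulated observers differ only by a seed-click
jitter (uniform in a ball, default 4 mm, constrained to the tumor support).
Threshold methods are deterministic given the image, so their two-observer
ICCs are exactly 1 — mirroring the near-perfect threshold-method
reproducibility reported clinically. The gradient method orients its ray
lattice along the click-to-center axis, emulating the click/drag axis of
interactive gradient tools; jittered clicks therefore perturb the
reconstructed surface slightly, degrading gradient-method ICCs below 1 while
leaving SUVmax agreement perfect (every method's mask contains the regional
maximum by construction). With zero jitter the observers are identical end to
end and every ICC is exactly 1 — a structural test anchor.

## Discretization and the four matrices

Absolute resampling (`discretize_absolute()`): 64 levels over 0–30 SUV,
`level = 1 + floor(64 · (clamp(v) − 0)/30)`, values at or above 30 mapped to
level 64. Levels are 1-based so the low-gray-level emphases never divide by
zero. No spatial resampling is performed: matrices are built on the
anisotropic grid, as 2016-era clinical texture software did.

* **Co-occurrence (GLCM):** one matrix accumulated over all 26 ordered unit
  offsets (13 directions × both signs), then normalized. The aggregated
  symmetric reading was chosen over per-direction index averaging; the choice
  is isolated inside `build_glcm()` so the alternative is a contained change.
  Entropy uses log base 2 (bits); 0 · log 0 ≡ 0. Correlation is flagged
  missing (`NA`) when the marginal variance vanishes.
* **Run length (GLRLM):** maximal equal-level runs along each of the 13
  directions, aggregated into one matrix. Run Percentage divides by
  13 · n_voxels so it stays in (0, 1].
* **Neighborhood dependence (NGLDM):** the dependence matrix Q(i, k) counts
  voxels of level i with k equal-level in-mask 26-neighbors (edge voxels
  simply have fewer neighbors; no renormalization). Coarseness, Contrast and
  Busyness use Amadasun–King-style per-level totals of |level − mean neighbor
  level| on the same neighborhood. The literature normalizes these three
  indices inconsistently; the formulas used here are documented in
  `ngldm_indices()` and tested against the package's own oracles, with no
  claim of magnitude agreement with any specific clinical software (whose
  Busyness values are reported many orders of magnitude larger). Coarseness
  carries an epsilon guard (1e−6) so uniform VOIs stay finite; Busyness is
  flagged `NA` when its denominator vanishes.
* **Zone length (GLZLM):** zones are 26-connected components of equal-level
  voxels (Rcpp flood fill); indices share the run-length functional forms
  with Zone Percentage = zones / voxels.

Eligibility: texture extraction requires a single 26-connected VOI of at
least 64 voxels (2.12 ml at the clinical voxel size); smaller or fragmented
VOIs raise explicit errors, and the pipeline records them as exclusions.

Every builder is verified against literal nested-loop brute-force
enumerations on random ≤ 5×5×5 grids — the oracles live in the test helpers
and in the acceptance script, written independently of the vectorized
builders.

## Agreement analysis

* **Correlation screening:** pairwise-complete Pearson correlations over the
  31 indices; greedy complete-linkage grouping at |r| > 0.8 in inventory
  order (a feature joins a group only if it exceeds the threshold against
  *every* member); one representative per group (first member unless
  overridden); representatives with |r| > 0.8 against SUVmax or MTV dropped.
  Features flagged missing in more than half the VOIs are excluded with a
  warning before screening.
* **Bland–Altman:** bias = mean difference, limits = bias ± 1.96 SD (n−1).
* **Friedman / Wilcoxon:** delegated to `stats::friedman.test()` and
  `stats::wilcox.test()` behind the module surface; the Wilcoxon wrapper
  drops zero differences, uses the exact distribution up to 25 non-zero pairs
  and the corrected normal approximation beyond, and reports all-zero input
  as degenerate with p = 1. The Friedman wrapper maps the all-constant-rows
  NaN to statistic 0, p = 1. No multiple-testing correction is applied; raw
  p-values are reported.
* **ICC:** the form is fixed to ICC(2,1) — two-way random effects, absolute
  agreement, single measures — computed from the mean-squares decomposition.
  This is a documented choice for the two-reader design, not a claim about
  what any particular clinical study computed. Labels follow the Landis–Koch
  cut-points with "excellent" strictly above 0.8.
* **Sampling unit:** the correlation screening uses the complete-case
  patients, observer 1, with the three methods stacked; the variability table
  uses observer 1; the reproducibility table compares the two observers per
  method. Complete cases are patients analyzable under all three methods and
  both observers.

## The end-to-end study

`run_study()` binds the chain: calibrate the adaptive law (if no coefficients
are supplied) on spheres matching the cohort blur, generate the cohort,
segment 3 methods × 2 observers per patient, extract features, and compute
the tables. Failures at any stage are logged per (patient, method, observer)
and become exclusions rather than aborts. `report_tables()` writes the CSV
analogues of the result tables and base-graphics Bland–Altman plots (solid
bias line, dashed limits).

Problem sizes used by the tests and the acceptance script: the default
43-phantom study (about two minutes of compute), a 10-phantom zero-jitter
study for the perfect-agreement anchor, 16 calibration spheres plus 3
held-out volumes, and 100 random grids for the brute-force oracle suite.

Expected structure of the default seeded study, all computed at run time by
`scripts/acceptance.R`: roughly 26–28 of 43 patients survive all methods;
SUVmax ICC is exactly 1 under every method; at least one (in practice every)
gradient-method texture ICC falls below 1 while threshold-method ICCs remain
1; and the mean VOI volume is larger for the gradient and adaptive methods
than for the fixed 40% threshold (positive Bland–Altman biases), matching the
clinically reported direction.

## Known limitations

* The adaptive and gradient methods are faithful *descriptions of a class*
  of methods (background-dependent threshold; radial gradient maximum), not
  bit-level reimplementations of any proprietary tool.
* NGLDM index magnitudes are convention-dependent; only within-package
  comparisons are meaningful.
* Observer variability is reduced to click jitter; real readers also differ
  in cluster choice and manual edits, which the pipeline does not model.
* The generator's Gaussian noise is additive and spatially white, so
  noise-driven index behavior at very low counts is out of scope.
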