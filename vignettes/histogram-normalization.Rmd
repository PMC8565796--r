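---
title: "Histogram-based intensity normalization for voxel-wise brain PET analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Histogram-based intensity normalization for voxel-wise brain PET analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petnorm)
```

## The problem

[18F]-FDG PET measures glucose uptake, but the global intensity level of a
brain scan varies strongly between subjects and sessions: injected dose,
body weight, blood glucose, stress and scanner calibration all scale the
whole image up or down. Converting to standard uptake values,
SUV = C·W/D (activity concentration C times weight W over injected dose D),
removes only the dose-per-weight part; substantial global variability
remains. Voxel-wise statistics against a normal database are meaningless
until each image is divided by a per-subject scalar that puts all scans on
a common intensity scale.

The simplest data-driven scalar is the in-brain mean ("global mean
scaling"). Its weakness is well known: anything that shifts the mean —
most importantly a focal lesion — biases the factor, and the bias then
masquerades as diffuse uptake change everywhere else in the brain.

## The histogram-mode factor

This package implements the data-driven alternative in which each image is
divided voxel-wise by a population template, the in-brain ratios are
histogrammed, and the **most prevalent ratio** — the histogram peak — is
the normalization factor. For a subject whose image is (approximately) a
scalar multiple *k* of the template, the bulk of ratios piles up at *k*; a
focal lesion moves a minority of ratios into a tail without touching the
peak. The mode is therefore robust exactly where the mean is not.

Concretely, `normalization_factor_histogram()`:

1. divides the image by the template inside the brain mask
   (`ratio_image()`);
2. bins the ratios on a fixed grid (`bin_width = 0.01` over `(0, 3]` by
   default) and finds the raw mode, ties broken toward the lowest bin
   (`ratio_histogram()`);
3. fits a Gaussian `A exp(-(x-c)²/2s²)` by least squares to the counts in
   a ±0.15-ratio-unit window around the raw mode, and uses the fitted
   center `c` as the factor. The fit interpolates the peak to sub-bin
   precision; if it does not converge the raw mode bin center is used and
   the fallback is reported.

Whether "the maximum of the histogram" should be the raw mode or the
fitted peak center is genuinely open; we use the fitted center with a raw
mode fallback because it is deterministic, sub-bin accurate, and honest
about fit failure, and both values are exposed on the returned object.

The brain mask is always derived from the *template* — all voxels
strictly above 50% of the template maximum — never from the individual
image, so every subject is normalized over the same region. For atlas
construction the mask comes from the initial (unnormalized-average)
template; we keep that same mask for the downstream group statistics so
that all subjects and tests share one region.

## Atlas construction and CoV

`build_atlas()` runs the full pipeline: voxel-wise average of the
coregistered inputs (initial template) → 50% mask → per-subject factor by
the chosen method (`histogram`, `global_mean`, `none`) → voxel-wise mean
and standard deviation of the normalized images. The SD uses the sample
(n−1) denominator, since the atlas is an estimate of population
variability used to score new subjects. Because the initial template is
built from *unnormalized* images, an optional `iterations` argument lets
the mean image replace the template and the loop repeat; the default is a
single pass, and in practice the factors change by less than a bin width
on iteration because the template scale cancels out of every ratio.

Residual between-subject variability is summarized by the
coefficient-of-variation map, CoV = 100·σᵢ/μᵢ per voxel, and its in-mask
mean (`cov_map()`, `mean_cov()`). The better the normalization, the closer
the mean CoV falls to the irreducible voxel noise.

## Voxel-wise statistics

Group level: `group_ttest()` computes a pooled-variance two-sample t per
in-mask voxel (df = n₁+n₂−2; Welch optional), two-sided p-values, and
Benjamini–Hochberg FDR selection across all in-mask voxels at level q
(default 0.05). Significant voxels are split by sign into increase and
decrease masks, and the smallest significant |t| is reported as the
display threshold T_FDR. No cluster-extent correction is applied. Note
that when a real effect produces many discoveries, BH admits its nominal
share of false ones — with ~900 lesion voxels significant at q = 0.05, a
few tens of scattered false-positive voxels (of either sign) are the
*expected* behavior, not a defect.

Individual level: `zscore_map()` computes z = (xᵢ−μᵢ)/σᵢ against the atlas
and `threshold_zmap_95()` thresholds at the empirical 2.5th/97.5th
percentiles *of that map* (linear interpolation between order statistics,
R quantile type 7). This is deliberately a per-image empirical interval,
not ±1.96: it flags exactly the 2.5% lowest and 2.5% highest in-brain
values up to one-voxel rounding, so a healthy subject always shows a
sparse scatter while a lesioned subject concentrates its lower tail at the
lesion. Voxels with zero atlas SD are excluded with a reported count; if
all z values are tied the percentiles degenerate and the significance
masks are empty.

## The phantom generator

Real normal-brain PET populations cannot ship with the package, so all
validation runs on digital phantoms (`phantom_spec()`,
`make_template_phantom()`, `sample_population()`) built to emulate the
statistical structure the method assumes:

* **Geometry** — an ellipsoidal brain (semi-axes 12 × 8 × 7 mm) of three
  concentric uptake compartments (0.8 / 1.0 / 1.2 relative, innermost
  first) on a 10%-of-brain-mean background, in an 80³ grid of 0.4 mm
  voxels (a 32 mm field of view), blurred to 1 mm FWHM system resolution.
* **Global scale** — per-subject log-normal factor, sdlog 0.3, matching
  the ≈30% unnormalized between-subject CoV scale typical of SUV data.
* **Noise** — voxel-wise multiplicative log-normal noise with unit mean
  and CV 5%, applied after lesion insertion with no further blur, so
  images stay positive and the noise CV is exactly the nominal parameter.
* **Lesions** — a multiplicative factor (default 0.7, i.e. a 30% uptake
  drop) on a sphere clipped to the brain, so the lesion is a connected
  subset of the brain region.
* **Regional variability** — optionally, three *fixed* ellipsoidal
  regions (~5% of the brain each, ≤15% total) fluctuate coherently: every
  subject draws one independent log-normal factor (sdlog 0.35) per
  region.

The last point is the one genuinely open design choice and deserves its
rationale. If instead each subject perturbed a *randomly located* region,
the in-brain mean would absorb part of that perturbation and global-mean
scaling would actually *reduce* per-voxel variance — mean-based scaling
approximately minimizes average per-voxel variance under spatially
uncorrelated disturbances, and no CoV advantage for the mode could exist.
What makes global mean scaling worse in real populations is *coherent*
regional variability: the same structures (glands spill-in, extremes of
the uptake distribution) vary between subjects in every scan, so the mean
factor inherits their variance and spreads it multiplicatively over the
entire brain, while the mode ignores them. The fixed-region design
reproduces exactly that mechanism, and under it the mean in-mask CoV
orders histogram < global mean < none replicate after replicate.

What the phantoms do **not** emulate: PET physics (attenuation, scatter,
reconstruction artifacts), spatially correlated noise, anatomical
variability requiring non-linear registration, and partial-volume effects.
Passing tests therefore demonstrate the statistical behavior of the
normalization and inference machinery on ideally coregistered data, not
performance on raw scanner output; inputs to the real pipeline are assumed
already coregistered (the package offers only integer-voxel
center-of-mass alignment, `align_center_of_mass()`).

## Numerical choices

* Histogram bins: width 0.01 ratio units over `(0, 3]`; values outside the
  range are excluded and counted. A ~44,000-voxel mask occupies several
  hundred bins, plenty for a stable fit.
* Gaussian peak fit: Levenberg–Marquardt least squares, started at the raw
  mode with σ₀ = 0.05, bounded inside the fit window; convergence is
  reported, never assumed.
* Smoothing: separable Gaussian, σ_vox = FWHM/(2√(2 ln 2))/voxel size,
  kernel truncated at 4σ, reflective (edge-duplicating) padding — a
  constant image is unchanged and interior mass is conserved. The boundary
  rule is our choice; the source workflows do not state one.
* All internal arithmetic is double precision; NIfTI volumes are written
  as 32-bit floats. Voxel indices are 1-based (R convention) with axis
  order (x, y, z); cropped volumes carry a 0-based corner offset.
* Strict inequality in the 50% mask rule ("larger than"); a constant
  positive template therefore yields a *full* mask, and an all-zero
  template is rejected.

## Problem sizes

The shipped tests and the acceptance script validate at the study scale
the method is meant for — 80³ grids, 28-subject normal populations,
9-subject comparison groups, 20 seeded replicates for the ordering and
null-detection properties — with smaller 40³ phantoms for unit-level
checks. A full atlas build (28 subjects, histogram method, 80³) takes a
few seconds on one core.

## Known limitations

* The histogram factor is only defined up to the template's own scale;
  factors are comparable across subjects, not across templates.
* With very coarse bins or very low noise the ratio histogram can
  degenerate to a single occupied bin; the Gaussian fit then falls back to
  the bin center, quantizing the factor to half a bin width.
* BH-FDR is applied voxel-wise with no spatial model; strongly correlated
  noise would make the effective number of tests smaller than the voxel
  count and the procedure conservative in a spatially structured way.
* The 95% empirical Z interval flags 5% of voxels in *every* subject by
  construction — it localizes, it does not test; sparse scatter is the
  expected healthy pattern.
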