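# petnorm

Data-driven intensity normalization and voxel-based statistical analysis of
coregistered [18F]-FDG brain PET volumes, with a digital phantom generator
for validation.

## The problem

Brain FDG-PET intensity varies globally between subjects — injected dose,
weight, blood glucose, stress, scanner calibration — so voxel-wise
comparison against a normal database requires dividing each scan by a
per-subject scalar first. Even after SUV conversion
(SUV = C·W/D, with C the activity concentration in kBq/cc, W the body
weight in g and D the decay-corrected injected dose in kBq), residual
between-subject variability is large. The common data-driven scalar, the
mean in-brain uptake ("global mean scaling"), is biased by any focal
lesion that shifts the mean.

`petnorm` implements the robust alternative: divide the image voxel-wise by
a population template, histogram the in-brain ratios, and take the **peak
of the histogram** — the most prevalent ratio, located by a Gaussian fit
around the raw mode — as the normalization factor. A focal lesion moves a
minority of ratios into a tail; the mode does not follow them.

Around that core the package provides, for populations of coregistered
volumes on a common grid:

* NIfTI-1 I/O, SUV conversion, cropping, Gaussian smoothing to a target
  FWHM, integer center-of-mass alignment (`read_volume()`, `to_suv()`,
  `crop_to_brain()`, `gaussian_smooth()`, `align_center_of_mass()`);
* brain masks at 50% of the template maximum, ratio histograms and the
  three normalization methods — histogram, global mean, none
  (`brain_mask_from_template()`, `ratio_histogram()`,
  `normalization_factor_histogram()`, `normalization_factor_global_mean()`,
  `normalize_none()`);
* normal-atlas construction (voxel-wise mean and SD of normalized images)
  and coefficient-of-variation maps, CoV = 100·σᵢ/μᵢ
  (`build_atlas()`, `cov_map()`, `mean_cov()`);
* voxel-wise statistics against the atlas: pooled two-sample t maps with
  Benjamini–Hochberg FDR across in-mask voxels, and individual Z-score
  maps z = (xᵢ−μᵢ)/σᵢ thresholded at their empirical 95% interval
  (`group_ttest()`, `zscore_map()`, `threshold_zmap_95()`, `bh_fdr()`);
* a phantom generator with known ground truth — global scales, coherent
  regional variability, focal lesions, multiplicative noise
  (`phantom_spec()`, `make_template_phantom()`, `sample_population()`);
* a one-call pipeline and a thin CLI
  (`run_pipeline()`, `inst/cli/petnorm.R`).

## Worked example

Build a 28-subject normal atlas from phantoms with coherent regional
variability and compare the residual between-subject CoV left by each
normalization method:

```r
library(petnorm)
spec <- phantom_spec()                     # 80^3 grid, 0.4 mm voxels
tmpl <- make_template_phantom(spec)
pop  <- sample_population(tmpl, spec, n_subjects = 28,
                          perturbations = TRUE, seed = 7)
for (m in c("histogram", "global_mean", "none")) {
  at <- build_atlas(pop$images, m)
  cv <- mean_cov(cov_map(at), at$mask)
  cat(sprintf("%-12s mean CoV %5.2f %% (SD %4.2f)\n", m, cv["mean"], cv["sd"]))
}
#> histogram    mean CoV  8.99 % (SD 9.53)
#> global_mean  mean CoV  9.47 % (SD 8.46)
#> none         mean CoV 37.98 % (SD 5.61)
```

Without normalization the ~30% between-subject global scale spread passes
straight into the atlas; the histogram factor removes it best, beating the
in-brain mean because the mean also inherits the coherent regional
variability.

Lesion robustness — the factor of a scan with a large hypometabolic lesion
(30% uptake drop, 4 mm radius) and true global scale 1.4:

```r
mask <- brain_mask_from_template(tmpl)
les  <- lesion_sphere(spec, radius_mm = 4)
img  <- sample_subject(tmpl, subject_truth(global_scale = 1.4,
                                           lesion_mask = les,
                                           lesion_factor = 0.7),
                       spec, rng_seed = 99)
normalization_factor_histogram(img, tmpl, mask)$factor
#> [1] 1.3973
normalization_factor_global_mean(img, mask)$factor
#> [1] 1.4502
```

The histogram factor recovers the true scale to 0.2%. The global-mean
factor should sit at 1.4903 for this template (1.4 times the mean in-mask
template uptake) but is dragged down ~2.7% by the lesion — bias that
global mean scaling would then spread over the whole brain as spurious
"increase".

See `vignettes/histogram-normalization.Rmd` for the method, the phantom
design and every numerical choice.

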