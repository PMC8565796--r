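# Synthetic digital rat-brain FDG phantoms with known ground truth.
#
# The generator emulates the statistical structure histogram-mode intensity
# normalization assumes: a fixed uptake pattern shared by all subjects, a
# per-subject multiplicative global scale (log-normal), optional focal
# regional perturbations and lesions (multiplicative on a connected region),
# and voxel-wise multiplicative log-normal noise.

#' Define a digital brain phantom
#'
#' Describes the geometry and statistics of a synthetic coregistered brain
#' PET population: an ellipsoidal "brain" composed of concentric uptake
#' compartments on a low-uptake background, blurred to the system
#' resolution, with per-voxel multiplicative noise.
#'
#' @param grid_shape integer triple, voxel grid dimensions.
#' @param voxel_size_mm isotropic voxel size in mm.
#' @param brain_center voxel coordinates (1-based) of the ellipsoid center;
#'   defaults to the grid center.
#' @param brain_semi_axes_mm semi-axes of the brain ellipsoid in mm.
#' @param compartment_levels relative uptake per concentric compartment,
#'   innermost first; all strictly positive.
#' @param background_uptake out-of-brain uptake as a fraction of the mean
#'   in-brain uptake.
#' @param noise_cv coefficient of variation of voxel-wise multiplicative
#'   noise (0 disables noise).
#' @param smoothing_fwhm_mm FWHM (mm) of the Gaussian blur emulating system
#'   resolution, applied to the noiseless template.
#' @param seed integer seed used when sampling populations from this spec.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(grid_shape = c(80L, 80L, 80L),
                         voxel_size_mm = 0.4,
                         brain_center = NULL,
                         brain_semi_axes_mm = c(12, 8, 7),
                         compartment_levels = c(0.8, 1.0, 1.2),
                         background_uptake = 0.1,
                         noise_cv = 0.05,
                         smoothing_fwhm_mm = 1.0,
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 4L))
    stop("configuration error: grid_shape must be three integers >= 4", call. = FALSE)
  if (voxel_size_mm <= 0)
    stop("configuration error: voxel_size_mm must be positive", call. = FALSE)
  if (is.null(brain_center)) brain_center <- floor(grid_shape / 2) + 1L
  if (length(brain_semi_axes_mm) != 3L || any(brain_semi_axes_mm <= 0))
    stop("configuration error: brain_semi_axes_mm must be three positive reals", call. = FALSE)
  if (length(compartment_levels) < 1L || any(compartment_levels <= 0))
    stop("configuration error: compartment levels must be strictly positive", call. = FALSE)
  if (background_uptake < 0)
    stop("configuration error: background_uptake must be nonnegative", call. = FALSE)
  if (noise_cv < 0 || smoothing_fwhm_mm < 0)
    stop("configuration error: noise_cv and smoothing_fwhm_mm must be nonnegative", call. = FALSE)
  semi_vox <- brain_semi_axes_mm / voxel_size_mm
  lo <- brain_center - semi_vox
  hi <- brain_center + semi_vox
  if (any(lo < 1) || any(hi > grid_shape))
    stop("configuration error: brain ellipsoid does not fit inside the grid", call. = FALSE)
  structure(list(grid_shape = grid_shape, voxel_size_mm = voxel_size_mm,
                 brain_center = as.numeric(brain_center),
                 brain_semi_axes_mm = as.numeric(brain_semi_axes_mm),
                 compartment_levels = as.numeric(compartment_levels),
                 background_uptake = background_uptake, noise_cv = noise_cv,
                 smoothing_fwhm_mm = smoothing_fwhm_mm, seed = as.integer(seed)),
            class = "phantom_spec")
}

# squared normalized ellipsoid radius for every voxel (u2 <= 1 is "brain")
phantom_radius2 <- function(spec) {
  d <- spec$grid_shape
  ax <- spec$brain_semi_axes_mm / spec$voxel_size_mm
  c0 <- spec$brain_center
  dx2 <- ((seq_len(d[1]) - c0[1]) / ax[1])^2
  dy2 <- ((seq_len(d[2]) - c0[2]) / ax[2])^2
  dz2 <- ((seq_len(d[3]) - c0[3]) / ax[3])^2
  outer(outer(dx2, dy2, "+"), dz2, "+")
}

#' Brain region of a phantom as a logical array
#'
#' @param spec a [phantom_spec()].
#' @return Logical 3D array, `TRUE` inside the brain ellipsoid.
#' @export
phantom_brain_region <- function(spec) phantom_radius2(spec) <= 1

#' Build the noiseless phantom uptake template
#'
#' Deterministic (uses no random numbers): concentric ellipsoidal uptake
#' compartments on a low background, blurred by the system-resolution FWHM.
#'
#' @param spec a [phantom_spec()].
#' @return A [voxel_image()] with unit `"SUV"`.
#' @export
make_template_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  u2 <- phantom_radius2(spec)
  brain <- u2 <= 1
  n_comp <- length(spec$compartment_levels)
  vol <- array(0, dim = spec$grid_shape)
  # equal-width radial bands, band 1 innermost
  band <- pmin(floor(sqrt(u2[brain]) * n_comp) + 1L, n_comp)
  vol[brain] <- spec$compartment_levels[band]
  if (spec$background_uptake > 0)
    vol[!brain] <- spec$background_uptake * mean(vol[brain])
  img <- voxel_image(vol, spec$voxel_size_mm, unit = "SUV")
  if (spec$smoothing_fwhm_mm > 0)
    img <- gaussian_smooth(img, spec$smoothing_fwhm_mm)
  img
}

#' Ground truth for one synthetic subject
#'
#' @param global_scale true per-subject multiplicative factor (positive).
#' @param perturbations list of regional perturbations, each a list with
#'   elements `mask` (logical array) and `factor` (positive real).
#' @param lesion_mask optional logical array marking the lesion; must be a
#'   connected subset of the brain region.
#' @param lesion_factor multiplicative lesion factor; values in (0, 1) model
#'   hypometabolism, values > 1 hypermetabolism.
#' @return A `subject_truth` object.
#' @export
subject_truth <- function(global_scale = 1, perturbations = list(),
                          lesion_mask = NULL, lesion_factor = 0.7) {
  if (global_scale <= 0)
    stop("configuration error: global_scale must be positive", call. = FALSE)
  for (p in perturbations)
    if (is.null(p$mask) || is.null(p$factor) || p$factor <= 0)
      stop("configuration error: each perturbation needs a mask and a positive factor",
           call. = FALSE)
  if (!is.null(lesion_mask) && !any(lesion_mask))
    lesion_mask <- NULL
  structure(list(global_scale = global_scale, perturbations = perturbations,
                 lesion_mask = lesion_mask, lesion_factor = lesion_factor),
            class = "subject_truth")
}

#' Spherical lesion mask inside the phantom brain
#'
#' Builds a sphere (in mm) centered at `center_vox`, clipped to the brain
#' ellipsoid so the lesion is a connected subset of the brain region.
#'
#' @param spec a [phantom_spec()].
#' @param center_vox sphere center in voxel coordinates; defaults to a
#'   dorsolateral offset from the brain center (striatum-like placement).
#' @param radius_mm sphere radius in mm.
#' @return Logical 3D array.
#' @export
lesion_sphere <- function(spec, center_vox = NULL, radius_mm = 2.4) {
  if (is.null(center_vox))
    center_vox <- spec$brain_center +
      c(0.35, 0.2, 0) * spec$brain_semi_axes_mm / spec$voxel_size_mm
  d <- spec$grid_shape
  r_vox <- radius_mm / spec$voxel_size_mm
  dx2 <- (seq_len(d[1]) - center_vox[1])^2
  dy2 <- (seq_len(d[2]) - center_vox[2])^2
  dz2 <- (seq_len(d[3]) - center_vox[3])^2
  sph <- outer(outer(dx2, dy2, "+"), dz2, "+") <= r_vox^2
  sph & phantom_brain_region(spec)
}

#' Sample one synthetic subject image
#'
#' Applies, in order: the global scale, regional perturbations, the lesion
#' (all multiplicative on their masks), then voxel-wise multiplicative
#' log-normal noise with unit mean and coefficient of variation
#' `spec$noise_cv`. No further blur is applied after noise.
#'
#' @param template noiseless template from [make_template_phantom()].
#' @param truth a [subject_truth()].
#' @param spec the [phantom_spec()] used for the template.
#' @param rng_seed integer seed making the subject reproducible.
#' @return A [voxel_image()] with unit `"SUV"`.
#' @export
sample_subject <- function(template, truth, spec, rng_seed = spec$seed) {
  stopifnot(is_voxel_image(template), inherits(truth, "subject_truth"))
  vol <- template$data * truth$global_scale
  for (p in truth$perturbations) {
    if (!identical(dim(p$mask), dim(vol)))
      stop("dimension error: perturbation mask does not match the grid", call. = FALSE)
    vol[p$mask] <- vol[p$mask] * p$factor
  }
  if (!is.null(truth$lesion_mask)) {
    if (!identical(dim(truth$lesion_mask), dim(vol)))
      stop("dimension error: lesion mask does not match the grid", call. = FALSE)
    vol[truth$lesion_mask] <- vol[truth$lesion_mask] * truth$lesion_factor
  }
  if (spec$noise_cv > 0) {
    set.seed(rng_seed)
    sdlog <- sqrt(log(1 + spec$noise_cv^2))
    # meanlog chosen so the noise has expectation exactly 1
    vol <- vol * stats::rlnorm(length(vol), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  with_data(template, vol, unit = "SUV")
}

#' Fixed volatile regions of a phantom
#'
#' Deterministic set of ellipsoidal subregions of the brain used to model
#' coherent between-subject regional variability: the same anatomical
#' regions fluctuate in every subject, each with its own per-subject
#' factor. This is the structure that separates global-mean from
#' histogram-mode scaling — coherent regional fluctuations shift the
#' in-brain mean of every subject while leaving the most prevalent ratio
#' untouched.
#'
#' @param spec a [phantom_spec()].
#' @param n_regions number of regions.
#' @param fraction_each target fraction of brain voxels per region.
#' @return List of logical arrays (one mask per region).
#' @export
phantom_perturbation_regions <- function(spec, n_regions = 3, fraction_each = 0.05) {
  brain_n <- sum(phantom_brain_region(spec))
  radius_mm <- (3 * fraction_each * brain_n / (4 * pi))^(1 / 3) * spec$voxel_size_mm
  # deterministic anatomical placements: offsets in units of the semi-axes
  offsets <- list(c(-0.45, 0.25, 0.2), c(0.4, -0.35, -0.15), c(0.05, 0.45, -0.35),
                  c(-0.3, -0.4, 0.3), c(0.5, 0.2, 0.35))
  lapply(seq_len(n_regions), function(k) {
    off <- offsets[[(k - 1L) %% length(offsets) + 1L]]
    ctr <- spec$brain_center + off * spec$brain_semi_axes_mm / spec$voxel_size_mm
    lesion_sphere(spec, center_vox = ctr, radius_mm = radius_mm)
  })
}

#' Sample a population of synthetic subjects
#'
#' Global scales are drawn log-normally. With `perturbations = TRUE`, a
#' fixed set of volatile brain regions (see
#' [phantom_perturbation_regions()]) fluctuates coherently: each subject
#' draws one independent log-normal factor per region. These coherent
#' regional fluctuations contaminate the in-brain mean (and hence the
#' global-mean normalization factor) but not the histogram mode. A shared
#' focal lesion can additionally be applied to every subject.
#'
#' @param template noiseless template from [make_template_phantom()].
#' @param spec the [phantom_spec()].
#' @param n_subjects number of subjects (>= 2).
#' @param scale_meanlog,scale_sdlog log-scale location and spread of the
#'   per-subject global scale factors.
#' @param perturbations if `TRUE`, enable coherent regional variability.
#' @param perturb_regions number of volatile regions (total coverage
#'   `perturb_regions * perturb_fraction_each` of the brain, kept <= 0.15).
#' @param perturb_fraction_each fraction of brain voxels per region.
#' @param perturb_sdlog log-scale spread of the per-subject region factors.
#' @param lesion optional list with elements `factor`, `radius_mm` and
#'   optionally `center_vox`, applied identically to every subject.
#' @param seed integer seed for the whole population.
#' @return A list with elements `images` (list of [voxel_image()]), `truths`
#'   (list of [subject_truth()]) and `scales` (numeric vector).
#' @export
sample_population <- function(template, spec, n_subjects,
                              scale_meanlog = 0, scale_sdlog = 0.3,
                              perturbations = FALSE,
                              perturb_regions = 3, perturb_fraction_each = 0.05,
                              perturb_sdlog = 0.35,
                              lesion = NULL, seed = spec$seed) {
  if (n_subjects < 2)
    stop("configuration error: n_subjects must be >= 2", call. = FALSE)
  set.seed(seed)
  scales <- stats::rlnorm(n_subjects, meanlog = scale_meanlog, sdlog = scale_sdlog)
  subject_seeds <- sample.int(.Machine$integer.max - 1L, n_subjects)
  region_masks <- if (perturbations)
    phantom_perturbation_regions(spec, perturb_regions, perturb_fraction_each)
  else list()
  pert_factors <- if (perturbations)
    matrix(stats::rlnorm(n_subjects * length(region_masks), 0, perturb_sdlog),
           nrow = n_subjects)
  else NULL
  lesion_mask <- NULL
  if (!is.null(lesion))
    lesion_mask <- lesion_sphere(spec,
                                 center_vox = lesion$center_vox,
                                 radius_mm = if (is.null(lesion$radius_mm)) 2.4 else lesion$radius_mm)

  truths <- vector("list", n_subjects)
  images <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    perts <- lapply(seq_along(region_masks), function(k)
      list(mask = region_masks[[k]], factor = pert_factors[i, k]))
    truths[[i]] <- subject_truth(global_scale = scales[i], perturbations = perts,
                                 lesion_mask = lesion_mask,
                                 lesion_factor = if (is.null(lesion$factor)) 0.7 else lesion$factor)
    images[[i]] <- sample_subject(template, truths[[i]], spec,
                                  rng_seed = subject_seeds[i])
  }
  list(images = images, truths = truths, scales = scales,
       subject_seeds = subject_seeds, seed = seed)
}

#' Write a phantom population to disk
#'
#' Writes one NIfTI-1 volume per subject plus a JSON ground-truth manifest
#' (per-subject scale, lesion bounding box, seeds).
#'
#' @param population result of [sample_population()].
#' @param dir output directory (created if missing).
#' @param prefix filename prefix for subject volumes.
#' @return Invisibly, the manifest path.
#' @export
write_phantom_population <- function(population, dir, prefix = "subject") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- length(population$images)
  files <- character(n)
  for (i in seq_len(n)) {
    files[i] <- file.path(dir, sprintf("%s_%02d.nii.gz", prefix, i))
    write_volume(population$images[[i]], files[i])
  }
  lesion_bbox <- NULL
  lm <- population$truths[[1]]$lesion_mask
  if (!is.null(lm)) {
    w <- which(lm, arr.ind = TRUE)
    lesion_bbox <- list(min = as.integer(apply(w, 2, min)),
                        max = as.integer(apply(w, 2, max)))
  }
  manifest <- list(
    n_subjects = n, seed = population$seed,
    subject_seeds = population$subject_seeds,
    global_scales = population$scales,
    lesion_bbox = lesion_bbox,
    files = basename(files)
  )
  path <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
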