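# Normal-brain atlas construction: initial template by voxel-wise averaging
# of coregistered images, 50%-of-maximum brain mask, per-subject intensity
# normalization, and the final atlas as the voxel-wise mean and standard
# deviation of the normalized images. Coefficient-of-variation maps
# (100 * sd / mean per voxel) quantify the residual between-subject
# variability each normalization method leaves behind.

# stack a list of congruent voxel images into an (n_voxels x n_subjects) matrix
stack_images <- function(images) {
  ref <- images[[1]]
  for (im in images) stop_unless_congruent(ref, im)
  vapply(images, function(im) as.vector(im$data),
         numeric(length(ref$data)))
}

#' Initial template by voxel-wise averaging
#'
#' @param images list of >= 2 congruent [voxel_image()]s.
#' @return A [voxel_image()] holding the voxel-wise arithmetic mean.
#' @export
build_initial_template <- function(images) {
  if (length(images) < 2)
    stop("configuration error: need at least 2 images", call. = FALSE)
  x <- stack_images(images)
  with_data(images[[1]], array(rowMeans(x), dim = dim(images[[1]]$data)))
}

#' Build a normal-brain atlas
#'
#' Pipeline: initial template (voxel-wise average of the unnormalized
#' images) -> brain mask (voxels above `threshold_fraction` of the template
#' maximum) -> per-subject normalization factor by `method` -> divide each
#' image by its factor -> voxel-wise mean and sample standard deviation of
#' the normalized images. With `iterations > 1`, the mean image replaces
#' the template and the mask/normalize/average loop repeats; the default
#' single pass matches the standard workflow.
#'
#' @param images list of >= 2 congruent [voxel_image()]s (SUV scale).
#' @param method normalization method: `"histogram"`, `"global_mean"` or
#'   `"none"`.
#' @param threshold_fraction brain-mask threshold as a fraction of the
#'   template maximum.
#' @param iterations number of template-refinement passes (>= 1).
#' @param bin_width,r_max ratio-histogram parameters for the histogram
#'   method.
#' @return An `atlas_template`: `mean_img`, `sd_img` (sample SD, n-1
#'   denominator), `n_subjects`, `mask`, `method`, per-subject `factors`
#'   and `fit_converged` flags.
#' @export
build_atlas <- function(images, method = c("histogram", "global_mean", "none"),
                        threshold_fraction = 0.5, iterations = 1,
                        bin_width = 0.01, r_max = 3.0) {
  method <- match.arg(method)
  n <- length(images)
  if (n < 2)
    stop("configuration error: need at least 2 images to build an atlas", call. = FALSE)
  template <- build_initial_template(images)
  mask <- NULL
  factors <- rep(1, n)
  converged <- rep(NA, n)
  normalized <- images
  for (it in seq_len(max(1L, as.integer(iterations)))) {
    mask <- brain_mask_from_template(template, threshold_fraction)
    for (i in seq_len(n)) {
      res <- normalize_image(images[[i]], method, template = template,
                             mask = mask, bin_width = bin_width, r_max = r_max)
      factors[i] <- res$factor
      converged[i] <- if (is.null(res$histogram)) NA else res$histogram$fit_converged
      normalized[[i]] <- res$normalized_image
    }
    x <- stack_images(normalized)
    m <- rowMeans(x)
    template <- with_data(images[[1]], array(m, dim = dim(images[[1]]$data)),
                          unit = if (method == "none") images[[1]]$unit else "normalized")
  }
  dvt <- x - m  # matrix minus column vector: recycles down columns
  s <- sqrt(rowSums(dvt^2) / (n - 1))
  structure(list(
    mean_img = template,
    sd_img = with_data(template, array(s, dim = dim(template$data))),
    n_subjects = n, mask = mask, method = method,
    threshold_fraction = threshold_fraction,
    factors = factors, fit_converged = converged,
    normalized_images = normalized
  ), class = "atlas_template")
}

#' @export
print.atlas_template <- function(x, ...) {
  cat(sprintf("<atlas_template> n = %d, method = %s, mask %d voxels\n",
              x$n_subjects, x$method, sum(x$mask$mask)))
  invisible(x)
}

#' Voxel-wise coefficient-of-variation map
#'
#' In-mask voxels hold `100 * sd / mean` (percent); out-of-mask voxels are
#' invalid (`NA`).
#'
#' @param atlas an `atlas_template` from [build_atlas()].
#' @return A [voxel_image()] with unit `"statistic"`.
#' @export
cov_map <- function(atlas) {
  stopifnot(inherits(atlas, "atlas_template"))
  m <- atlas$mask$mask
  mu <- atlas$mean_img$data
  if (any(mu[m] <= 0))
    stop("numerical-domain error: nonpositive atlas mean inside the mask", call. = FALSE)
  cv <- array(NA_real_, dim = dim(mu))
  cv[m] <- 100 * atlas$sd_img$data[m] / mu[m]
  with_data(atlas$mean_img, cv, unit = "statistic")
}

#' Summary of a CoV map over the brain mask
#'
#' @param cov_img a CoV [voxel_image()] from [cov_map()].
#' @param mask the [brain_mask()][brain_mask_from_template] to summarize over.
#' @return Named numeric vector `c(mean = ..., sd = ...)` of the in-mask
#'   CoV values (percent).
#' @export
mean_cov <- function(cov_img, mask) {
  stopifnot(is_voxel_image(cov_img), inherits(mask, "brain_mask"))
  v <- cov_img$data[mask$mask]
  v <- v[is.finite(v)]
  if (length(v) == 0)
    stop("validation error: empty mask", call. = FALSE)
  c(mean = mean(v), sd = stats::sd(v))
}

#' Relative reduction between two mean CoV values
#'
#' Convenience for comparing normalization methods:
#' `100 * (cov_baseline - cov_method) / cov_baseline` percent.
#'
#' @param cov_method mean CoV of the method of interest (percent).
#' @param cov_baseline mean CoV of the baseline method (percent).
#' @return Percent reduction of `cov_method` relative to `cov_baseline`.
#' @export
cov_reduction_pct <- function(cov_method, cov_baseline) {
  if (cov_baseline <= 0)
    stop("validation error: baseline CoV must be positive", call. = FALSE)
  100 * (cov_baseline - cov_method) / cov_baseline
}

#' Write an atlas bundle to disk
#'
#' Writes `atlas_mean.nii.gz`, `atlas_sd.nii.gz`, `atlas_mask.nii.gz` and
#' `atlas_meta.json` (subject count, method, threshold, software version).
#'
#' @param atlas an `atlas_template`.
#' @param dir output directory (created if missing).
#' @return Invisibly, `dir`.
#' @export
write_atlas <- function(atlas, dir) {
  stopifnot(inherits(atlas, "atlas_template"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_volume(atlas$mean_img, file.path(dir, "atlas_mean.nii.gz"))
  write_volume(atlas$sd_img, file.path(dir, "atlas_sd.nii.gz"))
  mask_img <- with_data(atlas$mean_img, array(as.numeric(atlas$mask$mask),
                                              dim = dim(atlas$mean_img$data)),
                        unit = "statistic")
  write_volume(mask_img, file.path(dir, "atlas_mask.nii.gz"))
  meta <- list(n_subjects = atlas$n_subjects, method = atlas$method,
               threshold_fraction = atlas$threshold_fraction,
               factors = atlas$factors,
               package_version = as.character(utils::packageVersion("petnorm")))
  jsonlite::write_json(meta, file.path(dir, "atlas_meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
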