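# Intensity normalization of coregistered brain PET volumes.
#
# The data-driven histogram method divides each image voxel-wise by a
# population template, histograms the in-brain ratios, and takes the peak
# of the histogram — the most prevalent ratio — as the per-subject scaling
# factor. Because the mode ignores tail values, focal lesions that drag the
# in-brain mean (and hence the global-mean factor) leave the histogram
# factor essentially unchanged.

#' Derive a brain mask from a template
#'
#' The normal brain region is defined on the template, never on individual
#' images: all voxels with intensity strictly larger than
#' `threshold_fraction` times the template maximum.
#'
#' @param template a [voxel_image()] with a positive maximum.
#' @param threshold_fraction fraction of the template maximum, in (0, 1).
#' @return A `brain_mask` object (logical grid plus provenance).
#' @export
brain_mask_from_template <- function(template, threshold_fraction = 0.5) {
  stopifnot(is_voxel_image(template))
  if (threshold_fraction <= 0 || threshold_fraction >= 1)
    stop("validation error: threshold_fraction must be in (0, 1)", call. = FALSE)
  mx <- max(template$data)
  if (mx <= 0)
    stop("validation error: template has no positive voxels", call. = FALSE)
  m <- template$data > threshold_fraction * mx
  if (!any(m))
    stop("validation error: empty brain mask (no voxel exceeds the threshold)",
         call. = FALSE)
  structure(list(mask = m, threshold_fraction = threshold_fraction),
            class = "brain_mask")
}

#' @export
print.brain_mask <- function(x, ...) {
  cat(sprintf("<brain_mask> %d voxels at >%g of template max\n",
              sum(x$mask), x$threshold_fraction))
  invisible(x)
}

#' Voxel-wise ratio of an image to a template
#'
#' In-mask voxels hold `img / template`; out-of-mask voxels are marked
#' invalid (`NA`) and excluded from all downstream computation.
#'
#' @param img,template congruent [voxel_image()]s; the template must be
#'   strictly positive inside the mask.
#' @param mask a [brain_mask()][brain_mask_from_template].
#' @return A [voxel_image()] with unit `"ratio"`.
#' @export
ratio_image <- function(img, template, mask) {
  stopifnot(is_voxel_image(img), is_voxel_image(template),
            inherits(mask, "brain_mask"))
  stop_unless_congruent(img, template)
  if (!identical(dim(mask$mask), dim(img$data)))
    stop("dimension error: mask grid does not match the images", call. = FALSE)
  tv <- template$data[mask$mask]
  if (any(tv <= 0)) {
    bad <- which(mask$mask & template$data <= 0, arr.ind = TRUE)[1, ]
    stop(sprintf("numerical-domain error: template is not positive at in-mask voxel (%d, %d, %d)",
                 bad[1], bad[2], bad[3]), call. = FALSE)
  }
  r <- array(NA_real_, dim = dim(img$data))
  r[mask$mask] <- img$data[mask$mask] / tv
  with_data(img, r, unit = "ratio")
}

#' Histogram of in-brain ratios with Gaussian peak fit
#'
#' Bins the in-mask ratio values on a fixed grid, locates the raw mode
#' (ties broken toward the lowest ratio) and fits a Gaussian
#' `A exp(-(x - c)^2 / (2 s^2))` by least squares to the bin counts in a
#' window of about +/- 0.15 ratio units around the raw mode. The fitted
#' center interpolates the peak to sub-bin precision; non-convergence is
#' reported honestly via `fit_converged`.
#'
#' @param ratio_img a ratio [voxel_image()] from [ratio_image()].
#' @param mask the [brain_mask()][brain_mask_from_template] used.
#' @param bin_width histogram bin width in ratio units.
#' @param r_max upper end of the histogram range (bins cover `(0, r_max]`).
#' @return A `ratio_histogram` object: bin edges, counts, raw mode,
#'   Gaussian parameters and `fit_converged`.
#' @export
ratio_histogram <- function(ratio_img, mask, bin_width = 0.01, r_max = 3.0) {
  stopifnot(is_voxel_image(ratio_img), inherits(mask, "brain_mask"))
  v <- ratio_img$data[mask$mask]
  v <- v[is.finite(v)]
  if (length(v) < 100)
    stop(sprintf("validation error: only %d in-mask ratios (>= 100 required)",
                 length(v)), call. = FALSE)
  edges <- seq(0, r_max, by = bin_width)
  n_bins <- length(edges) - 1L
  inside <- v > 0 & v <= r_max
  n_excluded <- sum(!inside)
  bin <- findInterval(v[inside], edges, left.open = TRUE, rightmost.closed = TRUE)
  counts <- tabulate(bin, nbins = n_bins)
  centers <- edges[-length(edges)] + bin_width / 2
  mode_bin <- which.max(counts)  # which.max takes the lowest bin on ties
  mode_center <- centers[mode_bin]

  w <- max(2L, as.integer(round(0.15 / bin_width)))
  win <- max(1L, mode_bin - w):min(n_bins, mode_bin + w)
  fit <- fit_gaussian_peak(centers[win], counts[win],
                           start_center = mode_center, start_sigma = 0.05)
  structure(list(bin_edges = edges, counts = counts, bin_width = bin_width,
                 raw_mode_bin_center = mode_center,
                 gauss_amplitude = fit$amplitude, gauss_center = fit$center,
                 gauss_sigma = fit$sigma, fit_converged = fit$converged,
                 n_in_mask = length(v), n_excluded = n_excluded),
            class = "ratio_histogram")
}

# least-squares Gaussian peak fit; reports convergence honestly
fit_gaussian_peak <- function(x, y, start_center, start_sigma) {
  failed <- list(amplitude = NA_real_, center = NA_real_, sigma = NA_real_,
                 converged = FALSE)
  if (sum(y > 0) < 4) return(failed)
  df <- data.frame(x = x, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A * exp(-(x - c0)^2 / (2 * s^2)), data = df,
                      start = list(A = max(y), c0 = start_center, s = start_sigma),
                      lower = c(A = 0, c0 = min(x), s = 1e-6),
                      upper = c(A = Inf, c0 = max(x), s = diff(range(x)) * 2),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(failed)
  p <- stats::coef(fit)
  if (!all(is.finite(p)) || p[["s"]] <= 0) return(failed)
  list(amplitude = unname(p[["A"]]), center = unname(p[["c0"]]),
       sigma = unname(p[["s"]]), converged = TRUE)
}

#' @export
print.ratio_histogram <- function(x, ...) {
  cat(sprintf("<ratio_histogram> %d ratios in %d bins of width %g\n",
              x$n_in_mask, length(x$counts), x$bin_width))
  cat(sprintf("  raw mode %.4g; Gaussian fit %s (center %.4g, sigma %.4g)\n",
              x$raw_mode_bin_center,
              if (x$fit_converged) "converged" else "NOT converged",
              x$gauss_center, x$gauss_sigma))
  invisible(x)
}

new_normalization_result <- function(method, factor, img, histogram = NULL) {
  structure(list(method = method, factor = factor,
                 normalized_image = img, histogram = histogram),
            class = "normalization_result")
}

#' Histogram-based normalization factor
#'
#' Divides the image by the template, histograms the in-brain ratios, and
#' uses the peak of the histogram — the most prevalent ratio — as the
#' normalization factor. The Gaussian fit center is used when the fit
#' converges; otherwise the raw mode bin center is used and the fallback is
#' reported via a message.
#'
#' @param img image to normalize.
#' @param template population template the ratios are taken against.
#' @param mask brain mask derived from the template.
#' @param bin_width,r_max histogram parameters, see [ratio_histogram()].
#' @return A `normalization_result`: method, factor, normalized image
#'   (`img / factor`) and the underlying [ratio_histogram()].
#' @export
normalization_factor_histogram <- function(img, template, mask,
                                           bin_width = 0.01, r_max = 3.0) {
  r <- ratio_image(img, template, mask)
  h <- ratio_histogram(r, mask, bin_width = bin_width, r_max = r_max)
  if (h$fit_converged) {
    factor <- h$gauss_center
  } else {
    message("Gaussian peak fit did not converge; falling back to the raw mode bin center")
    factor <- h$raw_mode_bin_center
  }
  if (!is.finite(factor) || factor <= 0)
    stop("numerical-domain error: nonpositive histogram normalization factor",
         call. = FALSE)
  new_normalization_result("histogram", factor,
                           with_data(img, img$data / factor, unit = "normalized"),
                           histogram = h)
}

#' Global-mean (whole-brain) normalization factor
#'
#' Scales the image by its mean in-brain uptake. Focal lesions shift the
#' mean and therefore bias this factor; compare
#' [normalization_factor_histogram()].
#'
#' @param img image to normalize.
#' @param mask brain mask derived from the template.
#' @return A `normalization_result` with `factor` the in-mask mean.
#' @export
normalization_factor_global_mean <- function(img, mask) {
  stopifnot(is_voxel_image(img), inherits(mask, "brain_mask"))
  if (!identical(dim(mask$mask), dim(img$data)))
    stop("dimension error: mask grid does not match the image", call. = FALSE)
  factor <- mean(img$data[mask$mask])
  if (!is.finite(factor) || factor == 0)
    stop("numerical-domain error: zero in-mask mean", call. = FALSE)
  new_normalization_result("global_mean", factor,
                           with_data(img, img$data / factor, unit = "normalized"))
}

#' No normalization (SUV passthrough)
#'
#' @param img image to pass through unchanged (factor 1).
#' @return A `normalization_result` with `factor = 1` and the input image,
#'   unit tag preserved.
#' @export
normalize_none <- function(img) {
  stopifnot(is_voxel_image(img))
  new_normalization_result("none", 1.0, img)
}

#' Apply a normalization method by name
#'
#' @param img image to normalize.
#' @param method `"histogram"`, `"global_mean"` or `"none"`.
#' @param template,mask required for `"histogram"` (template and mask) and
#'   `"global_mean"` (mask).
#' @param ... passed to [normalization_factor_histogram()].
#' @return A `normalization_result`.
#' @export
normalize_image <- function(img, method = c("histogram", "global_mean", "none"),
                            template = NULL, mask = NULL, ...) {
  method <- match.arg(method)
  switch(method,
         histogram = normalization_factor_histogram(img, template, mask, ...),
         global_mean = normalization_factor_global_mean(img, mask),
         none = normalize_none(img))
}
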