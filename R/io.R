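# NIfTI-1 I/O, SUV conversion and the preprocessing steps applied before
# normalization: cropping to a brain field-of-view, Gaussian smoothing to a
# target FWHM, and integer-voxel center-of-mass alignment. All internal
# computation is in 64-bit floats; files are written as 32-bit.

#' Read a 3D volume from a NIfTI-1 file
#'
#' @param path path to a `.nii` or `.nii.gz` file holding 3D scalar data.
#' @param unit intensity unit tag to attach (the file format does not carry
#'   one); defaults to `"kBq_cc"`, the scanner output unit.
#' @return A [voxel_image()]; voxel sizes are taken from the header.
#' @export
read_volume <- function(path, unit = "kBq_cc") {
  if (!file.exists(path))
    stop(sprintf("format error: file not found: %s", path), call. = FALSE)
  nii <- tryCatch(suppressWarnings(RNifti::readNifti(path)),
                  error = function(e)
                    stop(sprintf("format error: cannot read '%s' as NIfTI-1 (%s)",
                                 path, conditionMessage(e)), call. = FALSE))
  d <- dim(nii)
  if (length(d) != 3L)
    stop(sprintf("format error: expected 3D volume, got %dD in '%s'",
                 length(d), path), call. = FALSE)
  vox <- RNifti::pixdim(nii)[seq_len(3)]
  voxel_image(array(as.numeric(nii), dim = d), vox, unit = unit)
}

#' Write a volume to a NIfTI-1 file
#'
#' @param img a [voxel_image()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return Invisibly, `path`.
#' @export
write_volume <- function(img, path) {
  stopifnot(is_voxel_image(img))
  dat <- img$data
  dat[is.na(dat)] <- 0  # NIfTI has no mask channel; invalid voxels go to 0
  nii <- RNifti::asNifti(dat)
  RNifti::pixdim(nii) <- img$voxel_size_mm
  RNifti::writeNifti(nii, path, datatype = "float")
  invisible(path)
}

#' Acquisition information for SUV conversion
#'
#' @param injected_dose_kBq decay-corrected injected activity in kBq.
#' @param weight_g subject weight in g.
#' @return An `acquisition_info` object.
#' @export
acquisition_info <- function(injected_dose_kBq, weight_g) {
  if (!is.finite(injected_dose_kBq) || injected_dose_kBq <= 0)
    stop("validation error: injected_dose_kBq must be strictly positive", call. = FALSE)
  if (!is.finite(weight_g) || weight_g <= 0)
    stop("validation error: weight_g must be strictly positive", call. = FALSE)
  structure(list(injected_dose_kBq = injected_dose_kBq, weight_g = weight_g),
            class = "acquisition_info")
}

#' Convert a kBq/cc image to standard uptake values
#'
#' SUV normalizes the measured activity concentration C (kBq/cc) by the
#' injected dose per unit body weight: `SUV = C * W / D`, with D the
#' decay-corrected injected activity (kBq) and W the subject weight (g).
#'
#' @param img a [voxel_image()] with unit `"kBq_cc"`.
#' @param acq an [acquisition_info()].
#' @return A [voxel_image()] with unit `"SUV"`.
#' @export
to_suv <- function(img, acq) {
  stopifnot(is_voxel_image(img), inherits(acq, "acquisition_info"))
  if (img$unit != "kBq_cc")
    stop(sprintf("validation error: to_suv expects unit kBq_cc, got %s", img$unit),
         call. = FALSE)
  with_data(img, img$data * acq$weight_g / acq$injected_dose_kBq, unit = "SUV")
}

#' Crop a volume to a target window
#'
#' Extracts a `target_shape` sub-grid positioned so that voxel `center` of
#' the input lands at voxel `floor(target_shape/2) + 1` of the output (the
#' "center" voxel of the window). No implicit padding: the window must lie
#' entirely inside the input grid.
#'
#' @param img a [voxel_image()].
#' @param target_shape integer triple, output grid dimensions.
#' @param center 1-based voxel coordinates of the window center in `img`;
#'   defaults to the grid center.
#' @return A cropped [voxel_image()] with its origin updated.
#' @export
crop_to_brain <- function(img, target_shape, center = NULL) {
  stopifnot(is_voxel_image(img))
  d <- dim(img$data)
  target_shape <- as.integer(target_shape)
  if (length(target_shape) != 3L || any(target_shape < 1L))
    stop("dimension error: target_shape must be three positive integers", call. = FALSE)
  if (is.null(center)) center <- floor(d / 2) + 1L
  center <- as.integer(round(center))
  start <- center - target_shape %/% 2L
  end <- start + target_shape - 1L
  if (any(start < 1L) || any(end > d))
    stop(sprintf("dimension error: crop window [%s]..[%s] exceeds grid [%s]",
                 paste(start, collapse = ","), paste(end, collapse = ","),
                 paste(d, collapse = ",")), call. = FALSE)
  sub <- img$data[start[1]:end[1], start[2]:end[2], start[3]:end[3], drop = FALSE]
  voxel_image(sub, img$voxel_size_mm, unit = img$unit,
              origin = img$origin + start - 1L)
}

# reflective (edge-duplicating) index into 1..n
reflect_index <- function(i, n) {
  j <- (i - 1L) %% (2L * n)
  j <- ifelse(j < 0L, j + 2L * n, j)
  ifelse(j < n, j + 1L, 2L * n - j)
}

# 1D Gaussian correlation along the first array axis, reflective boundary
conv_axis1 <- function(arr, kern) {
  r <- (length(kern) - 1L) %/% 2L
  d <- dim(arr)
  n <- d[1]
  idx <- reflect_index(seq(1L - r, n + r), n)
  padded <- arr[idx, , , drop = FALSE]
  out <- array(0, dim = d)
  for (k in seq_along(kern))
    out <- out + kern[k] * padded[(k - 1L) + seq_len(n), , , drop = FALSE]
  out
}

#' Gaussian smoothing to a target FWHM
#'
#' Separable 3D Gaussian convolution with per-axis standard deviation
#' `sigma_vox = fwhm_mm / (2 sqrt(2 ln 2)) / voxel_size_mm`. Boundaries use
#' reflective (edge-duplicating) padding, so a constant image is unchanged
#' and total intensity is conserved away from the grid boundary.
#'
#' @param img a [voxel_image()].
#' @param fwhm_mm full width at half maximum of the kernel in mm; 0 returns
#'   the image unchanged.
#' @return A smoothed [voxel_image()].
#' @export
gaussian_smooth <- function(img, fwhm_mm) {
  stopifnot(is_voxel_image(img))
  if (!is.finite(fwhm_mm) || fwhm_mm < 0)
    stop("validation error: fwhm_mm must be nonnegative", call. = FALSE)
  if (fwhm_mm == 0) return(img)
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / img$voxel_size_mm
  out <- img$data
  for (axis in 1:3) {
    s <- sigma_vox[axis]
    r <- max(1L, as.integer(ceiling(4 * s)))
    kern <- stats::dnorm(seq(-r, r), sd = s)
    kern <- kern / sum(kern)
    perm <- switch(axis, `1` = 1:3, `2` = c(2L, 1L, 3L), `3` = c(3L, 2L, 1L))
    out <- aperm(conv_axis1(aperm(out, perm), kern), order(perm))
  }
  with_data(img, out)
}

#' Integer-voxel center-of-mass alignment
#'
#' Translates `img` by the integer voxel shift that best matches its
#' intensity center of mass to that of `reference`; vacated voxels are
#' zero-filled. This is a deliberately simple rigid alignment for volumes
#' assumed already coregistered up to a translation.
#'
#' @param img,reference congruent [voxel_image()]s with nonnegative data.
#' @return A list with `image` (the shifted [voxel_image()]) and `shift`
#'   (the applied integer voxel translation).
#' @export
align_center_of_mass <- function(img, reference) {
  stopifnot(is_voxel_image(img), is_voxel_image(reference))
  stop_unless_congruent(img, reference)
  com <- function(a) {
    tot <- sum(a)
    if (tot <= 0)
      stop("validation error: cannot align an all-zero image", call. = FALSE)
    d <- dim(a)
    vapply(1:3, function(ax) {
      margin <- apply(a, ax, sum)
      sum(seq_len(d[ax]) * margin) / tot
    }, numeric(1))
  }
  shift <- as.integer(round(com(reference$data) - com(img$data)))
  d <- dim(img$data)
  out <- array(0, dim = d)
  src_from <- pmax(1L, 1L - shift)
  src_to <- pmin(d, d - shift)
  if (all(src_from <= src_to)) {
    dst_from <- src_from + shift
    dst_to <- src_to + shift
    out[dst_from[1]:dst_to[1], dst_from[2]:dst_to[2], dst_from[3]:dst_to[3]] <-
      img$data[src_from[1]:src_to[1], src_from[2]:src_to[2], src_from[3]:src_to[3]]
  }
  list(image = with_data(img, out), shift = shift)
}
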