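#' @keywords internal
VOXEL_UNITS <- c("kBq_cc", "SUV", "normalized", "ratio", "statistic")

#' Construct a voxel image
#'
#' A `voxel_image` is the package's in-memory representation of a 3D scalar
#' volume: a numeric array plus voxel-size metadata (mm per axis), an
#' intensity-unit tag and the voxel coordinates of the grid corner. All
#' spatial analysis in this package is voxel-space: images entering a joint
#' analysis are assumed coregistered on a single grid.
#'
#' @param data 3D numeric array, finite values only.
#' @param voxel_size_mm positive voxel edge length(s) in mm; a scalar is
#'   recycled to all three axes.
#' @param unit intensity unit tag, one of `"kBq_cc"`, `"SUV"`,
#'   `"normalized"`, `"ratio"`, `"statistic"`.
#' @param origin integer voxel coordinates (0-based) of the grid corner in
#'   the parent frame; bookkeeping for cropped sub-volumes.
#' @return An object of class `voxel_image`.
#' @export
voxel_image <- function(data, voxel_size_mm, unit = "SUV", origin = c(0L, 0L, 0L)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array", call. = FALSE)
  storage.mode(data) <- "double"
  unit <- match.arg(unit, VOXEL_UNITS)
  # ratio and statistic maps mark out-of-mask voxels as NA; measured images
  # must be finite everywhere
  if (unit %in% c("ratio", "statistic")) {
    if (any(is.infinite(data) | is.nan(data)))
      stop("`data` contains NaN/Inf values", call. = FALSE)
  } else if (anyNA(data) || any(!is.finite(data))) {
    stop("`data` contains NaN/Inf values", call. = FALSE)
  }
  if (length(voxel_size_mm) == 1L) voxel_size_mm <- rep(voxel_size_mm, 3L)
  if (length(voxel_size_mm) != 3L || any(!is.finite(voxel_size_mm)) ||
      any(voxel_size_mm <= 0))
    stop("`voxel_size_mm` must be a positive scalar or length-3 vector", call. = FALSE)
  if (length(origin) != 3L) stop("`origin` must be a length-3 vector", call. = FALSE)
  structure(
    list(data = data, voxel_size_mm = as.numeric(voxel_size_mm),
         unit = unit, origin = as.integer(round(origin))),
    class = "voxel_image"
  )
}

#' Test for the voxel image class
#' @param x object to test.
#' @return `TRUE` for a `voxel_image`.
#' @export
is_voxel_image <- function(x) inherits(x, "voxel_image")

#' @export
print.voxel_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<voxel_image> %d x %d x %d voxels, %.3g x %.3g x %.3g mm, unit = %s\n",
              d[1], d[2], d[3],
              x$voxel_size_mm[1], x$voxel_size_mm[2], x$voxel_size_mm[3], x$unit))
  cat(sprintf("  range [%.4g, %.4g], origin (%d, %d, %d)\n",
              min(x$data), max(x$data), x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' @export
dim.voxel_image <- function(x) dim(x$data)

# shared grid-congruence check; `what` names the offending argument in errors
stop_unless_congruent <- function(a, b, what = "images") {
  if (!identical(dim(a$data), dim(b$data)))
    stop(sprintf("dimension error: %s are not on the same grid (%s vs %s)",
                 what, paste(dim(a$data), collapse = "x"),
                 paste(dim(b$data), collapse = "x")), call. = FALSE)
  invisible(TRUE)
}

# replace the data of an image, keeping/overriding metadata
with_data <- function(img, data, unit = img$unit) {
  voxel_image(data, img$voxel_size_mm, unit = unit, origin = img$origin)
}
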