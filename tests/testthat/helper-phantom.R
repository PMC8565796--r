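# Small phantom geometry shared by the unit tests: a 40^3 grid keeps each
# atlas build well under a second while leaving ~7000 brain voxels.
small_spec <- function(...) {
  phantom_spec(grid_shape = c(40L, 40L, 40L),
               brain_semi_axes_mm = c(6, 4.5, 4),
               ...)
}

# build a brain_mask directly from a logical array (for synthetic stat maps)
mask_from_logical <- function(m, threshold_fraction = 0.5) {
  structure(list(mask = m, threshold_fraction = threshold_fraction),
            class = "brain_mask")
}

# uniform random image on a small grid
random_image <- function(dim = c(8L, 8L, 8L), unit = "SUV", lo = 0.5, hi = 2) {
  voxel_image(array(stats::runif(prod(dim), lo, hi), dim = dim), 0.4, unit = unit)
}
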