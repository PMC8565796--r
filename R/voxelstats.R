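# Voxel-wise statistical comparison against the normal atlas: individual
# Z-score maps thresholded by an empirical 95% interval, and group-level
# two-sample t maps with Benjamini-Hochberg FDR correction across in-mask
# voxels.

new_stat_map <- function(values, kind, mask, threshold_low = NA_real_,
                         threshold_high = NA_real_, sig_mask_low = NULL,
                         sig_mask_high = NULL, n_invalid = 0L) {
  structure(list(values = values, kind = kind, mask = mask,
                 threshold_low = threshold_low, threshold_high = threshold_high,
                 sig_mask_low = sig_mask_low, sig_mask_high = sig_mask_high,
                 n_invalid = n_invalid),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf("<stat_map> kind = %s, %d in-mask voxels", x$kind,
              sum(x$mask$mask) - x$n_invalid))
  if (is.finite(x$threshold_low))
    cat(sprintf(", thresholds [%.3g, %.3g]", x$threshold_low, x$threshold_high))
  cat("\n")
  invisible(x)
}

#' Z-score map of an individual against the atlas
#'
#' Per in-mask voxel, `z = (x - mu) / sigma` with `mu` and `sigma` the
#' atlas voxel-wise mean and standard deviation; the subject image must
#' already be normalized the same way as the atlas. Voxels with zero atlas
#' SD inside the mask are flagged invalid and excluded, with their count
#' reported.
#'
#' @param subject a normalized [voxel_image()] on the atlas grid.
#' @param atlas an `atlas_template` from [build_atlas()].
#' @return A `stat_map` of kind `"z"` (`NA` outside the mask and at
#'   invalid voxels).
#' @export
zscore_map <- function(subject, atlas) {
  stopifnot(is_voxel_image(subject), inherits(atlas, "atlas_template"))
  stop_unless_congruent(subject, atlas$mean_img, "subject and atlas")
  m <- atlas$mask$mask
  sg <- atlas$sd_img$data
  valid <- m & sg > 0
  n_invalid <- sum(m) - sum(valid)
  if (n_invalid > 0)
    message(sprintf("%d in-mask voxels have zero atlas SD and are excluded", n_invalid))
  z <- array(NA_real_, dim = dim(subject$data))
  z[valid] <- (subject$data[valid] - atlas$mean_img$data[valid]) / sg[valid]
  new_stat_map(z, "z", atlas$mask, n_invalid = n_invalid)
}

#' Threshold a Z map at its empirical 95% interval
#'
#' Computes the empirical 2.5th and 97.5th percentiles of the in-mask
#' Z values of this map (linear interpolation between order statistics)
#' and flags voxels strictly below/above them, i.e. the 2.5% lowest and
#' 2.5% highest values in the image. With heavily tied values the
#' percentiles degenerate and the significance masks can be empty.
#'
#' @param zmap a `stat_map` from [zscore_map()] with >= 100 in-mask values.
#' @return The `stat_map` with `threshold_low`, `threshold_high`,
#'   `sig_mask_low` and `sig_mask_high` filled in.
#' @export
threshold_zmap_95 <- function(zmap) {
  stopifnot(inherits(zmap, "stat_map"))
  v <- zmap$values[zmap$mask$mask]
  v <- v[is.finite(v)]
  if (length(v) < 100)
    stop(sprintf("validation error: only %d in-mask values (>= 100 required)",
                 length(v)), call. = FALSE)
  qs <- stats::quantile(v, c(0.025, 0.975), type = 7, names = FALSE)
  vals <- zmap$values
  in_mask <- zmap$mask$mask & is.finite(vals)
  low <- in_mask & vals < qs[1]
  high <- in_mask & vals > qs[2]
  new_stat_map(vals, zmap$kind, zmap$mask,
               threshold_low = qs[1], threshold_high = qs[2],
               sig_mask_low = low, sig_mask_high = high,
               n_invalid = zmap$n_invalid)
}

#' Benjamini-Hochberg FDR selection
#'
#' Step-up procedure at level `q`: sort the p-values, find the largest k
#' with `p_(k) <= k q / m`, and declare those k hypotheses significant.
#'
#' @param p_values vector of p-values in \[0, 1\].
#' @param q FDR level.
#' @return List with `significant` (logical vector, original order) and
#'   `p_threshold` (largest significant p-value; 0 when none).
#' @export
bh_fdr <- function(p_values, q = 0.05) {
  if (length(p_values) == 0)
    stop("validation error: empty p-value vector", call. = FALSE)
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1))
    stop("validation error: p-values must lie in [0, 1]", call. = FALSE)
  significant <- stats::p.adjust(p_values, method = "BH") <= q
  p_threshold <- if (any(significant)) max(p_values[significant]) else 0
  list(significant = significant, p_threshold = p_threshold)
}

# vectorized two-sample t over columns-of-subjects matrices (voxels x n)
pooled_ttest_rows <- function(x1, x2, var_equal = TRUE) {
  n1 <- ncol(x1); n2 <- ncol(x2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(m1))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  t <- (m1 - m2) / se
  p <- 2 * stats::pt(-abs(t), df = df)
  list(t = t, p = p, df = df)
}

#' Voxel-wise group comparison against the atlas subjects
#'
#' Per in-mask voxel, a two-sample t statistic comparing the group images
#' with the normalized atlas subject images (pooled variance by default,
#' df = n1 + n2 - 2; Welch available), two-sided p-values, and
#' Benjamini-Hochberg FDR correction across all in-mask voxels at level
#' `q`. Significant voxels are split by the sign of t into increase
#' (group > atlas) and decrease masks. `fdr_t_threshold` is the smallest
#' absolute t among significant voxels (the T_FDR display threshold).
#'
#' @param group list of >= 2 normalized [voxel_image()]s.
#' @param atlas_subjects list of >= 2 normalized [voxel_image()]s (the
#'   atlas population, e.g. `atlas$normalized_images`).
#' @param mask [brain_mask()][brain_mask_from_template] restricting the tests.
#' @param q FDR level.
#' @param var_equal pooled-variance t if `TRUE` (default), Welch otherwise.
#' @return A `group_test_result`: `t_map` (`stat_map`), `p_map` (3D array,
#'   `NA` outside the mask), `q_threshold`, `p_threshold`,
#'   `fdr_t_threshold`, subject counts, and `sig_increase` /
#'   `sig_decrease` logical grids.
#' @export
group_ttest <- function(group, atlas_subjects, mask, q = 0.05, var_equal = TRUE) {
  if (length(group) < 2 || length(atlas_subjects) < 2)
    stop("configuration error: both groups need >= 2 subjects", call. = FALSE)
  stopifnot(inherits(mask, "brain_mask"))
  ref <- group[[1]]
  if (!identical(dim(mask$mask), dim(ref$data)))
    stop("dimension error: mask grid does not match the images", call. = FALSE)
  midx <- which(mask$mask)
  x1 <- vapply(group, function(im) {
    stop_unless_congruent(ref, im); im$data[midx]
  }, numeric(length(midx)))
  x2 <- vapply(atlas_subjects, function(im) {
    stop_unless_congruent(ref, im); im$data[midx]
  }, numeric(length(midx)))
  tt <- pooled_ttest_rows(x1, x2, var_equal = var_equal)
  fdr <- bh_fdr(tt$p, q)

  d <- dim(ref$data)
  t_arr <- array(NA_real_, dim = d); t_arr[midx] <- tt$t
  p_arr <- array(NA_real_, dim = d); p_arr[midx] <- tt$p
  sig <- fdr$significant
  inc <- array(FALSE, dim = d); inc[midx[sig & tt$t > 0]] <- TRUE
  dec <- array(FALSE, dim = d); dec[midx[sig & tt$t < 0]] <- TRUE
  fdr_t <- if (any(sig)) min(abs(tt$t[sig])) else NA_real_

  t_map <- new_stat_map(t_arr, "t", mask,
                        threshold_low = if (is.na(fdr_t)) NA_real_ else -fdr_t,
                        threshold_high = fdr_t,
                        sig_mask_low = dec, sig_mask_high = inc)
  structure(list(t_map = t_map, p_map = p_arr, q_threshold = q,
                 p_threshold = fdr$p_threshold, fdr_t_threshold = fdr_t,
                 n_group = length(group), n_atlas = length(atlas_subjects),
                 sig_increase = inc, sig_decrease = dec,
                 n_sig_increase = sum(inc), n_sig_decrease = sum(dec)),
            class = "group_test_result")
}

#' @export
print.group_test_result <- function(x, ...) {
  cat(sprintf("<group_test_result> n = %d vs %d, q = %g\n",
              x$n_group, x$n_atlas, x$q_threshold))
  cat(sprintf("  significant: %d increase, %d decrease (T_FDR = %s)\n",
              x$n_sig_increase, x$n_sig_decrease,
              if (is.na(x$fdr_t_threshold)) "none" else
                sprintf("%.3f", x$fdr_t_threshold)))
  invisible(x)
}
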