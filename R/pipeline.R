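# End-to-end orchestration: phantom population -> atlas -> group comparison
# and individual Z maps, driven by a single config, with a JSON run manifest
# for reproducibility.

#' Default pipeline configuration
#'
#' Mirrors the reference study design: 28 normal subjects for the atlas,
#' 9 lesioned and 9 control subjects for the comparisons.
#'
#' @param out_dir output directory.
#' @param seed integer seed driving all randomness.
#' @param ... overrides for any configuration field (see the returned list).
#' @return A named list (`run_config`).
#' @export
default_run_config <- function(out_dir = "petnorm_run", seed = 1L, ...) {
  cfg <- list(
    out_dir = out_dir, seed = as.integer(seed),
    in_dir = NULL,              # optional: read subject NIfTIs instead of simulating
    grid_shape = c(80L, 80L, 80L),
    voxel_size_mm = 0.4,
    brain_semi_axes_mm = c(12, 8, 7),
    n_normal = 28L, n_lesion = 9L, n_control = 9L,
    method = "histogram",
    threshold_fraction = 0.5, bin_width = 0.01, r_max = 3.0,
    fwhm_mm = 1.0, noise_cv = 0.05,
    scale_sdlog = 0.3, perturbations = FALSE,
    lesion_factor = 0.7, lesion_radius_mm = 2.4,
    q = 0.05, iterations = 1L,
    write_volumes = TRUE
  )
  over <- list(...)
  cfg[names(over)] <- over
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  if (!is.null(cfg$in_dir) && !dir.exists(cfg$in_dir))
    stop(sprintf("configuration error [input]: input directory not found: %s",
                 cfg$in_dir), call. = FALSE)
  if (cfg$n_normal < 2)
    stop("configuration error [config]: n_normal must be >= 2", call. = FALSE)
  if (!cfg$method %in% c("histogram", "global_mean", "none"))
    stop("configuration error [config]: unknown method", call. = FALSE)
  if (cfg$q <= 0 || cfg$q >= 1)
    stop("configuration error [config]: q must be in (0, 1)", call. = FALSE)
  if (cfg$threshold_fraction <= 0 || cfg$threshold_fraction >= 1)
    stop("configuration error [config]: threshold_fraction must be in (0, 1)",
         call. = FALSE)
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Unspecified fields take the [default_run_config()] values; the config
#' round-trips losslessly through [yaml::write_yaml()].
#'
#' @param path YAML file path.
#' @return A validated `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    stop(sprintf("configuration error [config]: file not found: %s", path),
         call. = FALSE)
  over <- yaml::read_yaml(path)
  do.call(default_run_config, over)
}

#' Run the full phantom-to-statistics pipeline
#'
#' Stages: (1) simulate a normal population plus lesioned and control
#' groups from the phantom spec; (2) build the normal atlas with the
#' configured normalization method and write the atlas bundle; (3)
#' normalize the lesion/control groups against the atlas and compare each
#' group voxel-wise to the atlas subjects (t + FDR); (4) produce a
#' thresholded Z map for the first subject of each group. Factors,
#' statistics and a reproducibility manifest are written under
#' `config$out_dir`.
#'
#' @param config a `run_config` list from [default_run_config()] /
#'   [read_run_config()], or a path to a YAML config.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  cfg <- validate_run_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)

  spec <- phantom_spec(grid_shape = cfg$grid_shape,
                       voxel_size_mm = cfg$voxel_size_mm,
                       brain_semi_axes_mm = cfg$brain_semi_axes_mm,
                       noise_cv = cfg$noise_cv,
                       smoothing_fwhm_mm = cfg$fwhm_mm,
                       seed = cfg$seed)
  template <- make_template_phantom(spec)

  normals <- sample_population(template, spec, cfg$n_normal,
                               scale_sdlog = cfg$scale_sdlog,
                               perturbations = cfg$perturbations,
                               seed = cfg$seed)
  atlas <- build_atlas(normals$images, method = cfg$method,
                       threshold_fraction = cfg$threshold_fraction,
                       iterations = cfg$iterations,
                       bin_width = cfg$bin_width, r_max = cfg$r_max)
  if (cfg$write_volumes) {
    write_phantom_population(normals, file.path(cfg$out_dir, "phantom_normals"))
    write_atlas(atlas, file.path(cfg$out_dir, "atlas"))
  }
  cv <- cov_map(atlas)
  cov_summary <- mean_cov(cv, atlas$mask)

  factors <- data.frame(subject_id = sprintf("normal_%02d", seq_len(cfg$n_normal)),
                        method = cfg$method, factor = atlas$factors,
                        fit_converged = atlas$fit_converged)

  normalize_group <- function(pop) {
    lapply(pop$images, function(im)
      normalize_image(im, cfg$method, template = atlas$mean_img,
                      mask = atlas$mask, bin_width = cfg$bin_width,
                      r_max = cfg$r_max))
  }
  stats_report <- list(method = cfg$method, q = cfg$q,
                       cov_mean_pct = unname(cov_summary["mean"]),
                       cov_sd_pct = unname(cov_summary["sd"]))

  groups <- list()
  if (cfg$n_lesion >= 2) {
    lesioned <- sample_population(template, spec, cfg$n_lesion,
                                  scale_sdlog = cfg$scale_sdlog,
                                  perturbations = cfg$perturbations,
                                  lesion = list(factor = cfg$lesion_factor,
                                                radius_mm = cfg$lesion_radius_mm),
                                  seed = cfg$seed + 1L)
    groups$lesion <- lesioned
  }
  if (cfg$n_control >= 2) {
    controls <- sample_population(template, spec, cfg$n_control,
                                  scale_sdlog = cfg$scale_sdlog,
                                  perturbations = cfg$perturbations,
                                  seed = cfg$seed + 2L)
    groups$control <- controls
  }
  for (gname in names(groups)) {
    res_list <- normalize_group(groups[[gname]])
    norm_imgs <- lapply(res_list, `[[`, "normalized_image")
    gt <- group_ttest(norm_imgs, atlas$normalized_images, atlas$mask, q = cfg$q)
    zmap <- threshold_zmap_95(zscore_map(norm_imgs[[1]], atlas))
    factors <- rbind(factors, data.frame(
      subject_id = sprintf("%s_%02d", gname, seq_along(res_list)),
      method = cfg$method,
      factor = vapply(res_list, `[[`, numeric(1), "factor"),
      fit_converged = vapply(res_list, function(r)
        if (is.null(r$histogram)) NA else r$histogram$fit_converged, logical(1))))
    stats_report[[gname]] <- list(
      n_group = gt$n_group, n_atlas = gt$n_atlas,
      fdr_t_threshold = gt$fdr_t_threshold,
      n_sig_increase = gt$n_sig_increase, n_sig_decrease = gt$n_sig_decrease,
      z_threshold_low = zmap$threshold_low, z_threshold_high = zmap$threshold_high,
      z_n_low = sum(zmap$sig_mask_low), z_n_high = sum(zmap$sig_mask_high))
    if (cfg$write_volumes) {
      tmap_img <- with_data(atlas$mean_img, gt$t_map$values, unit = "statistic")
      write_volume(tmap_img, file.path(cfg$out_dir, sprintf("t_map_%s.nii.gz", gname)))
      zimg <- with_data(atlas$mean_img, zmap$values, unit = "statistic")
      write_volume(zimg, file.path(cfg$out_dir, sprintf("z_map_%s.nii.gz", gname)))
    }
  }

  factors_path <- file.path(cfg$out_dir, "factors.csv")
  utils::write.csv(factors, factors_path, row.names = FALSE)
  jsonlite::write_json(stats_report, file.path(cfg$out_dir, "stats_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  out_files <- list.files(cfg$out_dir, recursive = TRUE, full.names = TRUE)
  manifest <- list(
    config = cfg[setdiff(names(cfg), "write_volumes")],
    package_version = as.character(utils::packageVersion("petnorm")),
    cov_summary = as.list(cov_summary),
    stats = stats_report,
    file_md5 = as.list(tools::md5sum(out_files[!grepl("manifest.json$", out_files)]))
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
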