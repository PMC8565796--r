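test_that("brain mask uses a strict threshold on the template maximum", {
  # constant positive template: every voxel strictly exceeds half the
  # maximum, so the mask is full; emptiness needs fraction -> 1
  const <- voxel_image(array(2, dim = c(6, 6, 6)), 0.4, unit = "SUV")
  expect_true(all(brain_mask_from_template(const)$mask))

  zero <- voxel_image(array(0, dim = c(6, 6, 6)), 0.4, unit = "SUV")
  expect_error(brain_mask_from_template(zero), "no positive voxels")

  binv <- array(0, dim = c(6, 6, 6)); binv[2:4, 2:4, 2:4] <- 1
  m <- brain_mask_from_template(voxel_image(binv, 0.4, unit = "SUV"), 0.5)
  expect_identical(m$mask, binv == 1)

  expect_error(brain_mask_from_template(const, 1.5), "threshold_fraction")
})

test_that("brain mask voxel count matches an exhaustive scan on the phantom template", {
  tmpl <- make_template_phantom(small_spec())
  m <- brain_mask_from_template(tmpl, 0.5)
  thr <- 0.5 * max(tmpl$data)
  count <- 0L
  d <- dim(tmpl$data)
  for (k in seq_len(d[3]))
    count <- count + sum(tmpl$data[, , k] > thr)
  expect_identical(sum(m$mask), count)
})

test_that("ratio images divide voxel-wise inside the mask and invalidate outside", {
  tmpl <- make_template_phantom(small_spec())
  m <- brain_mask_from_template(tmpl)

  r1 <- ratio_image(tmpl, tmpl, m)
  expect_true(all(r1$data[m$mask] == 1))
  expect_true(all(is.na(r1$data[!m$mask])))
  expect_identical(r1$unit, "ratio")

  img2 <- with_data(tmpl, 2 * tmpl$data)
  expect_true(all(ratio_image(img2, tmpl, m)$data[m$mask] == 2))

  set.seed(7)
  img <- with_data(tmpl, tmpl$data * runif(length(tmpl$data), 0.5, 2))
  r <- ratio_image(img, tmpl, m)
  idx <- which(m$mask, arr.ind = TRUE)
  pick <- idx[sample(nrow(idx), 300), , drop = FALSE]
  for (row in seq_len(nrow(pick))) {
    i <- pick[row, 1]; j <- pick[row, 2]; k <- pick[row, 3]
    expect_identical(r$data[i, j, k], img$data[i, j, k] / tmpl$data[i, j, k])
  }

  broken <- tmpl
  bad <- which(m$mask)[1]
  broken$data[bad] <- 0
  expect_error(ratio_image(img, broken, m), "numerical-domain error.*voxel")
})

test_that("ratio histogram locates the mode and fits the peak", {
  tmpl <- make_template_phantom(small_spec())
  m <- brain_mask_from_template(tmpl)

  # degenerate: every ratio exactly 1 -> a single occupied bin containing 1.0
  h1 <- ratio_histogram(ratio_image(tmpl, tmpl, m), m)
  occupied <- which(h1$counts > 0)
  expect_length(occupied, 1)
  expect_lte(h1$bin_edges[occupied], 1.0)
  expect_gte(h1$bin_edges[occupied + 1], 1.0)
  expect_equal(sum(h1$counts), sum(m$mask))

  # Gaussian-distributed ratios: fitted center recovers the generating mean
  set.seed(8)
  dims <- c(50L, 50L, 40L)
  all_mask <- mask_from_logical(array(TRUE, dims))
  vals <- rnorm(prod(dims), mean = 1.2, sd = 0.05)
  rimg <- voxel_image(array(vals, dims), 0.4, unit = "ratio")
  h2 <- ratio_histogram(rimg, all_mask)
  expect_true(h2$fit_converged)
  expect_lt(abs(h2$gauss_center - 1.2), 0.01)
  expect_lt(abs(h2$gauss_sigma - 0.05), 0.01)

  # lesion-like bimodality: the raw mode sits at the healthy peak, not the
  # hypometabolic secondary mass
  set.seed(9)
  n <- prod(dims)
  vals3 <- c(rnorm(0.8 * n, 1.0, 0.04), rnorm(0.2 * n, 0.6, 0.04))
  rimg3 <- voxel_image(array(vals3, dims), 0.4, unit = "ratio")
  h3 <- ratio_histogram(rimg3, all_mask)
  expect_lt(abs(h3$raw_mode_bin_center - 1.0), 0.03)

  tiny <- mask_from_logical(array(c(TRUE, rep(FALSE, prod(dims) - 1)), dims))
  expect_error(ratio_histogram(rimg, tiny), "validation error")
})

test_that("histogram factor recovers pure global scaling to within a bin", {
  tmpl <- make_template_phantom(small_spec())
  m <- brain_mask_from_template(tmpl)
  for (k in c(0.7, 1.0, 1.3, 2.1)) {
    res <- normalization_factor_histogram(with_data(tmpl, k * tmpl$data), tmpl, m)
    expect_lt(abs(res$factor - k), 0.01 + 1e-9)
    expect_equal(res$normalized_image$data[m$mask], tmpl$data[m$mask],
                 tolerance = 0.02)
    expect_identical(res$normalized_image$unit, "normalized")
  }
})

test_that("the histogram mode ignores a focal lesion that biases the mean", {
  spec <- small_spec(noise_cv = 0.05)
  tmpl <- make_template_phantom(spec)
  m <- brain_mask_from_template(tmpl)
  k <- 1.4

  set.seed(10)
  img <- sample_subject(tmpl, subject_truth(global_scale = k), spec, 11)
  # halve ~10% of in-mask voxels (focal hypometabolism)
  idx <- which(m$mask)
  lesion_idx <- sample(idx, round(0.10 * length(idx)))
  lesioned <- img
  lesioned$data[lesion_idx] <- lesioned$data[lesion_idx] * 0.5

  hist_res <- normalization_factor_histogram(lesioned, tmpl, m)
  mean_res <- normalization_factor_global_mean(lesioned, m)
  expect_lt(abs(hist_res$factor - k), 0.01 + 1e-9)
  expect_lt(mean_res$factor, hist_res$factor)
})

test_that("global-mean factor equals the exhaustive in-mask mean", {
  tmpl <- make_template_phantom(small_spec())
  m <- brain_mask_from_template(tmpl)

  const <- voxel_image(array(2.5, dim = dim(tmpl$data)), 0.4, unit = "SUV")
  res <- normalization_factor_global_mean(const, m)
  expect_equal(res$factor, 2.5)
  expect_true(all(res$normalized_image$data[m$mask] == 1))

  set.seed(11)
  img <- with_data(tmpl, tmpl$data * runif(length(tmpl$data), 0.5, 2))
  res2 <- normalization_factor_global_mean(img, m)
  total <- 0; count <- 0
  for (v in which(m$mask)) { total <- total + img$data[v]; count <- count + 1 }
  expect_equal(res2$factor, total / count, tolerance = 1e-12)
})

test_that("normalize_none passes the image through with factor 1", {
  img <- random_image()
  res <- normalize_none(img)
  expect_identical(res$factor, 1.0)
  expect_identical(res$normalized_image$data, img$data)
  expect_identical(res$normalized_image$unit, "SUV")
})

test_that("histogram factor is scale-equivariant", {
  spec <- small_spec(noise_cv = 0.05)
  tmpl <- make_template_phantom(spec)
  m <- brain_mask_from_template(tmpl)
  img <- sample_subject(tmpl, subject_truth(global_scale = 1.1), spec, 21)
  f1 <- normalization_factor_histogram(img, tmpl, m)$factor
  for (k in c(0.8, 1.5)) {
    fk <- normalization_factor_histogram(with_data(img, k * img$data), tmpl, m)$factor
    expect_lt(abs(fk - k * f1), 0.02 * k)
  }
})

test_that("histogram factor dominates global mean under focal lesions", {
  spec <- small_spec(noise_cv = 0.05)
  tmpl <- make_template_phantom(spec)
  m <- brain_mask_from_template(tmpl)
  les <- lesion_sphere(spec, radius_mm = 2.2)   # ~15% of the mask
  expect_lt(sum(les & m$mask) / sum(m$mask), 0.20)

  set.seed(12)
  wins <- 0L
  n_rep <- 20L
  for (r in seq_len(n_rep)) {
    k <- rlnorm(1, 0, 0.3)
    truth <- subject_truth(global_scale = k, lesion_mask = les, lesion_factor = 0.6)
    img <- sample_subject(tmpl, truth, spec, rng_seed = 5000 + r)
    e_hist <- abs(normalization_factor_histogram(img, tmpl, m)$factor - k)
    e_mean <- abs(normalization_factor_global_mean(img, m)$factor - k)
    if (e_hist <= e_mean) wins <- wins + 1L
  }
  expect_gte(wins, ceiling(0.95 * n_rep))
})
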