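# small synthetic atlas with controllable mean/sd for Z-map tests
make_toy_atlas <- function(dims = c(20L, 20L, 20L), mean_val = 1, sd_val = 0.1,
                           mask = NULL) {
  if (is.null(mask)) mask <- array(TRUE, dims)
  structure(list(
    mean_img = voxel_image(array(mean_val, dims), 0.4, unit = "normalized"),
    sd_img = voxel_image(array(sd_val, dims), 0.4, unit = "normalized"),
    n_subjects = 10L, mask = mask_from_logical(mask), method = "histogram",
    threshold_fraction = 0.5, factors = rep(1, 10),
    fit_converged = rep(TRUE, 10), normalized_images = NULL
  ), class = "atlas_template")
}

test_that("Z maps implement (x - mu) / sigma per voxel", {
  at <- make_toy_atlas()
  subj <- voxel_image(array(1, dim(at$mean_img$data)), 0.4, unit = "normalized")
  z0 <- zscore_map(subj, at)
  expect_true(all(z0$values[at$mask$mask] == 0))

  subj2 <- subj
  subj2$data[3, 4, 5] <- 1 + 2 * 0.1
  z2 <- zscore_map(subj2, at)
  expect_equal(z2$values[3, 4, 5], 2)

  set.seed(20)
  dims <- dim(at$mean_img$data)
  at$mean_img$data[] <- runif(prod(dims), 0.5, 2)
  at$sd_img$data[] <- runif(prod(dims), 0.05, 0.3)
  subj3 <- voxel_image(array(runif(prod(dims), 0.3, 2.5), dims), 0.4,
                       unit = "normalized")
  z3 <- zscore_map(subj3, at)
  for (v in sample(prod(dims), 200))
    expect_equal(z3$values[v],
                 (subj3$data[v] - at$mean_img$data[v]) / at$sd_img$data[v],
                 tolerance = 1e-12)
})

test_that("zero-SD voxels are excluded from Z maps with a reported count", {
  at <- make_toy_atlas()
  at$sd_img$data[1, 1, 1] <- 0
  subj <- voxel_image(array(1.2, dim(at$mean_img$data)), 0.4, unit = "normalized")
  expect_message(z <- zscore_map(subj, at), "1 in-mask voxels")
  expect_true(is.na(z$values[1, 1, 1]))
  expect_identical(z$n_invalid, 1L)
})

test_that("Z maps are invariant to joint rescaling of subject and atlas", {
  at <- make_toy_atlas()
  set.seed(21)
  dims <- dim(at$mean_img$data)
  subj <- voxel_image(array(runif(prod(dims), 0.5, 2), dims), 0.4,
                      unit = "normalized")
  z1 <- zscore_map(subj, at)
  k <- 3.7
  at_k <- at
  at_k$mean_img$data <- k * at$mean_img$data
  at_k$sd_img$data <- k * at$sd_img$data
  subj_k <- voxel_image(k * subj$data, 0.4, unit = "normalized")
  z2 <- zscore_map(subj_k, at_k)
  expect_equal(z1$values, z2$values, tolerance = 1e-12)
})

test_that("the empirical 95% interval keeps 2.5% of voxels in each tail", {
  at <- make_toy_atlas()
  set.seed(22)
  dims <- dim(at$mean_img$data)
  subj <- voxel_image(array(rnorm(prod(dims), 1, 0.1), dims), 0.4,
                      unit = "normalized")
  z <- threshold_zmap_95(zscore_map(subj, at))
  n <- sum(at$mask$mask)
  expect_lte(abs(sum(z$sig_mask_low) - 0.025 * n), 2)
  expect_lte(abs(sum(z$sig_mask_high) - 0.025 * n), 2)
  expect_true(all(z$sig_mask_low[!at$mask$mask] == FALSE))
  expect_identical(sum(z$sig_mask_low & z$sig_mask_high), 0L)

  # tie degeneracy: identical values produce empty significance masks
  flat <- voxel_image(array(1, dims), 0.4, unit = "normalized")
  zf <- threshold_zmap_95(zscore_map(flat, at))
  expect_identical(sum(zf$sig_mask_low) + sum(zf$sig_mask_high), 0L)
})

test_that("empirical Z thresholds approach the normal 95% quantiles", {
  dims <- c(50L, 50L, 40L)
  at <- make_toy_atlas(dims, mean_val = 0, sd_val = 1)
  set.seed(23)
  subj <- voxel_image(array(rnorm(prod(dims)), dims), 0.4, unit = "normalized")
  z <- threshold_zmap_95(zscore_map(subj, at))
  expect_lt(abs(z$threshold_high - 1.96), 0.05)
  expect_lt(abs(z$threshold_low + 1.96), 0.05)

  few <- make_toy_atlas(c(4L, 4L, 4L), mean_val = 0, sd_val = 1)
  small_subj <- voxel_image(array(rnorm(64), c(4L, 4L, 4L)), 0.4,
                            unit = "normalized")
  expect_error(threshold_zmap_95(zscore_map(small_subj, few)), "validation error")
})

test_that("Benjamini-Hochberg selection matches the literal step-up procedure", {
  out <- bh_fdr(c(0.001, 0.5, 0.9), q = 0.05)
  expect_identical(out$significant, c(TRUE, FALSE, FALSE))
  expect_equal(out$p_threshold, 0.001)

  expect_identical(bh_fdr(rep(1, 5), 0.05)$significant, rep(FALSE, 5))
  expect_identical(bh_fdr(rep(0, 5), 0.05)$significant, rep(TRUE, 5))
  expect_error(bh_fdr(numeric(0), 0.05), "validation error")
  expect_error(bh_fdr(c(0.5, 1.2), 0.05), "validation error")

  set.seed(24)
  for (rep in 1:20) {
    p <- c(runif(50), runif(10, 0, 0.01))
    q <- sample(c(0.01, 0.05, 0.1), 1)
    expect_identical(bh_fdr(p, q)$significant, oracle_bh_stepup(p, q))
  }
})

test_that("lowering a p-value never shrinks the BH significant set", {
  set.seed(25)
  for (rep in 1:10) {
    p <- runif(40)
    base <- bh_fdr(p, 0.05)$significant
    i <- sample(40, 1)
    p2 <- p
    p2[i] <- p[i] * runif(1)
    lowered <- bh_fdr(p2, 0.05)$significant
    expect_true(all(lowered[base]))
  }
})

test_that("group t maps reproduce the textbook pooled t-test per voxel", {
  dims <- c(4L, 4L, 4L)
  mk <- function(v) voxel_image(array(v, dims), 0.4, unit = "normalized")
  group <- lapply(c(1, 2, 3), mk)
  atlas_subjects <- lapply(c(2, 2, 2, 2), mk)
  # break the zero-variance atlas sample with a tiny perturbation at one voxel
  atlas_subjects[[1]]$data[1, 1, 1] <- 2.001
  m <- mask_from_logical(array(TRUE, dims))
  res <- group_ttest(group, atlas_subjects, m, q = 0.05)

  want <- oracle_pooled_t(c(1, 2, 3), c(2.001, 2, 2, 2))
  expect_equal(res$t_map$values[1, 1, 1], want$t, tolerance = 1e-12)
  expect_equal(res$p_map[1, 1, 1], want$p, tolerance = 1e-12)

  tt <- t.test(c(1, 2, 3), c(2.001, 2, 2, 2), var.equal = TRUE)
  expect_equal(res$t_map$values[1, 1, 1], unname(tt$statistic), tolerance = 1e-9)

  expect_error(group_ttest(group[1], atlas_subjects, m), "configuration error")
})

test_that("Welch option reproduces t.test(var.equal = FALSE)", {
  dims <- c(3L, 3L, 3L)
  set.seed(26)
  g <- lapply(1:4, function(i) voxel_image(array(rnorm(27, 1), dims), 0.4,
                                           unit = "normalized"))
  a <- lapply(1:5, function(i) voxel_image(array(rnorm(27, 1, 2), dims), 0.4,
                                           unit = "normalized"))
  m <- mask_from_logical(array(TRUE, dims))
  res <- group_ttest(g, a, m, var_equal = FALSE)
  gv <- sapply(g, function(im) im$data[2, 2, 2])
  av <- sapply(a, function(im) im$data[2, 2, 2])
  tt <- t.test(gv, av)
  expect_equal(res$t_map$values[2, 2, 2], unname(tt$statistic), tolerance = 1e-9)
  expect_equal(res$p_map[2, 2, 2], tt$p.value, tolerance = 1e-9)
})

test_that("FDR keeps the family-wise null discovery rate near q on null phantoms", {
  spec <- small_spec(noise_cv = 0.05)
  tmpl <- make_template_phantom(spec)
  pop <- sample_population(tmpl, spec, 12, seed = 27)
  at <- build_atlas(pop$images, "histogram")

  n_rep <- 50L
  any_sig <- 0L
  for (r in seq_len(n_rep)) {
    nulls <- sample_population(tmpl, spec, 5, seed = 900 + r)
    norm <- lapply(nulls$images, function(im)
      normalization_factor_histogram(im, at$mean_img, at$mask)$normalized_image)
    res <- group_ttest(norm, at$normalized_images, at$mask, q = 0.05)
    if (res$n_sig_increase + res$n_sig_decrease > 0) any_sig <- any_sig + 1L
  }
  # binomial(50, 0.05) has mean 2.5, sd ~1.5; allow ~3 sd of slack
  expect_lte(any_sig, 8L)
})
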