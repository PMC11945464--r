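test_that("WM mask rule: strict mean-probability threshold", {
  shape <- c(16, 16, 16)
  a <- array(0.4, dim = shape); b <- array(0.8, dim = shape)
  a[1, 1, 1] <- 0.5; b[1, 1, 1] <- 0.5          # mean exactly 0.5 -> out
  a[2, 1, 1] <- 0;   b[2, 1, 1] <- 0.2          # mean 0.1 -> out
  m <- build_wm_mask(list(volume_grid(a), volume_grid(b)), threshold = 0.5)
  expect_equal(m$mask$data[1, 1, 1], 0)
  expect_equal(m$mask$data[2, 1, 1], 0)
  expect_equal(m$mask$data[3, 1, 1], 1)          # mean 0.6 -> in
  expect_equal(m$n_subjects_averaged, 2L)

  # all-ones maps: mask equals the whole grid
  ones <- list(volume_grid(array(1, dim = shape)))
  expect_equal(sum(build_wm_mask(ones)$mask$data), prod(shape))

  expect_error(build_wm_mask(list()), "empty list")
  expect_error(build_wm_mask(list(volume_grid(array(2, dim = shape)))),
               "outside \\[0, 1\\]")
  expect_error(build_wm_mask(list(volume_grid(array(0.1, dim = shape)))),
               "degenerate")
})

test_that("per-voxel OLS matches the normal-equations oracle", {
  shape <- c(16L, 16L, 16L)
  mask <- box_mask(shape)
  in_idx <- which(mask$mask$data > 0)
  for (case in 1:20) {
    set.seed(100 + case)
    n <- sample(6:12, 1)
    ages <- sample(20:61, n, replace = TRUE)
    while (length(unique(ages)) < 3) ages <- sample(20:61, n, replace = TRUE)
    vols <- lapply(seq_len(n), function(i)
      volume_grid(array(rnorm(prod(shape), 1, 0.3), dim = shape)))
    atlas <- fit_atlas(vols, ages, mask)
    ref <- atlas$ref_age
    expect_equal(ref, mean(ages))
    check <- sample(in_idx, 25)
    for (v in check) {
      y <- vapply(vols, function(vol) vol$data[v], numeric(1))
      o <- oracle_ols(y, ages, ref)
      expect_equal(c(atlas$beta0$data[v], atlas$beta_age$data[v],
                     atlas$beta_age2$data[v]), o$beta, tolerance = 1e-8)
      expect_equal(atlas$rmse$data[v], o$rmse, tolerance = 1e-8)
    }
  }
})

test_that("noiseless quadratic cohorts are recovered exactly", {
  shape <- c(16L, 16L, 16L)
  beta <- c(1.07, 0.002, -2e-4)
  ages <- seq(25, 60, by = 5)
  vols <- law_cohort(shape, ages, beta, noise_sd = 0)
  atlas <- fit_atlas(vols, ages, box_mask(shape))
  idx <- which(box_mask(shape)$mask$data > 0)[1]
  expect_equal(atlas$beta0$data[idx], beta[1], tolerance = 1e-8)
  expect_equal(atlas$beta_age$data[idx], beta[2], tolerance = 1e-8)
  expect_equal(atlas$beta_age2$data[idx], beta[3], tolerance = 1e-8)
  # zero residual -> degenerate: excluded from the mask, coefficients kept
  expect_equal(sum(atlas$mask$mask$data), 0)
  expect_gt(sum(atlas$degenerate$data), 0)
})

test_that("constant cohort with varying ages gives beta0 = c and rmse 0", {
  shape <- c(16L, 16L, 16L)
  vols <- lapply(1:6, function(i) volume_grid(array(2.5, dim = shape)))
  atlas <- fit_atlas(vols, c(20, 30, 40, 50, 60, 25), box_mask(shape))
  idx <- which(box_mask(shape)$mask$data > 0)
  expect_true(all(abs(atlas$beta0$data[idx] - 2.5) < 1e-10))
  expect_true(all(abs(atlas$beta_age$data[idx]) < 1e-10))
  expect_true(all(abs(atlas$rmse$data[idx]) < 1e-10))
  expect_true(all(atlas$degenerate$data[idx] == 1))
})

test_that("design guards: distinct ages, alignment, minimum cohort", {
  shape <- c(16L, 16L, 16L)
  vols <- law_cohort(shape, c(30, 30, 40, 40), c(1, 0, 0), noise_sd = 0.1)
  expect_error(fit_atlas(vols, c(30, 30, 40, 40), box_mask(shape)),
               "distinct ages")
  expect_error(fit_atlas(vols, c(30, 40, 50), box_mask(shape)), "4 volumes")
  expect_error(fit_atlas(vols[1:3], c(30, 40, 50), box_mask(shape)),
               "at least 4")
})

test_that("rmse denominator convention: df (n-3) default, n optional", {
  shape <- c(16L, 16L, 16L)
  ages <- c(25, 33, 41, 49, 57, 61)
  vols <- law_cohort(shape, ages, c(1.07, 0.002, -2e-4), noise_sd = 0.2,
                     seed = 9)
  a_df <- fit_atlas(vols, ages, box_mask(shape))
  a_n <- fit_atlas(vols, ages, box_mask(shape), rmse_denominator = "n")
  idx <- which(box_mask(shape)$mask$data > 0)[5]
  expect_equal(a_n$rmse$data[idx],
               a_df$rmse$data[idx] * sqrt((6 - 3) / 6), tolerance = 1e-12)
})

test_that("prediction: centering identity, hand arithmetic, extrapolation warning", {
  shape <- c(16L, 16L, 16L)
  beta <- c(1.0, 0.01, -0.001)
  ages <- c(30, 35, 40, 45, 50, 55)
  vols <- law_cohort(shape, ages, beta, noise_sd = 0.05, seed = 4)
  atlas <- fit_atlas(vols, ages, box_mask(shape))
  # centering identity, bit-for-bit
  expect_identical(predict(atlas, atlas$ref_age)$data, atlas$beta0$data)
  # E{R1} at ref_age + 2 from the fitted coefficients, by hand
  idx <- which(atlas$mask$mask$data > 0)[1]
  manual <- atlas$beta0$data[idx] + atlas$beta_age$data[idx] * 2 +
    atlas$beta_age2$data[idx] * 4
  expect_equal(predict(atlas, atlas$ref_age + 2)$data[idx], manual,
               tolerance = 1e-12)
  # beta = (1.0, 0.01, -0.001) at a = 2 gives 1.016 (population value,
  # noise-free fit): check on an exact cohort
  exact <- law_cohort(shape, ages, beta, noise_sd = 0)
  at2 <- fit_atlas(exact, ages, box_mask(shape))
  expect_equal(predict(at2, at2$ref_age + 2)$data[idx],
               1.0 + 0.01 * 2 - 0.001 * 4, tolerance = 1e-8)
  expect_warning(predict(atlas, atlas$ref_age + 61), "extrapolation")
})

test_that("coefficient error shrinks with noise and with cohort size", {
  shape <- c(16L, 16L, 16L)
  beta <- c(1.07, 0.002, -2e-4)
  mask <- box_mask(shape)
  idx <- which(mask$mask$data > 0)
  err <- function(n, sd) {
    ages <- round(seq(20, 61, length.out = n))
    atlas <- fit_atlas(law_cohort(shape, ages, beta, sd, seed = 21),
                       ages, mask)
    mean(abs(atlas$beta0$data[idx] - beta[1]))
  }
  e <- c(err(8, 0.3), err(8, 0.1), err(8, 0.01))
  expect_true(all(diff(e) < 0))                 # monotone in noise
  e2 <- c(err(8, 0.2), err(32, 0.2), err(128, 0.2))
  expect_true(all(diff(e2) < 0))                # monotone in n
})

test_that("atlas persists and reloads faithfully", {
  shape <- c(16L, 16L, 16L)
  ages <- c(25, 33, 41, 49, 57, 61)
  vols <- law_cohort(shape, ages, c(1.07, 0.002, -2e-4), 0.15, seed = 2)
  atlas <- fit_atlas(vols, ages, box_mask(shape))
  dir <- withr::local_tempdir()
  write_atlas(atlas, dir)
  back <- read_atlas(dir)
  expect_equal(back$ref_age, atlas$ref_age)
  expect_equal(back$rmse$data, atlas$rmse$data, tolerance = 1e-6)
  expect_equal(back$mask$mask$data, atlas$mask$mask$data)
  expect_equal(back$rmse_denominator, "df")
})
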