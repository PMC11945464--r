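small_atlas <- function(shape = c(16L, 16L, 16L), noise_sd = 0.15, seed = 8) {
  ages <- c(25, 31, 37, 43, 49, 55, 61, 28)
  vols <- law_cohort(shape, ages, c(1.07, 0.002, -2e-4), noise_sd, seed = seed)
  list(atlas = fit_atlas(vols, ages, box_mask(shape)), ages = ages)
}

test_that("z-map is zero when the subject equals the prediction", {
  sa <- small_atlas()
  atlas <- sa$atlas
  subj <- predict(atlas, 45)
  subj$data[is.na(subj$data)] <- 0
  zm <- compute_zmap(subj, 45, atlas)
  m <- atlas$mask$mask$data > 0
  expect_true(all(abs(zm$z$data[m]) < 1e-10))
  expect_true(all(is.na(zm$z$data[!m])))
})

test_that("z-score substitution at the reference WM and GP magnitudes", {
  # hand-built one-voxel-scale atlas: E{R1} = 1.07, RMSE = 0.15 -> R1 = 1.97
  # gives z = 6; GP-like voxel E = 1.10, RMSE = 0.09, R1 = 1.19 -> z = 1
  sa <- small_atlas()
  atlas <- sa$atlas
  m_idx <- which(atlas$mask$mask$data > 0)
  v1 <- m_idx[1]; v2 <- m_idx[2]
  atlas$beta0$data[v1] <- 1.07; atlas$rmse$data[v1] <- 0.15
  atlas$beta0$data[v2] <- 1.10; atlas$rmse$data[v2] <- 0.09
  atlas$beta_age$data[c(v1, v2)] <- 0
  atlas$beta_age2$data[c(v1, v2)] <- 0
  subj <- predict(atlas, 40)
  subj$data[is.na(subj$data)] <- 0
  subj$data[v1] <- 1.97
  subj$data[v2] <- 1.19
  zm <- compute_zmap(subj, 40, atlas)
  expect_equal(zm$z$data[v1], 6.0, tolerance = 1e-12)
  expect_equal(zm$z$data[v2], 1.0, tolerance = 1e-12)
})

test_that("z-map guards: grid mismatch and non-positive RMSE", {
  sa <- small_atlas()
  wrong <- volume_grid(array(1, dim = c(15, 16, 16)))
  expect_error(compute_zmap(wrong, 40, sa$atlas), "grid mismatch")
  bad <- sa$atlas
  bad$rmse$data[which(bad$mask$mask$data > 0)[1]] <- 0
  subj <- volume_grid(array(1, dim = c(16, 16, 16)))
  expect_error(compute_zmap(subj, 40, bad), "invariant")
})

test_that("component labeling matches brute-force flood fill on random fields", {
  for (seed in 1:20) {
    set.seed(seed)
    mask <- array(runif(8^3) < 0.35, dim = c(8, 8, 8))
    for (conn in c(6, 18, 26)) {
      got <- label_components(mask, conn)
      ref <- oracle_label(mask, conn)
      expect_true(same_partition(got$labels, ref),
                  info = sprintf("seed %d, connectivity %d", seed, conn))
      expect_equal(sort(got$sizes, decreasing = TRUE), got$sizes)
      expect_equal(sum(got$sizes), sum(mask))
      expect_equal(sort(got$sizes), sort(tabulate(ref[ref > 0])),
                   ignore_attr = TRUE)
    }
  }
})

test_that("cluster extent boundary: 99 voxels discarded, 100 retained", {
  z <- array(0, dim = c(16, 16, 16))
  # a 100-voxel connected block: 5 x 5 x 4
  z[2:6, 2:6, 2:5] <- 10
  vg <- volume_grid(z)
  cs <- cluster_correct(vg, threshold = 6, min_extent = 100)
  expect_equal(cs$sizes, 100L)
  z[2, 2, 2] <- 0  # now 99 voxels
  cs2 <- cluster_correct(volume_grid(z), threshold = 6, min_extent = 100)
  expect_length(cs2$sizes, 0L)
  expect_true(all(cs2$labels$data == 0L))
  # all-zero map
  cs3 <- cluster_correct(volume_grid(array(0, dim = c(16, 16, 16))))
  expect_length(cs3$sizes, 0L)
})

test_that("thresholding is strict and one-sided; two-sided behind the flag", {
  z <- array(0, dim = c(16, 16, 16))
  z[4:9, 4:9, 4:9] <- 6          # exactly at threshold: excluded
  z[12:14, 12:14, 12:14] <- -50  # strong depression: excluded one-sided
  cs <- cluster_correct(volume_grid(z), threshold = 6, min_extent = 1)
  expect_length(cs$sizes, 0L)
  cs2 <- cluster_correct(volume_grid(z), threshold = 6, min_extent = 1,
                         two_sided = TRUE)
  expect_equal(cs2$sizes, 27L)
})

test_that("labels are ordered by decreasing size with deterministic tie-break", {
  z <- array(0, dim = c(16, 16, 16))
  z[2:3, 2:3, 2:3] <- 10          # 8 voxels, smallest linear index
  z[10:12, 10:12, 10:12] <- 10    # 27 voxels
  z[14:15, 14:15, 14:15] <- 10    # 8 voxels, larger linear index
  cs <- cluster_correct(volume_grid(z), threshold = 6, min_extent = 1)
  expect_equal(cs$sizes, c(27L, 8L, 8L))
  expect_equal(cs$labels$data[10, 10, 10], 1L)
  expect_equal(cs$labels$data[2, 2, 2], 2L)
  expect_equal(cs$labels$data[14, 14, 14], 3L)
})

test_that("retained clusters and supra-threshold mass are monotone in the settings", {
  set.seed(77)
  z <- array(rnorm(20^3, 0, 2.5), dim = c(20, 20, 20))
  z <- smooth_gaussian_3d(z, 2, c(1, 1, 1)) * 4
  vg <- volume_grid(z)
  thresholds <- c(1, 2, 3, 4)
  n_vox <- vapply(thresholds, function(t)
    sum(cluster_correct(vg, t, min_extent = 5)$sizes), numeric(1))
  expect_true(all(diff(n_vox) <= 0))
  extents <- c(1, 5, 20, 80)
  n_cl <- vapply(extents, function(e)
    length(cluster_correct(vg, 1, min_extent = e)$sizes), numeric(1))
  expect_true(all(diff(n_cl) <= 0))
})

test_that("translation equivariance of cluster centroids", {
  set.seed(5)
  z <- array(0, dim = c(20, 20, 20))
  z[5:8, 5:8, 5:8] <- 10
  z[12:13, 6:9, 11:14] <- 10
  shifted <- array(0, dim = c(20, 20, 20))
  shifted[2:20, , ] <- z[1:19, , ]   # +1 voxel along x
  s1 <- summarize_clusters(cluster_correct(volume_grid(z), 6, 1),
                           volume_grid(z))
  s2 <- summarize_clusters(cluster_correct(volume_grid(shifted), 6, 1),
                           volume_grid(shifted))
  expect_equal(s2$centroid_x, s1$centroid_x + 1)
  expect_equal(s2$centroid_y, s1$centroid_y)
  expect_equal(s2$centroid_z, s1$centroid_z)
})

test_that("cluster summary: empty set, symmetric cube, 0-based coordinates", {
  empty <- cluster_correct(volume_grid(array(0, dim = c(16, 16, 16))))
  expect_equal(nrow(summarize_clusters(empty, volume_grid(array(0, dim = c(16, 16, 16))))), 0L)

  z <- array(0, dim = c(16, 16, 16))
  z[6:10, 6:10, 6:10] <- 8   # 5^3 cube of constant z = 8
  vg <- volume_grid(z)
  tab <- summarize_clusters(cluster_correct(vg, 6, 1), vg)
  expect_equal(tab$size_vox, 125L)
  expect_equal(tab$peak_z, 8)
  expect_equal(c(tab$centroid_x, tab$centroid_y, tab$centroid_z),
               rep(7, 3))    # cube center voxel 8 (1-based) = 7 (0-based)
})

test_that("held-out null z-scores follow the small-sample t prediction", {
  # For a held-out control, z = residual / fitted RMSE; sampling theory gives
  # z / sqrt(1 + h) ~ t_{n-p}, so the pooled SD should sit near
  # sqrt((1 + h) (n-p)/(n-p-2)) with h ~ p/(n-p-1), approaching 1 as the
  # reference cohort grows.
  spec <- phantom_spec(grid_shape = c(24L, 24L, 24L), smoothing_fwhm = 0,
                       seed = 42L)
  co <- generate_cohort(spec, n_controls = 45, n_welders = 0,
                        lesion_policy = NULL)
  train <- 1:25
  held <- 26:45
  mask <- build_wm_mask(co$tissue_probability_maps[train])
  atlas <- fit_atlas(co$volumes[train], co$records$age[train], mask)
  m <- atlas$mask$mask$data > 0
  z <- unlist(lapply(held, function(i)
    compute_zmap(co$volumes[[i]], co$records$age[i], atlas)$z$data[m]))
  n <- 25; p <- 3
  pred_sd <- sqrt((1 + p / (n - p - 1)) * (n - p) / (n - p - 2))
  expect_lt(abs(mean(z)), 0.05)
  expect_lt(abs(sd(z) - pred_sd) / pred_sd, 0.08)
})

test_that("an injected lesion surfaces as the single retained cluster", {
  spec <- phantom_spec(grid_shape = c(32L, 32L, 32L), seed = 19L)
  lab <- generate_tissue_labels(spec)
  co <- generate_cohort(spec, n_controls = 12, n_welders = 0,
                        lesion_policy = NULL)
  mask <- build_wm_mask(co$tissue_probability_maps)
  atlas <- fit_atlas(co$volumes, co$records$age, mask)
  ctr <- round(dim(lab$data) / 2)
  les <- lesion_spec(ctr, radius = 4, delta_R1 = 8 * spec$noise_sd)
  subj <- generate_subject(spec, lab, 44, lesions = list(les),
                           subject_seed = 4242L)
  zm <- compute_zmap(subj, 44, atlas, "lesioned")
  cs <- cluster_correct(zm, threshold = 6, min_extent = 100)
  expect_length(cs$sizes, 1L)
  # the retained cluster overlaps the true lesion sphere
  d2 <- (slice.index(lab$data, 1) - ctr[1])^2 +
    (slice.index(lab$data, 2) - ctr[2])^2 +
    (slice.index(lab$data, 3) - ctr[3])^2
  expect_gt(sum(cs$labels$data > 0 & d2 <= les$radius^2), 0)
})
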