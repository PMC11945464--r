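# Synthetic brain phantoms: nested-ellipsoid tissue geometry, a quadratic
# age law for R1, spatially smooth between-subject Gaussian residuals, and
# optional focal R1 elevations emulating Mn deposits in exposed subjects.
# Everything is deterministic given the spec seed.

TISSUE_LEVELS <- c(background = 0L, GM = 1L, WM = 2L, GP = 3L)

#' Specification of a synthetic R1 phantom cohort
#'
#' Collects every generative parameter: grid geometry, per-tissue baseline
#' R1, the global quadratic age dependence, the between-subject residual
#' noise model, and the seed. The defaults emulate a healthy adult cohort at
#' 3T: frontal-white-matter R1 of 1.07 s^-1 and globus pallidus R1 of
#' 1.10 s^-1 at the reference age, with a residual SD of 0.15 s^-1.
#'
#' @param grid_shape Integer length-3, voxel counts per axis (all >= 16).
#' @param voxel_size Numeric length-3, mm per axis.
#' @param tissue_geometry List of nested-ellipsoid parameters:
#'   `brain_frac`, `wm_frac` (ellipsoid semi-axes as fractions of the grid
#'   half-extent), `gp_radius_mm`, `gp_offset_frac` (GP blob centers as a
#'   signed fractional offset from grid center along x, plus a y shift).
#' @param tissue_baseline_R1 Named numeric: mean R1 (s^-1) for GM, WM, GP.
#' @param age_coeffs Numeric length-2 `(beta_age, beta_age2)` in s^-1/yr and
#'   s^-1/yr^2, applied globally to all brain tissue.
#' @param ref_age Reference (centering) age in whole years; at this age a
#'   noise-free subject's tissue equals `tissue_baseline_R1` exactly.
#' @param noise_sd Between-subject residual SD in s^-1 (marginal, per voxel).
#' @param smoothing_fwhm Spatial FWHM (mm) of the residual field; 0 means
#'   voxel-wise independent noise.
#' @param seed Integer seed; all cohort-level randomness derives from it.
#'
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(64L, 64L, 64L),
                         voxel_size = c(1, 1, 1),
                         tissue_geometry = list(brain_frac = 0.9,
                                                wm_frac = 0.6,
                                                gp_radius_mm = 4,
                                                gp_offset_frac = 0.25),
                         tissue_baseline_R1 = c(GM = 0.65, WM = 1.07, GP = 1.10),
                         age_coeffs = c(beta_age = 0.002, beta_age2 = -2e-4),
                         ref_age = 39,
                         noise_sd = 0.15,
                         smoothing_fwhm = 3,
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 16L))
    stop("phantom_spec: grid_shape must be 3 integers, all >= 16", call. = FALSE)
  if (any(voxel_size <= 0))
    stop("phantom_spec: voxel_size must be strictly positive", call. = FALSE)
  for (nm in c("GM", "WM", "GP"))
    if (is.na(tissue_baseline_R1[nm]) || tissue_baseline_R1[nm] <= 0)
      stop("phantom_spec: tissue_baseline_R1 must be > 0 for ", nm, call. = FALSE)
  if (noise_sd < 0) stop("phantom_spec: noise_sd must be >= 0", call. = FALSE)
  if (smoothing_fwhm < 0) stop("phantom_spec: smoothing_fwhm must be >= 0", call. = FALSE)
  if (ref_age < 0) stop("phantom_spec: ref_age must be >= 0", call. = FALSE)
  structure(list(grid_shape = grid_shape,
                 voxel_size = as.numeric(voxel_size),
                 tissue_geometry = tissue_geometry,
                 tissue_baseline_R1 = tissue_baseline_R1,
                 age_coeffs = as.numeric(age_coeffs),
                 ref_age = as.numeric(ref_age),
                 noise_sd = as.numeric(noise_sd),
                 smoothing_fwhm = as.numeric(smoothing_fwhm),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' A focal R1 elevation (synthetic Mn deposit)
#'
#' Mn accumulation only raises R1, so `delta_R1` must be non-negative.
#'
#' @param center Voxel coordinates (1-based, length 3) of the lesion center.
#' @param radius Radius in mm (> 0).
#' @param delta_R1 Additive R1 elevation in s^-1 (>= 0).
#' @return An object of class `lesion_spec`.
#' @export
lesion_spec <- function(center, radius, delta_R1) {
  if (length(center) != 3L) stop("lesion_spec: center must be length 3", call. = FALSE)
  if (radius <= 0) stop("lesion_spec: radius must be > 0", call. = FALSE)
  if (delta_R1 < 0) stop("lesion_spec: delta_R1 must be >= 0", call. = FALSE)
  structure(list(center = as.numeric(center), radius = as.numeric(radius),
                 delta_R1 = as.numeric(delta_R1)), class = "lesion_spec")
}

# Squared normalized ellipsoid distance for every voxel: <=1 is inside.
ellipsoid_field <- function(shape, center, semiaxes) {
  x <- (seq_len(shape[1]) - center[1]) / semiaxes[1]
  y <- (seq_len(shape[2]) - center[2]) / semiaxes[2]
  z <- (seq_len(shape[3]) - center[3]) / semiaxes[3]
  outer(outer(x^2, y^2, `+`), z^2, `+`)
}

#' Generate the tissue label volume of a phantom
#'
#' Deterministic nested-ellipsoid geometry: an outer brain ellipsoid (GM
#' shell), an inner WM core, and two spherical GP blobs embedded in the core.
#' Labels: 0 background, 1 GM, 2 WM, 3 GP; every voxel gets exactly one.
#'
#' @param spec A [phantom_spec()].
#' @return A [volume_grid()] of integer labels.
#' @export
generate_tissue_labels <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  g <- spec$tissue_geometry
  if (is.null(g$gp_radius_mm) || g$gp_radius_mm <= 0)
    stop("generate_tissue_labels: invalid spec: GP radius must be > 0", call. = FALSE)
  shape <- spec$grid_shape
  center <- (shape + 1) / 2
  half <- (shape - 1) / 2
  brain_ax <- pmax(g$brain_frac * half, 1e-9)
  wm_ax <- pmax(g$wm_frac * half, 1e-9)

  lab <- array(TISSUE_LEVELS[["background"]], dim = shape)
  lab[ellipsoid_field(shape, center, brain_ax) <= 1] <- TISSUE_LEVELS[["GM"]]
  wm_in <- ellipsoid_field(shape, center, wm_ax) <= 1
  lab[wm_in] <- TISSUE_LEVELS[["WM"]]
  if (!any(wm_in))
    stop("generate_tissue_labels: invalid spec: geometry leaves zero WM voxels",
         call. = FALSE)

  # GP blobs: spheres (in mm) at +/- gp_offset_frac of the half-extent along
  # x, shifted slightly posterior; constrained to the WM core.
  gp_r_vox <- g$gp_radius_mm / spec$voxel_size
  off <- g$gp_offset_frac * half[1]
  for (s in c(-1, 1)) {
    gp_center <- c(center[1] + s * off, center[2] - 0.1 * half[2], center[3])
    gp_in <- ellipsoid_field(shape, gp_center, gp_r_vox) <= 1
    lab[gp_in & wm_in] <- TISSUE_LEVELS[["GP"]]
  }
  volume_grid(lab, voxel_size = spec$voxel_size)
}

# --- spatial smoothing ------------------------------------------------------

gaussian_kernel_1d <- function(sigma_vox) {
  r <- max(1L, ceiling(3 * sigma_vox))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma_vox^2))
  k / sum(k)
}

# Zero-padded separable convolution along one axis of a 3D array.
conv_axis <- function(arr, kernel, axis) {
  d <- dim(arr)
  r <- (length(kernel) - 1L) %/% 2L
  out <- array(0, dim = d)
  n <- d[axis]
  for (t in seq_along(kernel)) {
    s <- t - r - 1L  # shift
    src <- seq_len(n) + s
    ok <- src >= 1L & src <= n
    if (!any(ok)) next
    idx_dst <- which(ok); idx_src <- src[ok]
    if (axis == 1L) out[idx_dst, , ] <- out[idx_dst, , ] + kernel[t] * arr[idx_src, , ]
    else if (axis == 2L) out[, idx_dst, ] <- out[, idx_dst, ] + kernel[t] * arr[, idx_src, ]
    else out[, , idx_dst] <- out[, , idx_dst] + kernel[t] * arr[, , idx_src]
  }
  out
}

#' Separable 3D Gaussian smoothing
#'
#' Plain zero-padded separable convolution with a truncated (3 sigma)
#' Gaussian kernel, specified by its full width at half maximum in mm.
#'
#' @param arr 3D numeric array.
#' @param fwhm_mm FWHM in mm (scalar); 0 returns the input unchanged.
#' @param voxel_size Numeric length-3 voxel size in mm.
#' @param normalize_variance If TRUE, renormalize after each axis pass so a
#'   white-noise input keeps unit marginal variance everywhere (including at
#'   edges); used by the phantom noise model so that `noise_sd` is the
#'   marginal per-voxel SD irrespective of the smoothing FWHM.
#' @return Smoothed 3D array.
#' @export
smooth_gaussian_3d <- function(arr, fwhm_mm, voxel_size = c(1, 1, 1),
                               normalize_variance = FALSE) {
  if (fwhm_mm <= 0) return(arr)
  sigmas <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size
  for (axis in 1:3) {
    if (sigmas[axis] < 1e-8) next
    k <- gaussian_kernel_1d(sigmas[axis])
    arr <- conv_axis(arr, k, axis)
    if (normalize_variance) {
      # per-position sum of squared effective weights along this axis
      n <- dim(arr)[axis]
      r <- (length(k) - 1L) %/% 2L
      ss <- vapply(seq_len(n), function(i) {
        taps <- (i - r):(i + r)
        sum(k[taps >= 1L & taps <= n]^2)
      }, numeric(1))
      scale <- 1 / sqrt(ss)
      if (axis == 1L) arr <- arr * scale
      else if (axis == 2L) arr <- sweep(arr, 2L, scale, `*`)
      else arr <- sweep(arr, 3L, scale, `*`)
    }
  }
  arr
}

# Run expr with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Smooth, variance-calibrated Gaussian residual field (marginal SD = sd).
noise_field <- function(spec, sd, seed, fwhm = spec$smoothing_fwhm) {
  shape <- spec$grid_shape
  eps <- with_seed(seed, array(stats::rnorm(prod(shape)), dim = shape))
  if (fwhm > 0)
    eps <- smooth_gaussian_3d(eps, fwhm, spec$voxel_size, normalize_variance = TRUE)
  sd * eps
}

#' Generate one synthetic subject R1 map
#'
#' The generative model is the inverse of the normative regression fitted
#' downstream: per voxel,
#' \deqn{R_1(r) = \mathrm{base}(t(r)) + \beta_{age} a + \beta_{age^2} a^2
#'   + \epsilon(r) + \sum_l \Delta_l(r),}
#' with \eqn{a = \mathrm{age} - \mathrm{ref\_age}}, tissue t(r), a smooth
#' Gaussian residual \eqn{\epsilon} of marginal SD `noise_sd`, and additive
#' lesion elevations. Background voxels stay at 0; brain voxels are clamped
#' strictly positive.
#'
#' @param spec A [phantom_spec()].
#' @param labels Tissue label volume from [generate_tissue_labels()].
#' @param age Subject age in whole years (>= 0).
#' @param lesions List of [lesion_spec()] (possibly empty).
#' @param subject_seed Integer seed for this subject's residual field.
#' @return An R1 [volume_grid()] in s^-1.
#' @export
generate_subject <- function(spec, labels, age, lesions = list(),
                             subject_seed = spec$seed) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(labels, "volume_grid"))
  if (age < 0) stop("generate_subject: age must be >= 0", call. = FALSE)
  if (abs(age - round(age)) > 1e-9)
    stop("generate_subject: age must be a whole number of years", call. = FALSE)
  lab <- labels$data
  brain <- lab > 0
  base <- array(0, dim = dim(lab))
  base[lab == TISSUE_LEVELS[["GM"]]] <- spec$tissue_baseline_R1[["GM"]]
  base[lab == TISSUE_LEVELS[["WM"]]] <- spec$tissue_baseline_R1[["WM"]]
  base[lab == TISSUE_LEVELS[["GP"]]] <- spec$tissue_baseline_R1[["GP"]]

  a <- age - spec$ref_age
  r1 <- base
  r1[brain] <- r1[brain] + spec$age_coeffs[1] * a + spec$age_coeffs[2] * a^2

  if (spec$noise_sd > 0) {
    eps <- noise_field(spec, spec$noise_sd, subject_seed)
    r1[brain] <- r1[brain] + eps[brain]
  }
  for (les in lesions) {
    stopifnot(inherits(les, "lesion_spec"))
    d2 <- ellipsoid_field(spec$grid_shape, les$center,
                          les$radius / spec$voxel_size)
    inside <- d2 <= 1 & brain
    r1[inside] <- r1[inside] + les$delta_R1
  }
  r1[brain] <- pmax(r1[brain], 1e-6)
  volume_grid(r1, voxel_size = spec$voxel_size)
}

# WM-probability map: softened indicator of WM+GP plus a small smooth
# per-subject perturbation, clipped to [0,1]. Averaged over subjects and
# thresholded at 0.5 this recovers the WM+GP core.
wm_probability_map <- function(spec, labels, subject_seed) {
  ind <- array(0, dim = spec$grid_shape)
  ind[labels$data %in% TISSUE_LEVELS[c("WM", "GP")]] <- 1
  p <- smooth_gaussian_3d(ind, fwhm_mm = 2, voxel_size = spec$voxel_size)
  jitter <- noise_field(spec, sd = 0.04, seed = subject_seed + 1L, fwhm = 4)
  p <- pmin(pmax(p + jitter, 0), 1)
  volume_grid(p, voxel_size = spec$voxel_size)
}

#' Default lesion policy for exposed (welder) subjects
#'
#' Each welder receives 0-3 spherical lesions centered on WM or GP voxels,
#' with radius and R1 elevation drawn uniformly from the stated ranges. The
#' heterogeneity (some welders lesion-free) mirrors the observation that
#' high exposure does not imply uniformly high brain Mn deposition.
#'
#' @param n_lesions_range Integer range of lesion counts per subject.
#' @param delta_range R1 elevation range in s^-1.
#' @param radius_range Radius range in mm.
#' @return A list usable as `lesion_policy` in [generate_cohort()].
#' @export
default_lesion_policy <- function(n_lesions_range = c(0L, 3L),
                                  delta_range = c(0.3, 1.2),
                                  radius_range = c(2.5, 4.5)) {
  list(n_lesions_range = as.integer(n_lesions_range),
       delta_range = as.numeric(delta_range),
       radius_range = as.numeric(radius_range))
}

draw_lesions <- function(policy, candidate_idx, shape) {
  n <- sample(seq(policy$n_lesions_range[1], policy$n_lesions_range[2]), 1L)
  if (n == 0L || length(candidate_idx) == 0L) return(list())
  lapply(seq_len(n), function(i) {
    lin <- candidate_idx[sample.int(length(candidate_idx), 1L)]
    lesion_spec(center = arrayInd(lin, shape)[1, ],
                radius = stats::runif(1, policy$radius_range[1], policy$radius_range[2]),
                delta_R1 = stats::runif(1, policy$delta_range[1], policy$delta_range[2]))
  })
}

#' Generate a synthetic, pre-aligned cohort
#'
#' Produces `n_controls` control and `n_welders` welder R1 maps on one grid,
#' per-subject WM probability maps, and a metadata table with ages (whole
#' years, uniform over `age_range`) and exposure indices (welders drawn from
#' occupationally plausible ranges, controls near zero). Welders receive
#' focal lesions per `lesion_policy`. Fully deterministic given `spec$seed`.
#'
#' @param spec A [phantom_spec()].
#' @param n_controls Number of controls (>= 4; the atlas fit needs residual
#'   degrees of freedom).
#' @param n_welders Number of welders (>= 0).
#' @param age_range Whole-year age range, default c(20, 61).
#' @param lesion_policy See [default_lesion_policy()]; `NULL` for no lesions.
#' @return An object of class `synthetic_cohort`: list with `volumes`,
#'   `tissue_probability_maps`, `records`, `truth` (spec, labels and the
#'   per-subject lesion lists actually used).
#' @export
generate_cohort <- function(spec, n_controls, n_welders = 0L,
                            age_range = c(20, 61),
                            lesion_policy = default_lesion_policy()) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (n_controls < 4L)
    stop("generate_cohort: need at least 4 controls (atlas fit needs df)",
         call. = FALSE)
  if (n_welders < 0L) stop("generate_cohort: n_welders must be >= 0", call. = FALSE)
  labels <- generate_tissue_labels(spec)
  n <- n_controls + n_welders
  shape <- spec$grid_shape

  draws <- with_seed(spec$seed, {
    ages <- sample(seq(age_range[1], age_range[2]), n, replace = TRUE)
    subject_seeds <- sample.int(2^30, n)
    candidate <- which(labels$data %in% TISSUE_LEVELS[c("WM", "GP")])
    lesions <- lapply(seq_len(n), function(i) {
      if (i <= n_controls || is.null(lesion_policy)) list()
      else draw_lesions(lesion_policy, candidate, shape)
    })
    expo <- data.frame(
      cei_3m = c(stats::runif(n_controls, 0, 0.006),
                 stats::runif(n_welders, 0.006, 0.18)),
      cei_life = c(stats::runif(n_controls, 0.003, 0.4),
                   stats::runif(n_welders, 0.03, 4.8)),
      air_mn = c(stats::runif(n_controls, 0, 0.027),
                 stats::runif(n_welders, 0.05, 0.48)))
    list(ages = ages, subject_seeds = subject_seeds, lesions = lesions,
         expo = expo)
  })

  ids <- c(sprintf("C%02d", seq_len(n_controls)),
           if (n_welders > 0L) sprintf("W%02d", seq_len(n_welders)))
  records <- data.frame(
    subject_id = ids,
    age = as.integer(draws$ages),
    group = rep(c("control", "welder"), c(n_controls, n_welders)),
    cei_3m = round(draws$expo$cei_3m, 4),
    cei_life = round(draws$expo$cei_life, 4),
    air_mn = round(draws$expo$air_mn, 4),
    stringsAsFactors = FALSE)

  volumes <- vector("list", n)
  probs <- vector("list", n)
  for (i in seq_len(n)) {
    volumes[[i]] <- generate_subject(spec, labels, draws$ages[i],
                                     lesions = draws$lesions[[i]],
                                     subject_seed = draws$subject_seeds[i])
    probs[[i]] <- wm_probability_map(spec, labels, draws$subject_seeds[i])
  }
  structure(list(volumes = volumes,
                 tissue_probability_maps = probs,
                 records = records,
                 truth = list(spec = spec, labels = labels,
                              lesions = draws$lesions,
                              subject_seeds = draws$subject_seeds)),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d subjects (%d controls, %d welders), grid %s\n",
              nrow(x$records), sum(x$records$group == "control"),
              sum(x$records$group == "welder"),
              paste(dim(x$volumes[[1]]), collapse = "x")))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Writes one R1 and one WM-probability NIfTI per subject, the metadata CSV,
#' and a JSON sidecar with the generative ground truth (spec parameters and
#' per-subject lesions).
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- cohort$records$subject_id
  for (i in seq_along(ids)) {
    write_volume(cohort$volumes[[i]], file.path(dir, paste0("r1_", ids[i], ".nii.gz")))
    write_volume(cohort$tissue_probability_maps[[i]],
                 file.path(dir, paste0("wmprob_", ids[i], ".nii.gz")))
  }
  write_cohort_table(cohort$records, file.path(dir, "cohort.csv"))
  truth <- cohort$truth
  sidecar <- list(
    spec = unclass(truth$spec),
    lesions = lapply(truth$lesions, function(ll) lapply(ll, unclass)),
    subject_seeds = truth$subject_seeds)
  jsonlite::write_json(sidecar, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
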