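# Voxel-wise normative modeling of R1 over a healthy control cohort:
# the analysis mask from averaged WM probability maps, and per voxel an
# ordinary-least-squares fit of R1 on age centered at the cohort mean,
#   E{R1}(r) = beta0(r) + beta_age(r) a + beta_age2(r) a^2,  a = age - ref_age,
# with the residual SD (RMSE map) that later standardizes individual
# deviations. The quadratic term captures the inverted-U trajectory of R1
# over adult age.

#' Build the white-matter analysis mask
#'
#' Averages the subjects' normalized WM probability maps and keeps voxels
#' whose mean probability *strictly exceeds* `threshold`. At the default 50%
#' threshold this retains deep structures of high WM probability (in the
#' source methodology including the globus pallidus) while excluding
#' cortical voxels whose blended WM/GM content makes single-subject
#' standardization unreliable.
#'
#' @param wm_probability_maps List of [volume_grid()] with values in [0, 1],
#'   all on one grid.
#' @param threshold Probability threshold in (0, 1); inclusion is strict
#'   (mean > threshold). Default 0.5.
#' @return An object of class `analysis_mask`: list with `mask` (binary
#'   [volume_grid()]), `threshold`, `n_subjects_averaged`.
#' @export
build_wm_mask <- function(wm_probability_maps, threshold = 0.5) {
  if (length(wm_probability_maps) == 0L)
    stop("build_wm_mask: empty list of probability maps", call. = FALSE)
  if (threshold <= 0 || threshold >= 1)
    stop("build_wm_mask: threshold must be in (0, 1)", call. = FALSE)
  assert_shared_grid(wm_probability_maps)
  for (i in seq_along(wm_probability_maps)) {
    rng <- range(wm_probability_maps[[i]]$data, na.rm = TRUE)
    if (rng[1] < 0 || rng[2] > 1)
      stop("build_wm_mask: map ", i, " has values outside [0, 1]", call. = FALSE)
  }
  mean_map <- Reduce(`+`, lapply(wm_probability_maps, function(v) v$data)) /
    length(wm_probability_maps)
  m <- mean_map > threshold
  if (!any(m))
    stop("build_wm_mask: resulting mask is empty (degenerate)", call. = FALSE)
  structure(list(mask = same_grid(wm_probability_maps[[1]], m + 0),
                 threshold = threshold,
                 n_subjects_averaged = length(wm_probability_maps)),
            class = "analysis_mask")
}

#' Wrap an existing binary volume as an analysis mask
#' @param mask_volume Binary [volume_grid()].
#' @param threshold Threshold recorded as provenance (default 0.5).
#' @return An `analysis_mask`.
#' @export
as_analysis_mask <- function(mask_volume, threshold = 0.5) {
  stopifnot(inherits(mask_volume, "volume_grid"))
  if (!any(mask_volume$data > 0))
    stop("as_analysis_mask: mask is empty", call. = FALSE)
  structure(list(mask = same_grid(mask_volume, (mask_volume$data > 0) + 0),
                 threshold = threshold, n_subjects_averaged = NA_integer_),
            class = "analysis_mask")
}

# n x 3 (+ extras) design matrix for centered age.
age_design_matrix <- function(ages, ref_age, extra_covariates = NULL) {
  a <- ages - ref_age
  X <- cbind(intercept = 1, age = a, age2 = a^2)
  if (!is.null(extra_covariates)) X <- cbind(X, as.matrix(extra_covariates))
  X
}

#' Fit the voxel-wise normative age model
#'
#' Per voxel inside the mask, ordinary least squares of R1 on
#' \eqn{[1, a, a^2]} with \eqn{a = \mathrm{age} - \mathrm{ref\_age}} and
#' ref_age the (unrounded) mean cohort age. The RMSE map is
#' \eqn{\sqrt{SSR/(n - p)}} by default (residual degrees of freedom,
#' p = number of coefficients); `rmse_denominator = "n"` gives the strict
#' root-mean-square convention. Voxels with a (numerically) zero residual or
#' otherwise degenerate fit cannot support a z-score (the score divides by
#' RMSE) and are excluded from the atlas mask, but their coefficients are
#' still reported.
#'
#' @param cohort_volumes List of R1 [volume_grid()] (one per subject, one grid).
#' @param ages Whole-year ages, same length and order as `cohort_volumes`.
#' @param mask An `analysis_mask` (see [build_wm_mask()]).
#' @param rmse_denominator `"df"` (default, n - p) or `"n"`.
#' @param extra_covariates Optional numeric matrix (n x q) of additional
#'   columns for the design matrix (e.g. sex in a mixed cohort); coefficients
#'   beyond the age terms are fitted but not stored as maps.
#' @param degenerate_tol RMSE below this (s^-1) flags a voxel degenerate.
#' @return An object of class `normative_atlas`: coefficient maps `beta0`,
#'   `beta_age`, `beta_age2`, the `rmse` map, `ref_age`, the pruned `mask`,
#'   `degenerate` (binary map of excluded voxels), `n_subjects`,
#'   `rmse_denominator`.
#' @export
fit_atlas <- function(cohort_volumes, ages, mask,
                      rmse_denominator = c("df", "n"),
                      extra_covariates = NULL,
                      degenerate_tol = 1e-10) {
  rmse_denominator <- match.arg(rmse_denominator)
  stopifnot(inherits(mask, "analysis_mask"))
  n <- length(cohort_volumes)
  if (n != length(ages))
    stop("fit_atlas: ", n, " volumes but ", length(ages), " ages", call. = FALSE)
  if (n < 4L)
    stop("fit_atlas: need at least 4 subjects", call. = FALSE)
  if (length(unique(ages)) < 3L)
    stop("fit_atlas: need at least 3 distinct ages (quadratic design is ",
         "rank-deficient otherwise)", call. = FALSE)
  assert_shared_grid(c(cohort_volumes, list(mask$mask)))

  ref_age <- mean(ages)
  X <- age_design_matrix(ages, ref_age, extra_covariates)
  p <- ncol(X)
  if (n <= p)
    stop("fit_atlas: need more subjects than coefficients (n > ", p, ")",
         call. = FALSE)
  in_mask <- which(mask$mask$data > 0)
  Y <- vapply(cohort_volumes, function(v) v$data[in_mask],
              numeric(length(in_mask)))      # nvox x n
  Y <- t(Y)                                  # n x nvox
  # Invalid voxels (e.g. failed relaxometry fits) in any subject cannot be
  # modeled; drop them from the mask.
  ok <- colSums(!is.finite(Y)) == 0L
  qrX <- qr(X)
  if (qrX$rank < p)
    stop("fit_atlas: rank-deficient design matrix", call. = FALSE)
  coef <- matrix(NA_real_, p, length(in_mask))
  coef[, ok] <- qr.coef(qrX, Y[, ok, drop = FALSE])
  res <- Y - X %*% ifelse(is.na(coef), 0, coef)
  denom <- if (rmse_denominator == "df") n - p else n
  rmse_v <- sqrt(colSums(res^2) / denom)
  rmse_v[!ok] <- NA_real_

  shape <- dim(mask$mask$data)
  to_map <- function(values) {
    m <- array(NA_real_, dim = shape)
    m[in_mask] <- values
    same_grid(mask$mask, m)
  }
  degenerate_v <- !ok | !is.finite(rmse_v) | rmse_v < degenerate_tol
  pruned <- array(0, dim = shape)
  pruned[in_mask[!degenerate_v]] <- 1
  degen_map <- array(0, dim = shape)
  degen_map[in_mask[degenerate_v]] <- 1

  pruned_mask <- mask
  pruned_mask$mask <- same_grid(mask$mask, pruned)

  structure(list(beta0 = to_map(coef[1, ]),
                 beta_age = to_map(coef[2, ]),
                 beta_age2 = to_map(coef[3, ]),
                 rmse = to_map(rmse_v),
                 ref_age = ref_age,
                 mask = pruned_mask,
                 degenerate = same_grid(mask$mask, degen_map),
                 n_subjects = n,
                 rmse_denominator = rmse_denominator),
            class = "normative_atlas")
}

#' @export
print.normative_atlas <- function(x, ...) {
  cat(sprintf(paste0("<normative_atlas> n = %d subjects, ref age %.2f y, ",
                     "%d mask voxels (%d degenerate excluded)\n"),
              x$n_subjects, x$ref_age, sum(x$mask$mask$data > 0),
              sum(x$degenerate$data > 0)))
  invisible(x)
}

#' Predict the expected R1 map at a given age
#'
#' \eqn{E\{R_1\}(r) = \beta_0(r) + \beta_{age}(r) a + \beta_{age^2}(r) a^2}
#' with \eqn{a = \mathrm{age} - \mathrm{ref\_age}}, defined inside the atlas
#' mask (NA outside). At `age = ref_age` this is the `beta0` map exactly.
#' Ages more than 60 years from the reference trigger an extrapolation
#' warning (not an error).
#'
#' @param object A `normative_atlas`.
#' @param age Query age in whole years.
#' @param ... Unused.
#' @return Expected-R1 [volume_grid()] in s^-1.
#' @export
predict.normative_atlas <- function(object, age, ...) {
  a <- age - object$ref_age
  if (abs(a) > 60)
    warning("predict.normative_atlas: age ", age,
            " is far outside the reference cohort (extrapolation)",
            call. = FALSE)
  if (a == 0) return(object$beta0)
  e <- object$beta0$data + object$beta_age$data * a + object$beta_age2$data * a^2
  same_grid(object$beta0, e)
}

#' Persist a normative atlas
#'
#' Writes the four coefficient/RMSE maps and the mask as NIfTI plus a JSON
#' metadata file (ref_age, n_subjects, mask threshold, RMSE convention).
#'
#' @param atlas A `normative_atlas`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_atlas <- function(atlas, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_volume(atlas$beta0, file.path(dir, "beta0.nii.gz"))
  write_volume(atlas$beta_age, file.path(dir, "beta_age.nii.gz"))
  write_volume(atlas$beta_age2, file.path(dir, "beta_age2.nii.gz"))
  write_volume(atlas$rmse, file.path(dir, "rmse.nii.gz"))
  write_volume(atlas$mask$mask, file.path(dir, "mask.nii.gz"))
  write_volume(atlas$degenerate, file.path(dir, "degenerate.nii.gz"))
  meta <- list(ref_age = atlas$ref_age, n_subjects = atlas$n_subjects,
               mask_threshold = atlas$mask$threshold,
               rmse_denominator = atlas$rmse_denominator)
  jsonlite::write_json(meta, file.path(dir, "atlas.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Load a persisted normative atlas
#' @param dir Directory written by [write_atlas()].
#' @return A `normative_atlas`.
#' @export
read_atlas <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "atlas.json"), simplifyVector = TRUE)
  mask_vol <- read_volume(file.path(dir, "mask.nii.gz"))
  mask <- as_analysis_mask(mask_vol, threshold = meta$mask_threshold)
  structure(list(beta0 = read_volume(file.path(dir, "beta0.nii.gz")),
                 beta_age = read_volume(file.path(dir, "beta_age.nii.gz")),
                 beta_age2 = read_volume(file.path(dir, "beta_age2.nii.gz")),
                 rmse = read_volume(file.path(dir, "rmse.nii.gz")),
                 ref_age = meta$ref_age,
                 mask = mask,
                 degenerate = read_volume(file.path(dir, "degenerate.nii.gz")),
                 n_subjects = meta$n_subjects,
                 rmse_denominator = meta$rmse_denominator),
            class = "normative_atlas")
}
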