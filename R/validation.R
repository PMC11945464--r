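# False-positive behavior of the deviation mapping on non-exposed subjects:
# k-fold cross-validation over the control cohort. Each fold's subjects are
# held out, the atlas is refitted on the remainder, and the held-out
# controls' z-maps are scored — any flagged voxel is by construction a false
# positive. FPR is the voxel-level fraction of in-mask voxels flagged per
# held-out subject (optionally after cluster-extent filtering), averaged
# over subjects.

#' Deterministic k-fold partition
#'
#' Subjects are shuffled once (seeded) and dealt into k near-equal folds:
#' the first `n %% k` folds get `ceiling(n/k)` subjects, the rest
#' `floor(n/k)`. Folds are disjoint and cover all subjects.
#'
#' @param n Number of subjects.
#' @param k Number of folds (2 <= k <= n).
#' @param seed Integer seed.
#' @return List of k integer index vectors.
#' @export
make_folds <- function(n, k, seed = 1L) {
  if (k < 2L || k > n)
    stop("make_folds: need 2 <= k <= n", call. = FALSE)
  perm <- with_seed(seed, sample.int(n))
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  split(perm, rep(seq_len(k), times = sizes))
}

#' k-fold cross-validated false-positive rate
#'
#' @param control_volumes List of control R1 [volume_grid()].
#' @param ages Whole-year ages, index-aligned with `control_volumes`.
#' @param mask An `analysis_mask`.
#' @param k Fold count (default 10).
#' @param threshold z threshold used for flagging (default 2; the detection
#'   threshold of the mapping itself is a separate, higher setting).
#' @param min_extent Minimum cluster extent applied before counting when
#'   `cluster_corrected = TRUE`.
#' @param cluster_corrected If TRUE, a voxel counts as flagged only when it
#'   belongs to a retained cluster (z > threshold and component size >=
#'   min_extent); if FALSE, plain voxel-level flagging z > threshold.
#' @param connectivity Cluster connectivity when filtering (default 26).
#' @param seed Seed for the fold partition.
#' @param rmse_denominator Passed to [fit_atlas()].
#' @return An object of class `fpr_report`: `k`, `per_subject_fpr` (named by
#'   subject index), `mean_fpr`, `threshold`, `min_extent`,
#'   `cluster_corrected`, `folds`.
#' @export
kfold_fpr <- function(control_volumes, ages, mask, k = 10,
                      threshold = 2, min_extent = 100,
                      cluster_corrected = FALSE, connectivity = 26,
                      seed = 1L, rmse_denominator = "df") {
  n <- length(control_volumes)
  if (n != length(ages))
    stop("kfold_fpr: volumes/ages length mismatch", call. = FALSE)
  if (k < 2L || k > n)
    stop("kfold_fpr: need 2 <= k <= n (got k = ", k, ", n = ", n, ")",
         call. = FALSE)
  if (n - max(lengths(make_folds(n, k, seed))) < 4L)
    stop("kfold_fpr: some fold leaves fewer than 4 training subjects",
         call. = FALSE)
  folds <- make_folds(n, k, seed)
  per_subject <- rep(NA_real_, n)
  for (f in folds) {
    train <- setdiff(seq_len(n), f)
    atlas <- fit_atlas(control_volumes[train], ages[train], mask,
                       rmse_denominator = rmse_denominator)
    m <- atlas$mask$mask$data > 0
    n_mask <- sum(m)
    for (i in f) {
      zm <- compute_zmap(control_volumes[[i]], ages[i], atlas,
                         subject_id = paste0("cv", i))
      if (cluster_corrected) {
        cs <- cluster_correct(zm, threshold = threshold,
                              min_extent = min_extent,
                              connectivity = connectivity)
        flagged <- sum(cs$labels$data > 0L)
      } else {
        flagged <- sum(zm$z$data[m] > threshold, na.rm = TRUE)
      }
      # an all-degenerate (empty) pruned mask flags nothing: FPR 0
      per_subject[i] <- if (n_mask == 0L) 0 else flagged / n_mask
    }
  }
  structure(list(k = k,
                 per_subject_fpr = per_subject,
                 mean_fpr = mean(per_subject),
                 threshold = threshold,
                 min_extent = min_extent,
                 cluster_corrected = cluster_corrected,
                 folds = folds),
            class = "fpr_report")
}

#' @export
print.fpr_report <- function(x, ...) {
  cat(sprintf("<fpr_report> k = %d, z > %g%s: mean FPR = %.4g%% over %d subjects\n",
              x$k, x$threshold,
              if (x$cluster_corrected) sprintf(" & >= %d voxels", x$min_extent) else "",
              100 * x$mean_fpr, length(x$per_subject_fpr)))
  invisible(x)
}

#' Write an FPR report as JSON (plus a per-subject CSV)
#' @param report An `fpr_report`.
#' @param path Output JSON path; a sibling `.csv` holds per-subject rates.
#' @return `path`, invisibly.
#' @export
write_fpr_report <- function(report, path) {
  jsonlite::write_json(
    list(k = report$k, mean_fpr = report$mean_fpr,
         threshold = report$threshold, min_extent = report$min_extent,
         cluster_corrected = report$cluster_corrected,
         per_subject_fpr = report$per_subject_fpr),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(data.frame(subject = seq_along(report$per_subject_fpr),
                              fpr = report$per_subject_fpr),
                   sub("\\.json$", ".csv", path), row.names = FALSE)
  invisible(path)
}
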