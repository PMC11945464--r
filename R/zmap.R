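# Single-subject deviation mapping: per-voxel z-scores against the
# normative atlas,
#   z(r) = (R1(r) - E{R1}(r; age)) / RMSE(r),
# followed by cluster-extent correction — strict one-sided thresholding
# (Mn deposition only raises R1), connected-component labeling, and removal
# of components smaller than a minimum voxel extent to suppress isolated
# false positives.

#' Compute a subject's z-score deviation map
#'
#' @param subject_r1 R1 [volume_grid()] on the atlas grid.
#' @param age Subject age in whole years.
#' @param atlas A `normative_atlas` from [fit_atlas()].
#' @param subject_id Optional subject identifier carried into reports.
#' @return An object of class `zmap`: list with `z` ([volume_grid()], NA
#'   outside the atlas mask), `subject_id`, `age_used`.
#' @export
compute_zmap <- function(subject_r1, age, atlas, subject_id = "subject") {
  stopifnot(inherits(atlas, "normative_atlas"))
  assert_shared_grid(list(subject_r1, atlas$beta0))
  expected <- predict(atlas, age)
  in_mask <- atlas$mask$mask$data > 0
  rmse <- atlas$rmse$data
  if (any(in_mask & (!is.finite(rmse) | rmse <= 0)))
    stop("compute_zmap: internal invariant violation: non-positive RMSE ",
         "inside the atlas mask", call. = FALSE)
  z <- array(NA_real_, dim = dim(subject_r1$data))
  z[in_mask] <- (subject_r1$data[in_mask] - expected$data[in_mask]) / rmse[in_mask]
  structure(list(z = same_grid(subject_r1, z),
                 subject_id = subject_id,
                 age_used = age),
            class = "zmap")
}

#' @export
print.zmap <- function(x, ...) {
  zz <- x$z$data[is.finite(x$z$data)]
  cat(sprintf("<zmap> subject %s (age %s): %d in-mask voxels, z in [%.2f, %.2f]\n",
              x$subject_id, format(x$age_used), length(zz),
              min(zz), max(zz)))
  invisible(x)
}

# Neighbor offsets for 6/18/26-connectivity in 3D.
connectivity_offsets <- function(connectivity) {
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be 6, 18 or 26", call. = FALSE)
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  dist <- rowSums(abs(g))
  keep <- switch(as.character(connectivity),
                 "6" = dist == 1,
                 "18" = dist >= 1 & dist <= 2,
                 "26" = dist >= 1)
  g[keep, , drop = FALSE]
}

#' Label connected components of a binary 3D field
#'
#' Iterative minimum-label propagation: each foreground voxel starts with
#' its own linear index as label and repeatedly adopts the smallest label
#' among its foreground neighbors until a fixed point. Components touching
#' the volume border are ordinary components (no special treatment, no
#' periodic wrap). Final labels are renumbered 1..K by decreasing size, ties
#' broken by the smallest linear voxel index in the component.
#'
#' @param mask Logical or 0/1 3D array.
#' @param connectivity 6, 18 or 26 (default 26).
#' @return List with `labels` (integer 3D array, 0 = background) and `sizes`
#'   (integer vector, voxel count per component, decreasing).
#' @export
label_components <- function(mask, connectivity = 26) {
  mask <- mask > 0
  d <- dim(mask)
  if (length(d) != 3L)
    stop("label_components: mask must be a 3D array", call. = FALSE)
  offs <- connectivity_offsets(connectivity)
  lab <- array(0, dim = d)
  lab[mask] <- which(mask)
  # Precompute index slices once per offset axis shift.
  shift_min <- function(cur) {
    new <- cur
    for (k in seq_len(nrow(offs))) {
      o <- offs[k, ]
      sx <- seq_len(d[1]); sy <- seq_len(d[2]); sz <- seq_len(d[3])
      dst_x <- sx[sx + o[1] >= 1 & sx + o[1] <= d[1]]
      dst_y <- sy[sy + o[2] >= 1 & sy + o[2] <= d[2]]
      dst_z <- sz[sz + o[3] >= 1 & sz + o[3] <= d[3]]
      src <- cur[dst_x + o[1], dst_y + o[2], dst_z + o[3], drop = FALSE]
      sub <- new[dst_x, dst_y, dst_z, drop = FALSE]
      take <- src > 0 & sub > 0 & src < sub
      if (any(take)) {
        sub[take] <- src[take]
        new[dst_x, dst_y, dst_z] <- sub
      }
    }
    new
  }
  repeat {
    nxt <- shift_min(lab)
    if (identical(nxt, lab)) break
    lab <- nxt
  }
  roots <- sort(unique(lab[lab > 0]))
  if (length(roots) == 0L)
    return(list(labels = array(0L, dim = d), sizes = integer(0)))
  comp <- match(lab, roots)           # provisional 1..K by root index
  comp[is.na(comp)] <- 0L
  sizes <- tabulate(comp, nbins = length(roots))
  # reorder: decreasing size, tie -> smallest linear index (roots are the
  # minimal linear index of each component, and sort(roots) is increasing)
  ord <- order(-sizes, seq_along(roots))
  relabel <- integer(length(roots)); relabel[ord] <- seq_along(roots)
  out <- array(0L, dim = d)
  out[comp > 0L] <- relabel[comp[comp > 0L]]
  list(labels = out, sizes = sizes[ord])
}

#' Cluster-extent correction of a z-map
#'
#' Thresholds the z field (strict, one-sided positive by default: only
#' elevations survive, since Mn deposition raises R1), labels connected
#' components, and discards components smaller than `min_extent` voxels
#' (retain iff size >= min_extent). The defaults z > 6 with >= 100 voxels
#' reproduce the correction used in the source methodology.
#'
#' @param zmap A `zmap` (or a [volume_grid()] of z values).
#' @param threshold z threshold (strict). Default 6.
#' @param min_extent Minimum cluster size in voxels (>= 1). Default 100.
#' @param connectivity 6, 18 or 26 (default 26).
#' @param two_sided If TRUE, threshold on |z| instead of z.
#' @return An object of class `cluster_set`: `labels` ([volume_grid()],
#'   integer labels, 1..K by decreasing size), `sizes`, `threshold`,
#'   `min_extent`, `connectivity`, `two_sided`.
#' @export
cluster_correct <- function(zmap, threshold = 6, min_extent = 100,
                            connectivity = 26, two_sided = FALSE) {
  z <- if (inherits(zmap, "zmap")) zmap$z else zmap
  stopifnot(inherits(z, "volume_grid"))
  if (!is.finite(threshold)) stop("cluster_correct: threshold must be finite",
                                  call. = FALSE)
  if (min_extent < 1) stop("cluster_correct: min_extent must be >= 1",
                           call. = FALSE)
  zz <- z$data
  supra <- if (two_sided) abs(zz) > threshold else zz > threshold
  supra[!is.finite(zz)] <- FALSE
  cc <- label_components(supra, connectivity)
  keep <- which(cc$sizes >= min_extent)
  labels <- array(0L, dim = dim(zz))
  sizes <- integer(0)
  if (length(keep)) {
    # components are already ordered by decreasing size; retained ones keep
    # their relative order and are renumbered 1..K
    relabel <- integer(length(cc$sizes))
    relabel[keep] <- seq_along(keep)
    pos <- cc$labels > 0L
    mapped <- relabel[cc$labels[pos]]
    labels[pos] <- mapped
    sizes <- cc$sizes[keep]
  }
  structure(list(labels = same_grid(z, labels),
                 sizes = sizes,
                 threshold = threshold,
                 min_extent = min_extent,
                 connectivity = as.integer(connectivity),
                 two_sided = two_sided),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("<cluster_set> %d cluster(s) (z > %g, >= %d voxels, %d-connectivity)\n",
              length(x$sizes), x$threshold, x$min_extent, x$connectivity))
  if (length(x$sizes)) cat("  sizes:", paste(x$sizes, collapse = ", "), "\n")
  invisible(x)
}

#' Tabulate retained clusters
#'
#' One row per retained cluster: size, peak z, peak voxel coordinate and
#' center of mass. Voxel coordinates are 0-based (NIfTI convention).
#'
#' @param clusters A `cluster_set` from [cluster_correct()].
#' @param zmap The `zmap` the clusters came from.
#' @return Data.frame with columns `cluster`, `size_vox`, `peak_z`,
#'   `peak_x`, `peak_y`, `peak_z_coord`, `centroid_x`, `centroid_y`,
#'   `centroid_z` (empty for an empty cluster set).
#' @export
summarize_clusters <- function(clusters, zmap) {
  stopifnot(inherits(clusters, "cluster_set"))
  z <- if (inherits(zmap, "zmap")) zmap$z$data else zmap$data
  lab <- clusters$labels$data
  k <- length(clusters$sizes)
  out <- data.frame(cluster = integer(0), size_vox = integer(0),
                    peak_z = numeric(0), peak_x = integer(0),
                    peak_y = integer(0), peak_z_coord = integer(0),
                    centroid_x = numeric(0), centroid_y = numeric(0),
                    centroid_z = numeric(0))
  if (k == 0L) return(out)
  shape <- dim(lab)
  for (i in seq_len(k)) {
    idx <- which(lab == i)
    coords <- arrayInd(idx, shape)
    zi <- z[idx]
    peak <- which.max(zi)
    out <- rbind(out, data.frame(
      cluster = i, size_vox = length(idx), peak_z = zi[peak],
      peak_x = coords[peak, 1] - 1L, peak_y = coords[peak, 2] - 1L,
      peak_z_coord = coords[peak, 3] - 1L,
      centroid_x = mean(coords[, 1]) - 1, centroid_y = mean(coords[, 2]) - 1,
      centroid_z = mean(coords[, 3]) - 1))
  }
  out
}
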