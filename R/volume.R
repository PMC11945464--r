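#' A 3D scalar volume on a regular grid
#'
#' `volume_grid` is the container every stage of the pipeline operates on: a
#' 3D array of voxel values together with the voxel size (mm) and the
#' voxel-to-world affine of the grid it lives on. All volumes entering one
#' analysis must share a grid; see [assert_shared_grid()].
#'
#' Data are held as 64-bit doubles regardless of on-disk type, for regression
#' stability. Voxel indices are 1-based inside R; user-facing reports
#' (cluster tables) use 0-based indices following the NIfTI convention.
#'
#' @param data 3D numeric array of voxel values.
#' @param voxel_size Numeric length-3, voxel edge lengths in mm (all > 0).
#' @param affine 4x4 voxel-to-world transform. Default: diagonal scaling by
#'   `voxel_size` with the origin at voxel (0,0,0).
#'
#' @return An object of class `volume_grid` with elements `data`,
#'   `voxel_size` and `affine`.
#' @export
#' @examples
#' v <- volume_grid(array(0, dim = c(16, 16, 16)), voxel_size = c(1, 1, 2))
#' dim(v)
volume_grid <- function(data, voxel_size = c(1, 1, 1), affine = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("volume_grid: `data` must be a 3D array", call. = FALSE)
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) || any(voxel_size <= 0))
    stop("volume_grid: `voxel_size` must be 3 strictly positive numbers", call. = FALSE)
  if (is.null(affine)) {
    affine <- diag(c(voxel_size, 1))
  }
  affine <- as.matrix(affine)
  if (!identical(dim(affine), c(4L, 4L)))
    stop("volume_grid: `affine` must be a 4x4 matrix", call. = FALSE)
  d <- dim(data)
  data <- array(as.double(data), dim = d)  # strip foreign attributes
  structure(list(data = data, voxel_size = voxel_size,
                 affine = unname(affine)),
            class = "volume_grid")
}

#' @export
dim.volume_grid <- function(x) dim(x$data)

#' @export
as.array.volume_grid <- function(x, ...) x$data

#' @export
print.volume_grid <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume_grid> %d x %d x %d voxels, %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  rng <- range(x$data, na.rm = TRUE)
  cat(sprintf("  values in [%.4g, %.4g], %d NA\n", rng[1], rng[2],
              sum(is.na(x$data))))
  invisible(x)
}

# Construct a volume on the same grid as `template` with new data.
same_grid <- function(template, data) {
  volume_grid(data, voxel_size = template$voxel_size, affine = template$affine)
}

#' Read a NIfTI volume
#'
#' Reads a NIfTI-1/NIfTI-2 file (`.nii` or `.nii.gz`) into a [volume_grid()].
#' A 4D file whose last axis has length 1 is squeezed to 3D; any other
#' non-3D payload is an error.
#'
#' @param path Path to a NIfTI file.
#' @return A [volume_grid()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path))
    stop("read_volume: file does not exist: ", path, call. = FALSE)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("read_volume: unreadable NIfTI file '",
                                           path, "': ", conditionMessage(e),
                                           call. = FALSE))
  d <- dim(img)
  a <- as.array(img)
  if (length(d) == 4L && d[4] == 1L) {
    a <- array(a, dim = d[1:3])
    d <- d[1:3]
  }
  if (length(d) != 3L)
    stop("read_volume: expected a 3D volume, got payload with dims [",
         paste(dim(img), collapse = ", "), "] in ", path, call. = FALSE)
  pd <- RNifti::pixdim(img)[1:3]
  aff <- unclass(RNifti::xform(img))[1:4, 1:4]
  volume_grid(a, voxel_size = pd, affine = aff)
}

#' Write a volume as NIfTI-1
#'
#' @param volume A [volume_grid()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param datatype On-disk datatype, default single-precision float.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, datatype = "float") {
  stopifnot(inherits(volume, "volume_grid"))
  img <- RNifti::asNifti(volume$data)
  RNifti::pixdim(img) <- volume$voxel_size
  RNifti::sform(img) <- structure(volume$affine, code = 2L)
  RNifti::qform(img) <- structure(volume$affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Check that volumes share one grid
#'
#' Downstream voxel-wise math assumes all volumes are already aligned on a
#' single grid (spatial normalization is upstream of this package). This
#' check passes iff every volume has the same shape and an affine equal to
#' the first volume's within relative tolerance `tol`.
#'
#' @param volumes List of [volume_grid()] objects (length >= 1).
#' @param tol Relative tolerance on affine entries (default 1e-6).
#' @return `TRUE` invisibly; otherwise an error naming the offending volume.
#' @export
assert_shared_grid <- function(volumes, tol = 1e-6) {
  if (length(volumes) == 0L)
    stop("assert_shared_grid: empty volume list", call. = FALSE)
  ref <- volumes[[1L]]
  ref_scale <- max(abs(ref$affine), 1)
  for (i in seq_along(volumes)) {
    v <- volumes[[i]]
    if (!identical(dim(v$data), dim(ref$data)))
      stop(sprintf(
        "grid mismatch: volume %d has shape [%s], expected [%s]",
        i, paste(dim(v$data), collapse = ", "),
        paste(dim(ref$data), collapse = ", ")), call. = FALSE)
    if (max(abs(v$affine - ref$affine)) > tol * ref_scale)
      stop(sprintf("grid mismatch: volume %d affine differs beyond tolerance %g",
                   i, tol), call. = FALSE)
  }
  invisible(TRUE)
}

#' Read a cohort metadata table
#'
#' Reads a CSV with one row per subject. Required columns: `subject_id`,
#' `age`, `group` (\code{"control"} or \code{"welder"}). Optional exposure
#' columns: `cei_3m`, `cei_life` (cumulative exposure indices, mg/m3 yr) and
#' `air_mn` (mean airborne Mn, mg/m3); missing exposure cells are allowed
#' (typically for controls). Ages are whole years.
#'
#' @param path Path to a CSV file.
#' @return A data.frame of subject records (possibly 0-row for an empty file).
#' @export
read_cohort_table <- function(path) {
  if (!file.exists(path))
    stop("read_cohort_table: file does not exist: ", path, call. = FALSE)
  if (file.size(path) == 0L || length(readLines(path, n = 1L, warn = FALSE)) == 0L) {
    return(empty_cohort_table())
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_cohort_table(df)
}

empty_cohort_table <- function() {
  data.frame(subject_id = character(), age = integer(), group = character(),
             cei_3m = numeric(), cei_life = numeric(), air_mn = numeric(),
             stringsAsFactors = FALSE)
}

validate_cohort_table <- function(df) {
  need <- c("subject_id", "age", "group")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("cohort table: missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (nrow(df) == 0L) return(empty_cohort_table())
  if (any(is.na(df$subject_id) | !nzchar(as.character(df$subject_id))))
    stop("cohort table: missing subject_id", call. = FALSE)
  age <- suppressWarnings(as.numeric(df$age))
  if (any(is.na(age)))
    stop("cohort table: missing or non-numeric age", call. = FALSE)
  if (any(age < 0))
    stop("cohort table: negative age is invalid", call. = FALSE)
  df$age <- as.integer(round(age))
  df$group <- as.character(df$group)
  bad_grp <- setdiff(unique(df$group), c("control", "welder"))
  if (length(bad_grp))
    stop("cohort table: unknown group label(s): ",
         paste(bad_grp, collapse = ", "), call. = FALSE)
  for (col in c("cei_3m", "cei_life", "air_mn")) {
    if (!col %in% names(df)) df[[col]] <- NA_real_
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
    if (any(df[[col]] < 0, na.rm = TRUE))
      stop("cohort table: negative exposure value in ", col, call. = FALSE)
  }
  df[c("subject_id", "age", "group", "cei_3m", "cei_life", "air_mn")]
}

#' Write a cohort metadata table
#' @param records Data.frame of subject records.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_table <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}
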