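# Two-point variable-flip-angle (VFA) R1 estimation from spoiled
# gradient-echo (SPGR) magnitude signals. The steady-state SPGR signal is
#   S(alpha) = M0 sin(alpha) (1 - E1) / (1 - E1 cos(alpha)),  E1 = exp(-TR R1),
# which linearizes as S/sin(alpha) = E1 * S/tan(alpha) + M0 (1 - E1); with
# two flip angles the slope E1 (hence R1) follows in closed form per voxel.
# Nominal flip angles are trusted (no B1 correction: the phantoms carry no
# transmit-field inhomogeneity and B1 mapping is upstream of this package).

#' A two-flip-angle SPGR acquisition
#'
#' @param signals List of two [volume_grid()] magnitude volumes, one per flip
#'   angle, on one grid.
#' @param flip_angles Two distinct flip angles in degrees, each in (0, 90).
#'   Default 3 and 17 degrees.
#' @param tr Repetition time in ms (> 0). Default 6.36 ms.
#' @return An object of class `vfa_acquisition`.
#' @export
vfa_acquisition <- function(signals, flip_angles = c(3, 17), tr = 6.36) {
  if (length(signals) != 2L)
    stop("vfa_acquisition: exactly two signal volumes required", call. = FALSE)
  assert_shared_grid(signals)
  flip_angles <- as.numeric(flip_angles)
  if (length(flip_angles) != 2L || any(flip_angles <= 0) || any(flip_angles >= 90))
    stop("vfa_acquisition: flip angles must be two values in (0, 90) degrees",
         call. = FALSE)
  if (flip_angles[1] == flip_angles[2])
    stop("vfa_acquisition: flip angles must be distinct", call. = FALSE)
  if (tr <= 0) stop("vfa_acquisition: tr must be > 0 ms", call. = FALSE)
  structure(list(signals = signals, flip_angles = flip_angles, tr = tr),
            class = "vfa_acquisition")
}

#' Forward SPGR steady-state signal
#'
#' @param r1 Longitudinal relaxation rate(s) in s^-1.
#' @param m0 Equilibrium magnetization (arbitrary units).
#' @param flip_deg Flip angle in degrees.
#' @param tr_ms Repetition time in ms.
#' @return Signal magnitude(s), same shape as `r1`.
#' @export
spgr_signal <- function(r1, m0, flip_deg, tr_ms) {
  a <- flip_deg * pi / 180
  e1 <- exp(-tr_ms / 1000 * r1)
  m0 * sin(a) * (1 - e1) / (1 - e1 * cos(a))
}

#' Fit an R1 map from a two-point VFA acquisition
#'
#' Per masked voxel the linearized SPGR model gives
#' \eqn{E_1 = (y_2 - y_1) / (x_2 - x_1)} with \eqn{y_i = S_i/\sin\alpha_i},
#' \eqn{x_i = S_i/\tan\alpha_i}, and \eqn{R_1 = -\ln(E_1)/\mathrm{TR}}.
#' Voxels with a non-physical slope (\eqn{E_1 \notin (0, 1)}) or degenerate
#' signals are set to `NA` (invalid marker); they behave as outside-mask
#' downstream.
#'
#' @param acq A [vfa_acquisition()].
#' @param mask Binary [volume_grid()] on the same grid, or `NULL` to fit
#'   every voxel.
#' @return An R1 [volume_grid()] in s^-1; `NA` outside the mask and at
#'   invalid voxels.
#' @export
fit_vfa_r1 <- function(acq, mask = NULL) {
  stopifnot(inherits(acq, "vfa_acquisition"))
  s1 <- acq$signals[[1]]$data
  s2 <- acq$signals[[2]]$data
  if (!is.null(mask)) {
    assert_shared_grid(list(acq$signals[[1]], mask))
    in_mask <- mask$data > 0
  } else {
    in_mask <- array(TRUE, dim = dim(s1))
  }
  a <- acq$flip_angles * pi / 180
  y1 <- s1 / sin(a[1]); x1 <- s1 / tan(a[1])
  y2 <- s2 / sin(a[2]); x2 <- s2 / tan(a[2])
  dx <- x2 - x1
  e1 <- (y2 - y1) / dx
  valid <- in_mask & is.finite(e1) & e1 > 0 & e1 < 1 & abs(dx) > 0
  r1 <- array(NA_real_, dim = dim(s1))
  r1[valid] <- -log(e1[valid]) / (acq$tr / 1000)
  if (any(in_mask) && !any(valid))
    stop("fit_vfa_r1: no voxel yielded a physical fit (all invalid)",
         call. = FALSE)
  same_grid(acq$signals[[1]], r1)
}
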