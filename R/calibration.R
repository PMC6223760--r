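# Pivot calibration: recover the tip offset of a pointed tool (in its own
# frame) and the fixed pivot point (in the reference frame) from tracked
# poses acquired while pivoting the tool about its tip.

#' Pivot calibration of a tracked pointed tool
#'
#' While the tool pivots about its stationary tip, every pose satisfies
#' \eqn{R_i p_{tip} + t_i = p_{pivot}}. Stacking all poses gives the linear
#' least-squares system \eqn{[R_i \; -I] (p_{tip}, p_{pivot})^T = -t_i}
#' (3n x 6), solved by QR. The formulation is exact in the noiseless case
#' and yields both unknowns directly. Poses must span meaningfully
#' different orientations, otherwise the system is rank-deficient. No
#' sample-validity filtering is applied.
#'
#' @param poses a list of `tool_pose` objects (at least 3, with distinct
#'   rotations).
#' @return An object of class `pivot_solution`: `tip_offset` (mm, tool
#'   frame), `pivot_point` (mm, reference frame), `rms_residual` (mm) and
#'   `n_poses`.
#' @examples
#' tip <- c(0, 0, 150); piv <- c(10, 20, 30)
#' poses <- lapply(seq(0, 1, length.out = 20), function(a) {
#'   R <- rotation_axis_angle(c(1, 1, 0), a)
#'   pose(a, "pointer", rigid_transform(R, piv - drop(R %*% tip)))
#' })
#' pivot_calibrate(poses)
#' @export
pivot_calibrate <- function(poses) {
  if (!is.list(poses) || length(poses) < 3L ||
      !all(vapply(poses, is_pose, logical(1)))) {
    slreg_error("slreg_invalid_input",
                "pivot_calibrate needs a list of at least 3 tool_pose objects")
  }
  n <- length(poses)
  A <- matrix(0, 3L * n, 6L)
  b <- numeric(3L * n)
  for (i in seq_len(n)) {
    rows <- (3L * i - 2L):(3L * i)
    A[rows, 1:3] <- poses[[i]]$transform$rotation
    A[rows, 4:6] <- -diag(3)
    b[rows] <- -poses[[i]]$transform$translation
  }
  sv <- svd(A, nu = 0, nv = 0)$d
  if (sv[6L] <= 1e-8) {
    slreg_error("slreg_insufficient_motion",
                "poses share (nearly) one orientation; pivot system is rank-deficient")
  }
  x <- qr.solve(A, b)
  tip <- x[1:3]
  pivot <- x[4:6]
  res <- vapply(poses, function(p) {
    sqrt(sum((drop(p$transform$rotation %*% tip) +
                p$transform$translation - pivot)^2))
  }, numeric(1))
  structure(list(tip_offset = tip, pivot_point = pivot,
                 rms_residual = sqrt(mean(res^2)), n_poses = n),
            class = "pivot_solution")
}

#' @export
print.pivot_solution <- function(x, ...) {
  cat(sprintf("Pivot calibration from %d poses\n", x$n_poses))
  cat(sprintf("  tip offset (tool frame):  %8.3f %8.3f %8.3f mm\n",
              x$tip_offset[1], x$tip_offset[2], x$tip_offset[3]))
  cat(sprintf("  pivot point (reference):  %8.3f %8.3f %8.3f mm\n",
              x$pivot_point[1], x$pivot_point[2], x$pivot_point[3]))
  cat(sprintf("  RMS residual: %.4f mm\n", x$rms_residual))
  invisible(x)
}
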