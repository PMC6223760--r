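# Rigid-body mathematics shared by all modules: proper rigid transforms
# (3x3 rotation + translation, mm), unit quaternions at the I/O boundary,
# frame construction from measured axes, and rotation averaging.

# Orthonormality drift above this triggers SVD re-orthonormalization;
# above .ROT_REJECT_TOL the matrix is rejected as not a rotation.
.ROT_DRIFT_TOL <- 1e-12
.ROT_REJECT_TOL <- 1e-6

#' Construct a rigid transform
#'
#' A rigid transform maps points of one frame into another as
#' \eqn{p' = R p + t}, with \eqn{R} a proper rotation (orthonormal,
#' determinant +1) and \eqn{t} a translation in millimetres. Small
#' orthonormality drift (common after long compositions) is silently
#' repaired by SVD projection onto the nearest rotation; matrices that are
#' far from orthonormal, or improper (reflections), are rejected.
#'
#' @param rotation 3x3 numeric matrix, orthonormal with determinant +1.
#' @param translation numeric length-3 vector (mm).
#' @return An object of class `rigid_transform` with elements `rotation`
#'   and `translation`.
#' @examples
#' T1 <- rigid_transform(diag(3), c(5, 0, 0))
#' apply_transform(T1, c(1, 2, 3))
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  if (!all(dim(rotation) == c(3L, 3L))) {
    slreg_error("slreg_invalid_input", "rotation must be a 3x3 matrix")
  }
  if (length(translation) != 3L) {
    slreg_error("slreg_invalid_input", "translation must have length 3")
  }
  stopifnot_finite(rotation, "rotation")
  stopifnot_finite(translation, "translation")
  drift <- max(abs(crossprod(rotation) - diag(3)))
  if (drift > .ROT_REJECT_TOL) {
    slreg_error("slreg_invalid_input",
                sprintf("matrix is not orthonormal (drift %.3g)", drift))
  }
  if (drift > .ROT_DRIFT_TOL) {
    rotation <- orthonormalize(rotation)
  }
  if (det(rotation) < 0) {
    slreg_error("slreg_invalid_input",
                "matrix is a reflection (det = -1), not a proper rotation")
  }
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @rdname rigid_transform
#' @export
transform_identity <- function() rigid_transform(diag(3), c(0, 0, 0))

#' @rdname rigid_transform
#' @param x object to test or print.
#' @export
is_rigid_transform <- function(x) inherits(x, "rigid_transform")

#' @rdname rigid_transform
#' @param ... ignored.
#' @export
print.rigid_transform <- function(x, ...) {
  cat("Rigid transform (mm)\n")
  m <- cbind(x$rotation, x$translation)
  dimnames(m) <- list(NULL, c("R1", "R2", "R3", "t"))
  print(round(m, 6))
  invisible(x)
}

# Nearest rotation in Frobenius norm (polar decomposition via SVD).
orthonormalize <- function(R) {
  s <- svd(R)
  Q <- s$u %*% t(s$v)
  if (det(Q) < 0) {
    Q <- s$u %*% diag(c(1, 1, -1)) %*% t(s$v)
  }
  Q
}

#' Compose, invert and apply rigid transforms
#'
#' `compose(outer, inner)` returns the transform equivalent to applying
#' `inner` first, then `outer`: \eqn{R = R_o R_i}, \eqn{t = R_o t_i + t_o}.
#' `invert` returns the inverse transform. `apply_transform` maps a point
#' (length-3 vector) or a set of points (n x 3 matrix, one point per row).
#'
#' @param outer,inner,transform `rigid_transform` objects.
#' @param points numeric length-3 vector or n x 3 matrix of points (mm).
#' @return A `rigid_transform`, or transformed points in the input shape.
#' @examples
#' Rz90 <- rotation_axis_angle(c(0, 0, 1), pi / 2)
#' T1 <- rigid_transform(Rz90, c(10, 0, 0))
#' apply_transform(T1, c(1, 0, 0))
#' compose(T1, invert(T1))  # identity
#' @export
compose <- function(outer, inner) {
  check_transform(outer)
  check_transform(inner)
  rigid_transform(outer$rotation %*% inner$rotation,
                  drop(outer$rotation %*% inner$translation) +
                    outer$translation)
}

#' @rdname compose
#' @export
invert <- function(transform) {
  check_transform(transform)
  Rt <- t(transform$rotation)
  rigid_transform(Rt, drop(-Rt %*% transform$translation))
}

#' @rdname compose
#' @export
apply_transform <- function(transform, points) {
  check_transform(transform)
  if (is.matrix(points)) {
    if (ncol(points) != 3L) {
      slreg_error("slreg_invalid_input", "points matrix must have 3 columns")
    }
    stopifnot_finite(points, "points")
    return(sweep(points %*% t(transform$rotation), 2L,
                 transform$translation, "+"))
  }
  p <- as.numeric(points)
  if (length(p) != 3L) {
    slreg_error("slreg_invalid_input", "point must have length 3")
  }
  stopifnot_finite(p, "point")
  drop(transform$rotation %*% p) + transform$translation
}

check_transform <- function(x) {
  if (!is_rigid_transform(x)) {
    slreg_error("slreg_invalid_input", "expected a rigid_transform object")
  }
  invisible(x)
}

#' Elementary rotation about an axis
#'
#' Rodrigues' formula: rotation by `angle` radians about the (normalized)
#' `axis`.
#'
#' @param axis numeric length-3, non-zero.
#' @param angle rotation angle in radians.
#' @return 3x3 rotation matrix.
#' @export
rotation_axis_angle <- function(axis, angle) {
  axis <- as.numeric(axis)
  stopifnot_finite(axis, "axis")
  n <- sqrt(sum(axis^2))
  if (n < 1e-12) {
    slreg_error("slreg_invalid_input", "rotation axis must be non-zero")
  }
  a <- axis / n
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

vec_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Build a rotation from two measured body axes
#'
#' Constructs the orthonormal frame used by the single-landmark method from
#' a measured longitudinal direction and an approximate "up" (anterior)
#' direction: column 1 is the normalized longitudinal axis, column 3 the
#' component of `up` orthogonal to it (Gram-Schmidt), and column 2 the
#' cross product completing a right-handed frame (left-right axis).
#'
#' @param longitudinal numeric length-3, the patient's cranio-caudal axis.
#' @param up numeric length-3, approximate anterior direction; must not be
#'   (anti)parallel to `longitudinal`.
#' @return 3x3 proper rotation matrix with the frame axes as columns.
#' @examples
#' rotation_from_axes(c(1, 0, 0), c(0, 0, 1))  # identity
#' @export
rotation_from_axes <- function(longitudinal, up) {
  longitudinal <- as.numeric(longitudinal)
  up <- as.numeric(up)
  stopifnot_finite(longitudinal, "longitudinal")
  stopifnot_finite(up, "up")
  nl <- sqrt(sum(longitudinal^2))
  nu <- sqrt(sum(up^2))
  if (nl < 1e-12 || nu < 1e-12) {
    slreg_error("slreg_invalid_input", "axis vectors must be non-zero")
  }
  x <- longitudinal / nl
  u <- up / nu
  z <- u - sum(u * x) * x
  nz <- sqrt(sum(z^2))
  # sin of the angle between the axes; reject near-(anti)parallel input
  if (nz < 1e-6) {
    slreg_error("slreg_degenerate_axes",
                "longitudinal and up axes are (anti)parallel")
  }
  z <- z / nz
  y <- vec_cross(z, x)  # right-handed: x cross y = z
  cbind(x, y, z, deparse.level = 0)
}

#' Quaternion conversions
#'
#' Unit quaternions in (w, x, y, z) component order, the convention of
#' optical-tracking pose files. `quat_to_matrix` normalizes its input;
#' `matrix_to_quat` returns the quaternion with non-negative w (q and -q
#' encode the same rotation).
#'
#' @param q numeric length-4 quaternion `(w, x, y, z)`.
#' @param R 3x3 rotation matrix.
#' @return A rotation matrix, or a unit quaternion.
#' @export
quat_to_matrix <- function(q) {
  q <- as.numeric(q)
  if (length(q) != 4L) {
    slreg_error("slreg_invalid_input", "quaternion must have length 4")
  }
  stopifnot_finite(q, "quaternion")
  n <- sqrt(sum(q^2))
  if (n < 1e-12) {
    slreg_error("slreg_invalid_input", "quaternion must be non-zero")
  }
  q <- q / n
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3)
}

#' @rdname quat_to_matrix
#' @export
matrix_to_quat <- function(R) {
  R <- as.matrix(R)
  if (!all(dim(R) == c(3L, 3L))) {
    slreg_error("slreg_invalid_input", "expected a 3x3 rotation matrix")
  }
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  # Shepperd's method: pick the numerically largest pivot
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s,
           (R[3, 2] - R[2, 3]) / s,
           (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] > R[2, 2] && R[1, 1] > R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s,
           0.25 * s,
           (R[1, 2] + R[2, 1]) / s,
           (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] > R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s,
           (R[1, 2] + R[2, 1]) / s,
           0.25 * s,
           (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s,
           (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s,
           0.25 * s)
  }
  q <- q / sqrt(sum(q^2))
  if (q[1] < 0) q <- -q
  q
}

#' Average of clustered rotation samples
#'
#' Chordal mean of unit quaternions: signs are aligned to the first sample
#' (a quaternion and its negation encode the same rotation), components are
#' averaged and the result renormalized. Adequate for the tightly clustered
#' samples produced by repeated orientation acquisition with a tracked tool;
#' not intended for widely spread rotations.
#'
#' @param samples a list of length-4 quaternions `(w, x, y, z)`, or an
#'   n x 4 matrix with one quaternion per row.
#' @return A unit quaternion `(w, x, y, z)`.
#' @examples
#' qa <- matrix_to_quat(rotation_axis_angle(c(0, 0, 1), 10 * pi / 180))
#' qb <- matrix_to_quat(rotation_axis_angle(c(0, 0, 1), 20 * pi / 180))
#' mean_rotation(list(qa, qb))  # z-rotation by 15 degrees
#' @export
mean_rotation <- function(samples) {
  if (is.list(samples)) {
    if (length(samples) == 0L) {
      slreg_error("slreg_empty_input", "mean_rotation needs at least one sample")
    }
    samples <- do.call(rbind, lapply(samples, as.numeric))
  }
  if (is.null(samples) || length(samples) == 0L) {
    slreg_error("slreg_empty_input", "mean_rotation needs at least one sample")
  }
  samples <- as.matrix(samples)
  if (nrow(samples) < 1L || ncol(samples) != 4L) {
    if (length(samples) == 0L || nrow(samples) < 1L) {
      slreg_error("slreg_empty_input",
                  "mean_rotation needs at least one sample")
    }
    slreg_error("slreg_invalid_input", "samples must be quaternions (n x 4)")
  }
  stopifnot_finite(samples, "quaternion samples")
  norms <- sqrt(rowSums(samples^2))
  if (any(norms < 1e-12)) {
    slreg_error("slreg_invalid_input", "zero quaternion in samples")
  }
  samples <- samples / norms
  signs <- ifelse(samples %*% samples[1L, ] < 0, -1, 1)
  m <- colSums(samples * drop(signs))
  m / sqrt(sum(m^2))
}

#' Tracked-tool pose
#'
#' One timestamped sample of a tracked tool's rigid transform (tool frame to
#' the tracking reference frame), as reported by an optical tracking system.
#'
#' @param timestamp acquisition time in seconds.
#' @param tool_id character label of the tracked tool.
#' @param transform `rigid_transform` mapping tool frame to reference frame.
#' @return An object of class `tool_pose`.
#' @export
pose <- function(timestamp, tool_id, transform) {
  check_transform(transform)
  stopifnot_finite(as.numeric(timestamp), "timestamp")
  structure(list(timestamp = as.numeric(timestamp),
                 tool_id = as.character(tool_id),
                 transform = transform),
            class = "tool_pose")
}

#' @rdname pose
#' @param x object to test or print.
#' @export
is_pose <- function(x) inherits(x, "tool_pose")

#' @rdname pose
#' @param ... ignored.
#' @export
print.tool_pose <- function(x, ...) {
  cat(sprintf("Pose of tool '%s' at t = %.4f s\n", x$tool_id, x$timestamp))
  print(x$transform)
  invisible(x)
}
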