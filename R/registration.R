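# Image-to-patient registration: the single-landmark method (SLRM; tool
# orientation + one landmark, translation-only re-registration) and
# classical least-squares fiducial registration (FLRM) with FRE reporting.

#' Corresponding landmark pairs
#'
#' A set of landmarks marked both in the preoperative image frame and in
#' the patient/tracking reference frame (mm). Stored as a data frame with
#' columns `label`, `image_x/y/z`, `patient_x/y/z`; `landmark_pair` builds
#' the single-pair case.
#'
#' @param labels character vector of landmark labels.
#' @param p_image n x 3 matrix (or length-3 vector for one pair) of image
#'   frame coordinates.
#' @param p_patient n x 3 matrix (or length-3 vector) of patient frame
#'   coordinates.
#' @param label label for the single pair.
#' @return A data frame of class `landmark_pairs`.
#' @export
landmark_pairs <- function(labels, p_image, p_patient) {
  if (is.null(dim(p_image))) p_image <- matrix(p_image, ncol = 3L)
  if (is.null(dim(p_patient))) p_patient <- matrix(p_patient, ncol = 3L)
  p_image <- as.matrix(p_image)
  p_patient <- as.matrix(p_patient)
  if (!all(dim(p_image) == dim(p_patient)) || ncol(p_image) != 3L) {
    slreg_error("slreg_invalid_input",
                "p_image and p_patient must both be n x 3")
  }
  if (length(labels) != nrow(p_image)) {
    slreg_error("slreg_invalid_input", "one label per pair required")
  }
  stopifnot_finite(p_image, "image points")
  stopifnot_finite(p_patient, "patient points")
  out <- data.frame(label = as.character(labels),
                    image_x = p_image[, 1], image_y = p_image[, 2],
                    image_z = p_image[, 3],
                    patient_x = p_patient[, 1], patient_y = p_patient[, 2],
                    patient_z = p_patient[, 3],
                    stringsAsFactors = FALSE)
  class(out) <- c("landmark_pairs", "data.frame")
  out
}

#' @rdname landmark_pairs
#' @export
landmark_pair <- function(label, p_image, p_patient) {
  landmark_pairs(label, p_image, p_patient)
}

as_landmark_pairs <- function(pairs) {
  if (inherits(pairs, "landmark_pairs")) return(pairs)
  need <- c("label", "image_x", "image_y", "image_z",
            "patient_x", "patient_y", "patient_z")
  if (is.data.frame(pairs) && all(need %in% names(pairs))) {
    class(pairs) <- c("landmark_pairs", "data.frame")
    return(pairs)
  }
  slreg_error("slreg_invalid_input", "expected a landmark_pairs data frame")
}

image_points <- function(pairs) {
  unname(as.matrix(pairs[, c("image_x", "image_y", "image_z")]))
}

patient_points <- function(pairs) {
  unname(as.matrix(pairs[, c("patient_x", "patient_y", "patient_z")]))
}

new_registration_result <- function(transform, method, fre, n_points) {
  structure(list(transform = transform, method = method,
                 fre = fre, n_points = as.integer(n_points)),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("%s registration (%d point%s)\n", x$method, x$n_points,
              if (x$n_points == 1L) "" else "s"))
  if (!is.na(x$fre)) cat(sprintf("FRE: %.4f mm\n", x$fre))
  print(x$transform)
  invisible(x)
}

# Tool-axis convention: the pointer's local +x axis is laid along the
# patient's longitudinal (cranio-caudal) axis, its local +z points
# anteriorly ("up" for a supine patient). The patient frame is rebuilt from
# these two measured axes by Gram-Schmidt.
tool_axes_to_rotation <- function(R_tool) {
  rotation_from_axes(R_tool[, 1L], R_tool[, 3L])
}

#' Single-landmark image-to-patient registration (initialization)
#'
#' Phase 1 of the single-landmark method: the rotation of the
#' image-to-patient transform is taken from the measured orientation of a
#' tracked tool laid along the patient's longitudinal axis, parallel to the
#' coronal plane; the translation is then chosen so that one anatomical
#' reference landmark, marked in the image and sampled with the tracked
#' pointer, maps exactly. For a prone patient the pointer is still held
#' facing up (so its markers stay visible), and a 180-degree rotation about
#' the longitudinal axis is pre-composed to account for the flipped
#' anatomy.
#'
#' Several orientation samples may be supplied; by default they are
#' averaged (chordal quaternion mean), or the last sample alone can be
#' used.
#'
#' @param tool_pose a `tool_pose`, or a list of poses when the orientation
#'   was sampled several times.
#' @param orientation `"supine"` or `"prone"`.
#' @param ref a single [landmark_pair()]: the reference landmark in image
#'   and patient coordinates.
#' @param sample_mode how to combine several orientation samples:
#'   `"average"` (default) or `"last"`.
#' @return A `registration_result` with `method = "SLRM"` (no FRE: a
#'   single-point fit has zero residual at the registered point by
#'   construction).
#' @seealso [slrm_reregister()], [flrm_register()]
#' @export
slrm_initialize <- function(tool_pose, orientation = c("supine", "prone"),
                            ref, sample_mode = c("average", "last")) {
  orientation <- match.arg(orientation)
  sample_mode <- match.arg(sample_mode)
  poses <- if (is_pose(tool_pose)) list(tool_pose) else tool_pose
  if (!length(poses) || !all(vapply(poses, is_pose, logical(1)))) {
    slreg_error("slreg_invalid_input", "tool_pose must be pose object(s)")
  }
  ref <- as_landmark_pairs(ref)
  if (nrow(ref) != 1L) {
    slreg_error("slreg_invalid_input", "ref must be a single landmark pair")
  }
  R_tool <- if (length(poses) == 1L || sample_mode == "last") {
    poses[[length(poses)]]$transform$rotation
  } else {
    quat_to_matrix(mean_rotation(lapply(poses, function(p) {
      matrix_to_quat(p$transform$rotation)
    })))
  }
  R <- tool_axes_to_rotation(R_tool)
  if (orientation == "prone") {
    # anatomy flipped about the cranio-caudal axis relative to the pointer
    R <- R %*% rotation_axis_angle(c(1, 0, 0), pi)
  }
  p_img <- drop(image_points(ref))
  p_pat <- drop(patient_points(ref))
  t <- p_pat - drop(R %*% p_img)
  new_registration_result(rigid_transform(R, t), "SLRM", NA_real_, 1L)
}

#' Re-register a single-landmark registration at a new point
#'
#' Phase 2 of the single-landmark method: whenever a new landmark is
#' sampled intraoperatively (e.g. a lesion centre clicked on the tracked
#' ultrasound image), the translation offset is updated so the new point
#' maps exactly, while the orientation is kept unchanged. Only the latest
#' point is honoured; there is no history blending.
#'
#' @param current a `registration_result` produced by [slrm_initialize()]
#'   (or a previous re-registration).
#' @param new_pair a single [landmark_pair()].
#' @return A `registration_result` with the same rotation and an updated
#'   translation; the new landmark has zero residual.
#' @export
slrm_reregister <- function(current, new_pair) {
  if (!inherits(current, "registration_result") || current$method != "SLRM") {
    slreg_error("slreg_method_mismatch",
                "re-registration applies to SLRM results only")
  }
  new_pair <- as_landmark_pairs(new_pair)
  if (nrow(new_pair) != 1L) {
    slreg_error("slreg_invalid_input", "new_pair must be a single pair")
  }
  R <- current$transform$rotation
  p_img <- drop(image_points(new_pair))
  p_pat <- drop(patient_points(new_pair))
  t <- p_pat - drop(R %*% p_img)
  out <- new_registration_result(
    structure(list(rotation = R, translation = t), class = "rigid_transform"),
    "SLRM", NA_real_, 1L)
  out
}

#' Fiducial least-squares rigid registration
#'
#' Classical rigid point-set matching of three or more corresponding
#' fiducials: centroids are subtracted, the rotation is the SVD solution of
#' the cross-covariance (Procrustes/Arun) problem with reflection
#' correction (sign flip of the last singular direction when the determinant
#' is negative), and the translation aligns the centroids. The fiducial
#' registration error (FRE) is the root-mean-square residual over the
#' fitting pairs.
#'
#' @param pairs a [landmark_pairs()] data frame with at least 3
#'   non-collinear pairs.
#' @return A `registration_result` with `method = "FLRM"`, the fitted
#'   transform, `fre` (mm) and `n_points`. The logical attribute
#'   `reflection_corrected` records whether the degenerate-sign branch was
#'   taken.
#' @export
flrm_register <- function(pairs) {
  pairs <- as_landmark_pairs(pairs)
  n <- nrow(pairs)
  if (n < 3L) {
    slreg_error("slreg_insufficient_points",
                "fiducial registration needs at least 3 pairs")
  }
  X <- image_points(pairs)
  Y <- patient_points(pairs)
  xc <- colMeans(X)
  yc <- colMeans(Y)
  Xc <- sweep(X, 2L, xc)
  Yc <- sweep(Y, 2L, yc)
  sv <- svd(Xc, nu = 0, nv = 0)$d
  if (sv[2L] / sv[1L] <= 1e-6) {
    slreg_error("slreg_degenerate_configuration",
                "image-side fiducials are (nearly) collinear")
  }
  H <- crossprod(Xc, Yc)  # 3x3 cross-covariance
  s <- svd(H)
  R <- s$v %*% t(s$u)
  corrected <- FALSE
  if (det(R) < 0) {
    R <- s$v %*% diag(c(1, 1, -1)) %*% t(s$u)
    corrected <- TRUE
  }
  t <- yc - drop(R %*% xc)
  transform <- rigid_transform(R, t)
  res <- residual_norms(transform, X, Y)
  out <- new_registration_result(transform, "FLRM",
                                 sqrt(mean(res^2)), n)
  attr(out, "reflection_corrected") <- corrected
  out
}

residual_norms <- function(transform, X, Y) {
  pred <- apply_transform(transform, X)
  sqrt(rowSums((pred - Y)^2))
}

#' Per-fiducial residuals of a registration
#'
#' Euclidean distance, per pair, between each image landmark mapped by the
#' registration transform and its measured patient-frame position. For the
#' pairs a fiducial registration was fitted on, the root-mean-square of
#' these residuals equals the reported FRE.
#'
#' @param result a `registration_result`.
#' @param pairs a [landmark_pairs()] data frame.
#' @return Numeric vector of residuals (mm), one per pair.
#' @export
fiducial_residuals <- function(result, pairs) {
  if (!inherits(result, "registration_result")) {
    slreg_error("slreg_invalid_input", "expected a registration_result")
  }
  pairs <- as_landmark_pairs(pairs)
  residual_norms(result$transform, image_points(pairs),
                 patient_points(pairs))
}
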