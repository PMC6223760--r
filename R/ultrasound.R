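# Tracked 2-D ultrasound point localization: map a user click on the live
# US slice to a 3-D point in the tracking reference frame via the probe
# calibration transform and the probe pose at click time.

#' Ultrasound image geometry
#'
#' Pixel grid and physical geometry of a tracked 2-D (linear-array)
#' ultrasound image: pixel counts, mm-per-pixel spacings and the probe
#' spatial calibration transform, which maps the image-plane frame into the
#' probe sensor frame. Pixels are 0-based, `u` along columns (lateral) and
#' `v` along rows (axial depth); points sit at pixel centres and the image
#' plane is z = 0.
#'
#' @param rows,cols pixel counts.
#' @param spacing_u,spacing_v pixel spacings in mm/pixel (positive).
#' @param calibration `rigid_transform` image-plane frame -> probe sensor
#'   frame (the probe calibration, estimated elsewhere; an input here).
#' @return An object of class `us_geometry`.
#' @export
us_geometry <- function(rows, cols, spacing_u, spacing_v,
                        calibration = transform_identity()) {
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (rows < 1L || cols < 1L) {
    slreg_error("slreg_invalid_input", "rows and cols must be positive")
  }
  if (!is.numeric(spacing_u) || !is.numeric(spacing_v) ||
      spacing_u <= 0 || spacing_v <= 0) {
    slreg_error("slreg_invalid_input", "pixel spacings must be positive")
  }
  check_transform(calibration)
  structure(list(rows = rows, cols = cols,
                 spacing_u = as.numeric(spacing_u),
                 spacing_v = as.numeric(spacing_v),
                 calibration = calibration),
            class = "us_geometry")
}

#' A click on the live ultrasound slice
#'
#' User-selected point on the tracked US image (e.g. the centre of a
#' tumour), together with the probe pose at click time. Coordinates may be
#' fractional: zooming the slice lets the user aim between pixel centres.
#'
#' @param u,v 0-based pixel coordinates (column, row); fractional allowed.
#' @param probe_pose `tool_pose` of the probe sensor at click time.
#' @return An object of class `us_click`.
#' @export
us_click <- function(u, v, probe_pose) {
  stopifnot_finite(c(u, v), "click coordinates")
  if (!is_pose(probe_pose)) {
    slreg_error("slreg_invalid_input", "probe_pose must be a tool_pose")
  }
  structure(list(u = as.numeric(u), v = as.numeric(v),
                 probe_pose = probe_pose),
            class = "us_click")
}

#' Convert a click to image-plane millimetres
#'
#' Scales pixel coordinates by the pixel spacings; the result lies in the
#' image-plane frame with z identically 0 (a 2-D slice).
#'
#' @param click a [us_click()].
#' @param geom a [us_geometry()].
#' @return Numeric length-3 point (mm) in the image-plane frame.
#' @export
pixel_to_image_mm <- function(click, geom) {
  if (!inherits(click, "us_click") || !inherits(geom, "us_geometry")) {
    slreg_error("slreg_invalid_input", "expected a us_click and a us_geometry")
  }
  if (click$u < 0 || click$u > geom$cols - 1L ||
      click$v < 0 || click$v > geom$rows - 1L) {
    slreg_error("slreg_out_of_bounds",
                sprintf("click (%.2f, %.2f) outside %d x %d image",
                        click$u, click$v, geom$cols, geom$rows))
  }
  c(click$u * geom$spacing_u, click$v * geom$spacing_v, 0)
}

#' Localize a click in the tracking reference frame
#'
#' The full tracked-ultrasound chain: pixel -> image-plane mm -> probe
#' sensor frame (probe calibration) -> reference frame (probe pose at click
#' time). This is the mechanism by which a lesion clicked on the US image
#' becomes a 3-D landmark for re-registration.
#'
#' @inheritParams pixel_to_image_mm
#' @return Numeric length-3 point (mm) in the reference frame.
#' @export
click_to_reference <- function(click, geom) {
  p_plane <- pixel_to_image_mm(click, geom)
  apply_transform(click$probe_pose$transform,
                  apply_transform(geom$calibration, p_plane))
}
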