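# Plain-text file formats: 4x4 homogeneous transform files, tracked-pose
# CSV (quaternion + translation), landmark CSV, ultrasound geometry config
# (YAML) and simulated-trial tables.

#' Read and write 4x4 homogeneous transform files
#'
#' Plain text, four rows of four whitespace-separated floats (row-major
#' homogeneous matrix, millimetre units). The last row must be
#' `0 0 0 1`.
#'
#' @param file path to the transform file.
#' @param transform a `rigid_transform`.
#' @return `read_transform` returns a `rigid_transform`;
#'   `write_transform` invisibly returns `file`.
#' @export
read_transform <- function(file) {
  m <- unname(as.matrix(read.table(file, header = FALSE)))
  if (!all(dim(m) == c(4L, 4L))) {
    slreg_error("slreg_invalid_input",
                sprintf("'%s' is not a 4x4 transform file", file))
  }
  if (max(abs(m[4L, ] - c(0, 0, 0, 1))) > 1e-9) {
    slreg_error("slreg_invalid_input",
                "last row of a homogeneous transform must be 0 0 0 1")
  }
  rigid_transform(m[1:3, 1:3], m[1:3, 4L])
}

#' @rdname read_transform
#' @export
write_transform <- function(transform, file) {
  check_transform(transform)
  m <- rbind(cbind(transform$rotation, transform$translation), c(0, 0, 0, 1))
  lines <- apply(m, 1L, function(r) paste(formatC(r, format = "g", digits = 17),
                                          collapse = " "))
  writeLines(lines, file)
  invisible(file)
}

#' Read and write tracked-pose CSV files
#'
#' CSV with header `timestamp,tool_id,qw,qx,qy,qz,tx,ty,tz`: unit
#' quaternion (w, x, y, z) and translation in mm, one tracking sample per
#' row.
#'
#' @param file path to the pose CSV.
#' @param poses a list of `tool_pose` objects.
#' @return `read_poses` returns a list of `tool_pose` objects;
#'   `write_poses` invisibly returns `file`.
#' @export
read_poses <- function(file) {
  df <- read.csv(file, stringsAsFactors = FALSE)
  need <- c("timestamp", "tool_id", "qw", "qx", "qy", "qz", "tx", "ty", "tz")
  if (!all(need %in% names(df))) {
    slreg_error("slreg_invalid_input",
                paste("pose CSV must have columns", paste(need, collapse = ",")))
  }
  lapply(seq_len(nrow(df)), function(i) {
    q <- as.numeric(df[i, c("qw", "qx", "qy", "qz")])
    t <- as.numeric(df[i, c("tx", "ty", "tz")])
    pose(df$timestamp[i], df$tool_id[i],
         rigid_transform(quat_to_matrix(q), t))
  })
}

#' @rdname read_poses
#' @export
write_poses <- function(poses, file) {
  rows <- lapply(poses, function(p) {
    if (!is_pose(p)) {
      slreg_error("slreg_invalid_input", "write_poses expects tool_pose objects")
    }
    q <- matrix_to_quat(p$transform$rotation)
    data.frame(timestamp = p$timestamp, tool_id = p$tool_id,
               qw = q[1], qx = q[2], qy = q[3], qz = q[4],
               tx = p$transform$translation[1],
               ty = p$transform$translation[2],
               tz = p$transform$translation[3])
  })
  write.csv(do.call(rbind, rows), file, row.names = FALSE)
  invisible(file)
}

#' Read and write landmark files
#'
#' CSV with columns `label,frame,x,y,z`, `frame` being `image` or
#' `patient` (mm units). Rows are joined on `label` into corresponding
#' point pairs; every label must appear once per frame.
#'
#' @param file path to the landmark CSV.
#' @param pairs a `landmark_pairs` data frame (see [landmark_pairs()]).
#' @return `read_landmarks` returns a `landmark_pairs` data frame;
#'   `write_landmarks` invisibly returns `file`.
#' @export
read_landmarks <- function(file) {
  df <- read.csv(file, stringsAsFactors = FALSE)
  need <- c("label", "frame", "x", "y", "z")
  if (!all(need %in% names(df))) {
    slreg_error("slreg_invalid_input",
                "landmark CSV must have columns label,frame,x,y,z")
  }
  if (!all(df$frame %in% c("image", "patient"))) {
    slreg_error("slreg_invalid_input",
                "landmark frame must be 'image' or 'patient'")
  }
  img <- df[df$frame == "image", ]
  pat <- df[df$frame == "patient", ]
  labels <- sort(intersect(img$label, pat$label))
  if (anyDuplicated(img$label) || anyDuplicated(pat$label)) {
    slreg_error("slreg_invalid_input",
                "each label may appear once per frame in a landmark file")
  }
  if (length(labels) == 0L) {
    slreg_error("slreg_invalid_input", "no matching image/patient labels")
  }
  img <- img[match(labels, img$label), ]
  pat <- pat[match(labels, pat$label), ]
  landmark_pairs(labels,
                 as.matrix(img[, c("x", "y", "z")]),
                 as.matrix(pat[, c("x", "y", "z")]))
}

#' @rdname read_landmarks
#' @export
write_landmarks <- function(pairs, file) {
  pairs <- as_landmark_pairs(pairs)
  long <- rbind(
    data.frame(label = pairs$label, frame = "image",
               x = pairs$image_x, y = pairs$image_y, z = pairs$image_z),
    data.frame(label = pairs$label, frame = "patient",
               x = pairs$patient_x, y = pairs$patient_y, z = pairs$patient_z))
  write.csv(long, file, row.names = FALSE)
  invisible(file)
}

#' Read an ultrasound geometry configuration file
#'
#' YAML with fields `rows`, `cols`, `spacing_u`, `spacing_v` (mm/pixel) and
#' `calibration`: either a path to a 4x4 transform file (resolved relative
#' to the config file) or an inline list of four rows of four numbers.
#'
#' @param file path to the YAML config.
#' @return A `us_geometry` object (see [us_geometry()]).
#' @export
read_us_geometry <- function(file) {
  cfg <- yaml::read_yaml(file)
  need <- c("rows", "cols", "spacing_u", "spacing_v")
  if (!all(need %in% names(cfg))) {
    slreg_error("slreg_invalid_input",
                "us geometry config needs rows, cols, spacing_u, spacing_v")
  }
  calib <- transform_identity()
  if (!is.null(cfg$calibration)) {
    if (is.character(cfg$calibration)) {
      path <- cfg$calibration
      if (!file.exists(path)) path <- file.path(dirname(file), cfg$calibration)
      calib <- read_transform(path)
    } else {
      m <- do.call(rbind, lapply(cfg$calibration, as.numeric))
      calib <- rigid_transform(m[1:3, 1:3], m[1:3, 4L])
    }
  }
  us_geometry(cfg$rows, cfg$cols, cfg$spacing_u, cfg$spacing_v, calib)
}
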