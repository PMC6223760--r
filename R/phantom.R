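# Virtual abdominal-phantom simulator: a labelled-point stand-in for a
# soft-tissue ultrasound phantom in a rigid fiducial-carrying case, plus
# the table-displacement experiment comparing single-landmark and fiducial
# registration through the full tracked-pointer / tracked-US chain.

#' Build the default virtual phantom
#'
#' A synthetic stand-in for an abdominal ultrasound phantom, reduced to the
#' labelled points every reported computation needs: an anatomical
#' reference landmark (standing for the meeting point of the round and
#' falciform ligaments on the liver), one lesion placed exactly 60 mm from
#' it, and five fiducial markers spread non-coplanarly over the rigid case
#' (four near the top face, one on the bottom). All coordinates are in the
#' image frame (mm); the current placement on the table is the
#' `ground_truth` image-to-reference transform, identity for a freshly
#' built phantom. Fiducial jitter is deterministic given `seed`.
#'
#' @param seed integer seed for the fiducial jitter.
#' @return An object of class `phantom_model` with elements
#'   `ref_landmark`, `lesion`, `fiducials` (5 x 3 matrix) and
#'   `ground_truth`.
#' @export
build_default_phantom <- function(seed = 0L) {
  ref <- c(150, 200, 80)
  lesion_dir <- c(0.48, 0.64, 0.60)  # unit vector
  lesion <- ref + 60 * lesion_dir
  base <- rbind(c(10, 15, 170),
                c(320, 20, 165),
                c(330, 430, 172),
                c(15, 440, 168),
                c(170, 225, 5))
  fid <- with_seed(as.integer(seed) %% 2147483647L, {
    base + matrix(runif(15L, -5, 5), 5L, 3L)
  })
  rownames(fid) <- paste0("F", 1:5)
  structure(list(ref_landmark = ref, lesion = lesion, fiducials = fid,
                 ground_truth = transform_identity()),
            class = "phantom_model")
}

#' @export
print.phantom_model <- function(x, ...) {
  cat("Virtual phantom\n")
  cat(sprintf("  reference landmark (image): %s mm\n",
              paste(round(x$ref_landmark, 2), collapse = ", ")))
  cat(sprintf("  lesion (image, %.1f mm from landmark): %s mm\n",
              sqrt(sum((x$lesion - x$ref_landmark)^2)),
              paste(round(x$lesion, 2), collapse = ", ")))
  cat(sprintf("  %d case fiducials; placement translation: %s mm\n",
              nrow(x$fiducials),
              paste(round(x$ground_truth$translation, 2), collapse = ", ")))
  invisible(x)
}

# Evaluate expr with a temporary RNG state so simulator helpers do not
# disturb (or depend on) the caller's stream.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Displace the phantom on the table
#'
#' Shifts the phantom's placement (`ground_truth` translation) by `mm`
#' along one of the two table-grid axes; the rotation and all image-frame
#' coordinates are unchanged. Axis convention: `frontal` is reference-frame
#' x, `longitudinal` is reference-frame y.
#'
#' @param phantom a `phantom_model`.
#' @param axis `"frontal"` or `"longitudinal"`.
#' @param mm signed displacement in millimetres.
#' @return The displaced `phantom_model`.
#' @export
apply_displacement <- function(phantom, axis, mm) {
  if (!inherits(phantom, "phantom_model")) {
    slreg_error("slreg_invalid_input", "expected a phantom_model")
  }
  stopifnot_finite(mm, "displacement")
  dir <- switch(as.character(axis),
                frontal = c(1, 0, 0),
                longitudinal = c(0, 1, 0),
                slreg_error("slreg_unknown_axis",
                            sprintf("unknown displacement axis '%s'", axis)))
  g <- phantom$ground_truth
  phantom$ground_truth <- structure(
    list(rotation = g$rotation, translation = g$translation + mm * dir),
    class = "rigid_transform")
  phantom
}

#' Measurement noise model for the simulator
#'
#' Zero-mean Gaussian perturbations applied to the simulated measurement
#' chain: isotropic position jitter on tracked tool origins and sampled
#' points (`sigma_tool_pos`, mm per axis), orientation jitter as a rotation
#' by |N(0, `sigma_tool_angle`)| degrees about a uniformly random axis, and
#' in-plane click jitter on the US image (`sigma_click`, mm per in-plane
#' axis). Defaults are on the order of the sub-millimetre calibration
#' errors of optical tracking set-ups (pointer ~0.4 mm, probe ~0.2 mm):
#' 0.3 mm position, 1 degree orientation, 0.5 mm click.
#'
#' A deterministic pointer-orientation bias (`angle_bias_deg` about
#' `angle_bias_axis`) can additionally be injected to study how a fixed
#' orientation error propagates; it affects only the pointer orientation
#' used by the single-landmark method, not the tracked probe. With
#' `angle_bias_axis = NULL` the axis is chosen perpendicular to the
#' landmark-to-lesion direction, the worst case for target error at the
#' lesion.
#'
#' @param sigma_tool_pos position jitter sd, mm (per axis).
#' @param sigma_tool_angle orientation jitter sd, degrees.
#' @param sigma_click US click jitter sd, mm (per in-plane axis).
#' @param angle_bias_deg deterministic pointer-orientation bias, degrees.
#' @param angle_bias_axis length-3 axis for the bias, or `NULL` for the
#'   automatic perpendicular choice.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(sigma_tool_pos = 0.3, sigma_tool_angle = 1,
                        sigma_click = 0.5, angle_bias_deg = 0,
                        angle_bias_axis = NULL) {
  sig <- c(sigma_tool_pos, sigma_tool_angle, sigma_click)
  stopifnot_finite(sig, "noise sigmas")
  if (any(sig < 0)) {
    slreg_error("slreg_invalid_input", "noise sigmas must be >= 0")
  }
  stopifnot_finite(angle_bias_deg, "angle_bias_deg")
  if (!is.null(angle_bias_axis)) {
    stopifnot_finite(angle_bias_axis, "angle_bias_axis")
  }
  structure(list(sigma_tool_pos = sigma_tool_pos,
                 sigma_tool_angle = sigma_tool_angle,
                 sigma_click = sigma_click,
                 angle_bias_deg = angle_bias_deg,
                 angle_bias_axis = angle_bias_axis),
            class = "noise_model")
}

#' Simulated noisy measurements
#'
#' `sample_tracked_point` perturbs a true 3-D point with isotropic Gaussian
#' jitter (sd `sigma_tool_pos` per axis). `sample_tool_orientation`
#' perturbs a rotation by an angle drawn from |N(0, `sigma_tool_angle`
#' degrees)| about a uniformly random axis (applied in the reference
#' frame). Both consume the global RNG stream, so results are deterministic
#' given `set.seed()`.
#'
#' @param true_point numeric length-3 true position (mm).
#' @param true_rotation 3x3 true rotation matrix.
#' @param noise a [noise_model()].
#' @return A perturbed point or rotation matrix.
#' @export
sample_tracked_point <- function(true_point, noise) {
  stopifnot_finite(true_point, "true_point")
  as.numeric(true_point) + rnorm(3L, 0, noise$sigma_tool_pos)
}

#' @rdname sample_tracked_point
#' @export
sample_tool_orientation <- function(true_rotation, noise) {
  angle <- abs(rnorm(1L, 0, noise$sigma_tool_angle * pi / 180))
  axis <- rnorm(3L)
  while (sqrt(sum(axis^2)) < 1e-9) axis <- rnorm(3L)
  rotation_axis_angle(axis, angle) %*% true_rotation
}

#' Displacement-experiment configuration
#'
#' The protocol of the accuracy experiment: for each registration method,
#' the phantom is moved `repetitions` times by each displacement along each
#' table axis; after every move the model is re-registered and the target
#' error is measured at the lesion. Defaults reproduce the study protocol:
#' 10 repetitions x displacements {10, 50, 100} mm x axes {frontal,
#' longitudinal}, i.e. 60 TRE samples per method.
#'
#' @param displacements positive displacements in mm.
#' @param axes subset of `c("frontal", "longitudinal")`.
#' @param repetitions repetitions per (axis, displacement) cell.
#' @param methods subset of `c("SLRM", "FLRM")`.
#' @param noise a [noise_model()].
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(displacements = c(10, 50, 100),
                              axes = c("frontal", "longitudinal"),
                              repetitions = 10L,
                              methods = c("SLRM", "FLRM"),
                              noise = noise_model()) {
  if (length(displacements) < 1L || any(displacements <= 0)) {
    slreg_error("slreg_invalid_input", "displacements must be positive")
  }
  axes <- match.arg(axes, c("frontal", "longitudinal"), several.ok = TRUE)
  methods <- match.arg(methods, c("SLRM", "FLRM"), several.ok = TRUE)
  repetitions <- as.integer(repetitions)
  if (repetitions < 1L) {
    slreg_error("slreg_invalid_input", "repetitions must be >= 1")
  }
  if (!inherits(noise, "noise_model")) {
    slreg_error("slreg_invalid_input", "noise must be a noise_model")
  }
  structure(list(displacements = as.numeric(displacements), axes = axes,
                 repetitions = repetitions, methods = methods,
                 noise = noise),
            class = "experiment_config")
}

#' Read an experiment configuration file
#'
#' YAML mirroring [experiment_config()]: top-level `displacements`, `axes`,
#' `repetitions`, `methods` and an optional `noise` block with the
#' [noise_model()] fields. Missing fields fall back to the defaults.
#'
#' @param file path to the YAML config.
#' @return An `experiment_config`.
#' @export
read_experiment_config <- function(file) {
  cfg <- yaml::read_yaml(file)
  if (is.null(cfg)) cfg <- list()
  noise_args <- cfg$noise
  noise <- if (is.null(noise_args)) noise_model() else {
    do.call(noise_model, noise_args)
  }
  args <- cfg[intersect(names(cfg),
                        c("displacements", "axes", "repetitions", "methods"))]
  args$noise <- noise
  do.call(experiment_config, args)
}

# Fixed simulated-US geometry: 512x512 linear-array image, 0.2 mm/px,
# identity probe calibration (the calibration is an input; identity keeps
# the simulated chain transparent without loss of generality).
sim_us_geometry <- function() {
  us_geometry(512L, 512L, 0.2, 0.2, transform_identity())
}

# Pointer-bias axis: user-supplied, else perpendicular to the
# landmark-to-lesion direction (worst case for lesion TRE).
bias_axis_for <- function(phantom, noise) {
  if (!is.null(noise$angle_bias_axis)) {
    a <- as.numeric(noise$angle_bias_axis)
    return(a / sqrt(sum(a^2)))
  }
  d <- phantom$lesion - phantom$ref_landmark
  a <- vec_cross(d, c(0, 0, 1))
  if (sqrt(sum(a^2)) < 1e-9) a <- vec_cross(d, c(1, 0, 0))
  a / sqrt(sum(a^2))
}

#' Run the displacement accuracy experiment on the virtual phantom
#'
#' For every (method, axis, displacement, repetition) cell the simulator:
#' displaces the phantom; simulates the measurement chain with the
#' configured noise (pointer-sampled landmark positions, pointer
#' orientation, fiducial positions, probe pose, US click); registers the
#' image to the reference frame (SLRM: orientation + reference landmark,
#' then translation-only re-registration at a fresh sample of the same
#' landmark; FLRM: least-squares fit of all five case fiducials); localizes
#' the lesion by a simulated click on the tracked US image; and records the
#' target registration error (TRE) between the registered image-frame
#' lesion and the US-localized lesion.
#'
#' Each trial draws from its own RNG substream derived from `seed` and the
#' trial index, so results are fully deterministic and independent of trial
#' order.
#'
#' @param config an [experiment_config()].
#' @param seed integer master seed.
#' @param phantom a `phantom_model`; by default the standard phantom built
#'   from `seed`.
#' @return A data frame with one row per trial and columns `method`,
#'   `axis`, `displacement_mm`, `rep`, `tre_mm`, plus an attribute
#'   `transforms`: the list of registered `rigid_transform`s, one per row.
#' @export
run_experiment <- function(config = experiment_config(), seed = 1L,
                           phantom = build_default_phantom(seed)) {
  if (!inherits(config, "experiment_config")) {
    slreg_error("slreg_invalid_input", "config must be an experiment_config")
  }
  grid <- expand.grid(rep = seq_len(config$repetitions),
                      displacement_mm = config$displacements,
                      axis = config$axes,
                      method = config$methods,
                      stringsAsFactors = FALSE)
  noise <- config$noise
  bias_axis <- bias_axis_for(phantom, noise)
  bias_rad <- noise$angle_bias_deg * pi / 180
  geom <- sim_us_geometry()
  u0 <- (geom$cols - 1L) / 2
  v0 <- (geom$rows - 1L) / 2
  p_plane <- c(u0 * geom$spacing_u, v0 * geom$spacing_v, 0)
  seed <- as.numeric(seed)

  transforms <- vector("list", nrow(grid))
  tre_mm <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    trial_seed <- as.integer(((abs(seed) %% 1000003) * 2039 + i * 7919) %%
                               2147483647)
    row <- grid[i, ]
    out <- with_seed(trial_seed, {
      simulate_trial(phantom, row$method, row$axis, row$displacement_mm,
                     noise, bias_axis, bias_rad, geom, u0, v0, p_plane)
    })
    transforms[[i]] <- out$transform
    tre_mm[i] <- out$tre
  }
  trials <- data.frame(method = grid$method, axis = grid$axis,
                       displacement_mm = grid$displacement_mm,
                       rep = grid$rep, tre_mm = tre_mm,
                       stringsAsFactors = FALSE)
  attr(trials, "transforms") <- transforms
  trials
}

simulate_trial <- function(phantom, method, axis, displacement_mm, noise,
                           bias_axis, bias_rad, geom, u0, v0, p_plane) {
  ph <- apply_displacement(phantom, axis, displacement_mm)
  G <- ph$ground_truth
  lesion_ref <- apply_transform(G, ph$lesion)

  # tracked probe, rigidly attached to the case with the lesion in-plane
  probe_R_true <- G$rotation
  probe_t_true <- lesion_ref - drop(probe_R_true %*% p_plane)
  probe_R <- sample_tool_orientation(probe_R_true, noise)
  probe_t <- sample_tracked_point(probe_t_true, noise)
  probe_pose <- pose(0, "probe", rigid_transform(probe_R, probe_t))
  u <- min(max(u0 + rnorm(1L, 0, noise$sigma_click / geom$spacing_u), 0),
           geom$cols - 1L)
  v <- min(max(v0 + rnorm(1L, 0, noise$sigma_click / geom$spacing_v), 0),
           geom$rows - 1L)
  lesion_us <- click_to_reference(us_click(u, v, probe_pose), geom)

  reg <- if (method == "SLRM") {
    # pointer laid along the patient's longitudinal axis; deterministic
    # bias (if any) plus stochastic orientation jitter
    R_true <- if (bias_rad != 0) {
      rotation_axis_angle(bias_axis, bias_rad) %*% G$rotation
    } else {
      G$rotation
    }
    R_sampled <- sample_tool_orientation(R_true, noise)
    tool <- pose(0, "pointer", rigid_transform(R_sampled, c(0, 0, 0)))
    ref_meas1 <- sample_tracked_point(apply_transform(G, ph$ref_landmark),
                                      noise)
    reg0 <- slrm_initialize(tool, "supine",
                            landmark_pair("ref", ph$ref_landmark, ref_meas1))
    ref_meas2 <- sample_tracked_point(apply_transform(G, ph$ref_landmark),
                                      noise)
    slrm_reregister(reg0, landmark_pair("ref", ph$ref_landmark, ref_meas2))
  } else {
    fid_meas <- t(apply(ph$fiducials, 1L, function(f) {
      sample_tracked_point(apply_transform(G, f), noise)
    }))
    flrm_register(landmark_pairs(rownames(ph$fiducials), ph$fiducials,
                                 fid_meas))
  }
  list(transform = reg$transform,
       tre = tre(apply_transform(reg$transform, ph$lesion), lesion_us))
}
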