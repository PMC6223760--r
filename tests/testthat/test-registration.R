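make_tool_pose <- function(R = diag(3)) {
  pose(0, "pointer", rigid_transform(R, c(0, 0, 0)))
}

test_that("slrm_initialize maps the reference landmark exactly", {
  ref <- landmark_pair("ref", c(0, 0, 0), c(5, 5, 5))
  reg <- slrm_initialize(make_tool_pose(), "supine", ref)
  expect_equal(reg$method, "SLRM")
  expect_true(is.na(reg$fre))
  expect_equal(reg$transform$rotation, diag(3))
  expect_equal(reg$transform$translation, c(5, 5, 5))

  # prone: anatomy flipped 180 degrees about the longitudinal axis,
  # registered point still maps with zero residual
  regp <- slrm_initialize(make_tool_pose(), "prone", ref)
  expect_equal(regp$transform$rotation, diag(c(1, -1, -1)), tolerance = 1e-12)
  expect_equal(fiducial_residuals(regp, ref), 0, tolerance = 1e-12)

  Rz30 <- rotation_axis_angle(c(0, 0, 1), 30 * pi / 180)
  reg30 <- slrm_initialize(make_tool_pose(Rz30), "supine",
                           landmark_pair("ref", c(0, 0, 0), c(0, 0, 0)))
  expect_equal(reg30$transform$rotation, Rz30, tolerance = 1e-12)
  expect_equal(reg30$transform$translation, c(0, 0, 0), tolerance = 1e-12)
})

test_that("slrm registration is exact at the registered point for any input", {
  set.seed(31)
  for (i in 1:50) {
    ref <- landmark_pair("ref", runif(3, -100, 100), runif(3, -100, 100))
    reg <- slrm_initialize(make_tool_pose(random_rotation()),
                           sample(c("supine", "prone"), 1), ref)
    expect_lt(fiducial_residuals(reg, ref), 1e-9)
  }
})

test_that("multiple orientation samples are averaged (or last kept)", {
  q10 <- rotation_axis_angle(c(0, 0, 1), 10 * pi / 180)
  q20 <- rotation_axis_angle(c(0, 0, 1), 20 * pi / 180)
  q15 <- rotation_axis_angle(c(0, 0, 1), 15 * pi / 180)
  ref <- landmark_pair("ref", c(0, 0, 0), c(0, 0, 0))
  poses <- list(make_tool_pose(q10), make_tool_pose(q20))
  reg_avg <- slrm_initialize(poses, "supine", ref)
  expect_equal(reg_avg$transform$rotation, q15, tolerance = 1e-9)
  reg_last <- slrm_initialize(poses, "supine", ref, sample_mode = "last")
  expect_equal(reg_last$transform$rotation, q20, tolerance = 1e-12)
})

test_that("slrm_reregister updates the offset, keeping orientation constant", {
  current <- slrm_initialize(make_tool_pose(), "supine",
                             landmark_pair("ref", c(0, 0, 0), c(5, 5, 5)))
  new_pair <- landmark_pair("lesion", c(10, 0, 0), c(12, 1, 0))
  reg <- slrm_reregister(current, new_pair)
  expect_equal(reg$transform$translation, c(2, 1, 0))
  expect_identical(reg$transform$rotation, current$transform$rotation)

  # new point maps with zero residual; the operation is idempotent
  expect_equal(fiducial_residuals(reg, new_pair), 0)
  reg2 <- slrm_reregister(reg, new_pair)
  expect_identical(reg2$transform$translation, reg$transform$translation)

  # a pair already satisfied by the current transform changes nothing
  sat <- landmark_pair("p", c(1, 2, 3), apply_transform(current$transform,
                                                        c(1, 2, 3)))
  expect_equal(slrm_reregister(current, sat)$transform$translation,
               current$transform$translation)
})

test_that("slrm_reregister keeps the rotation bitwise across random cases", {
  set.seed(67)
  for (i in 1:25) {
    reg <- slrm_initialize(make_tool_pose(random_rotation()), "supine",
                           landmark_pair("ref", runif(3), runif(3)))
    reg2 <- slrm_reregister(reg, landmark_pair("p", runif(3, -50, 50),
                                               runif(3, -50, 50)))
    expect_identical(reg2$transform$rotation, reg$transform$rotation)
  }
})

test_that("re-registration rejects non-SLRM results", {
  set.seed(2)
  X <- random_fiducials(5)
  flrm <- flrm_register(landmark_pairs(paste0("f", 1:5), X, X))
  expect_error(slrm_reregister(flrm, landmark_pair("p", c(0, 0, 0),
                                                   c(1, 1, 1))),
               class = "slreg_method_mismatch")
})

test_that("flrm_register recovers constructed transforms exactly", {
  set.seed(12)
  X <- random_fiducials(5)
  ident <- flrm_register(landmark_pairs(paste0("f", 1:5), X, X))
  expect_transform_equal(ident$transform, transform_identity(), tol = 1e-9)
  expect_equal(ident$fre, 0, tolerance = 1e-9)
  expect_equal(ident$n_points, 5L)

  Tt <- rigid_transform(rotation_axis_angle(c(0, 0, 1), pi / 2), c(10, 0, 0))
  Y <- apply_transform(Tt, X)
  reg <- flrm_register(landmark_pairs(paste0("f", 1:5), X, Y))
  expect_transform_equal(reg$transform, Tt, tol = 1e-9)
  expect_lt(reg$fre, 1e-9)
})

test_that("flrm_register matches the brute-force minimizer under noise", {
  set.seed(40)
  for (i in 1:10) {
    X <- random_fiducials(5)
    Tt <- random_rigid()
    Y <- apply_transform(Tt, X) + matrix(rnorm(15, 0, 0.5), 5, 3)
    reg <- flrm_register(landmark_pairs(paste0("f", 1:5), X, Y))
    o <- oracle_rigid_fit(X, Y)
    expect_lt(rotation_angle_between(reg$transform$rotation, o$rotation), 1e-6)
    expect_lt(max(abs(reg$transform$translation - o$translation)), 1e-6)
    expect_lt(abs(reg$fre - o$fre), 1e-6)
    # estimate stays within the noise scale of the truth
    expect_lt(rotation_angle_between(reg$transform$rotation, Tt$rotation), 0.05)
    expect_lt(max(abs(reg$transform$translation - Tt$translation)), 3)
  }
})

test_that("flrm_register rejects too few or collinear fiducials", {
  expect_error(flrm_register(landmark_pairs(c("a", "b"),
                                            rbind(c(0, 0, 0), c(1, 0, 0)),
                                            rbind(c(0, 0, 0), c(1, 0, 0)))),
               class = "slreg_insufficient_points")
  X <- cbind(seq(0, 40, 10), 0, 0)  # five collinear points
  expect_error(flrm_register(landmark_pairs(paste0("f", 1:5), X, X)),
               class = "slreg_degenerate_configuration")
})

test_that("reflection correction yields a proper rotation on a degenerate fit", {
  # frozen instance: near-coplanar image points + heavy noise drive the
  # unconstrained Procrustes solution to a reflection
  set.seed(1)
  X <- cbind(matrix(runif(10, -50, 50), 5, 2), runif(5, -0.01, 0.01))
  R <- rotation_axis_angle(rnorm(3), runif(1, 0, pi))
  Y <- t(R %*% t(X)) + matrix(rnorm(15, 0, 30), 5, 3)
  reg <- flrm_register(landmark_pairs(paste0("f", 1:5), X, Y))
  expect_true(attr(reg, "reflection_corrected"))
  expect_equal(det(reg$transform$rotation), 1, tolerance = 1e-9)
  # corrected solution still matches the constrained brute-force optimum
  o <- oracle_rigid_fit(X, Y)
  expect_lt(abs(reg$fre - o$fre), 1e-6)
})

test_that("flrm translation equivariance: shifting both sets shifts t only", {
  set.seed(90)
  X <- random_fiducials(5)
  Tt <- random_rigid()
  Y <- apply_transform(Tt, X) + matrix(rnorm(15, 0, 0.3), 5, 3)
  d <- c(12, -7, 31)
  reg0 <- flrm_register(landmark_pairs(paste0("f", 1:5), X, Y))
  reg1 <- flrm_register(landmark_pairs(paste0("f", 1:5),
                                       sweep(X, 2, d, "+"),
                                       sweep(Y, 2, d, "+")))
  expect_equal(reg1$transform$rotation, reg0$transform$rotation,
               tolerance = 1e-9)
  expect_equal(reg1$transform$translation,
               reg0$transform$translation +
                 d - drop(reg0$transform$rotation %*% d),
               tolerance = 1e-9)
  expect_equal(reg1$fre, reg0$fre, tolerance = 1e-9)
})

test_that("fiducial_residuals are per-pair distances whose RMS equals FRE", {
  X <- random_fiducials(4)
  perfect <- flrm_register(landmark_pairs(paste0("f", 1:4), X, X))
  expect_equal(fiducial_residuals(perfect, landmark_pairs(paste0("f", 1:4),
                                                          X, X)),
               rep(0, 4), tolerance = 1e-9)

  pairs_off <- landmark_pairs(paste0("f", 1:4), X, sweep(X, 2, c(3, 4, 0), "+"))
  ident_fit <- slrm_initialize(pose(0, "p", transform_identity()), "supine",
                               landmark_pair("r", c(0, 0, 0), c(0, 0, 0)))
  expect_equal(fiducial_residuals(ident_fit, pairs_off), rep(5, 4))

  set.seed(4)
  Y <- X + matrix(rnorm(12, 0, 1), 4, 3)
  pairs <- landmark_pairs(paste0("f", 1:4), X, Y)
  reg <- flrm_register(pairs)
  expect_equal(sqrt(mean(fiducial_residuals(reg, pairs)^2)), reg$fre,
               tolerance = 1e-12)
})

test_that("landmark files round-trip and join image/patient rows on label", {
  set.seed(8)
  pairs <- landmark_pairs(paste0("f", 1:5), random_fiducials(5),
                          random_fiducials(5))
  f <- withr::local_tempfile(fileext = ".csv")
  write_landmarks(pairs, f)
  back <- read_landmarks(f)
  expect_equal(as.data.frame(back)[order(back$label), ],
               as.data.frame(pairs)[order(pairs$label), ],
               ignore_attr = TRUE)

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines("label,frame,x,y,z\nf1,image,0,0,0", bad)
  expect_error(read_landmarks(bad), class = "slreg_invalid_input")
})
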