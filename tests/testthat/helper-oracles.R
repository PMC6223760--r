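# Independent oracles and random-instance generators used across the suite.
# The oracles deliberately avoid the closed-form paths of the package: the
# rigid fit and pivot oracles minimize the residual sum numerically over an
# explicit parameter vector; the Welch oracle is the textbook formula.

rot_vec_to_matrix <- function(v) {
  angle <- sqrt(sum(v^2))
  if (angle < 1e-14) return(diag(3))
  rotation_axis_angle(v / angle, angle)
}

# angle (radians) of the relative rotation between two rotation matrices
rotation_angle_between <- function(R1, R2) {
  ctheta <- (sum(diag(crossprod(R1, R2))) - 1) / 2
  acos(min(1, max(-1, ctheta)))
}

# Brute-force rigid least-squares fit: direct numerical minimization over
# the three rotation parameters (rotation vector), multi-start BFGS. For
# any fixed rotation the optimal translation aligns the centroids
# (elementary calculus), so the search runs on centered points and the
# translation is recovered afterwards.
oracle_rigid_fit <- function(X, Y) {
  xc <- colMeans(X); yc <- colMeans(Y)
  Xc <- sweep(X, 2L, xc); Yc <- sweep(Y, 2L, yc)
  objective <- function(par) {
    sum((Xc %*% t(rot_vec_to_matrix(par)) - Yc)^2)
  }
  starts <- list(c(0, 0, 0), c(pi, 0, 0), c(0, pi, 0), c(0, 0, pi))
  best <- NULL
  for (s in starts) {
    fit <- optim(s, objective, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-16,
                                ndeps = rep(1e-7, 3)))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  # polish: re-minimize over a local perturbation of the best rotation,
  # where the parameters are near zero and finite differences are accurate
  R0 <- rot_vec_to_matrix(best$par)
  obj_local <- function(dv) {
    sum((Xc %*% t(rot_vec_to_matrix(dv) %*% R0) - Yc)^2)
  }
  fit2 <- optim(c(0, 0, 0), obj_local, method = "BFGS",
                control = list(maxit = 200, reltol = 1e-16,
                               ndeps = rep(1e-8, 3)))
  R <- rot_vec_to_matrix(fit2$par) %*% R0
  list(rotation = R, translation = yc - drop(R %*% xc),
       fre = sqrt(min(fit2$value, best$value) / nrow(X)))
}

# Brute-force pivot calibration: minimize the summed squared residuals
# over (tip offset, pivot point).
oracle_pivot <- function(poses) {
  Rs <- lapply(poses, function(p) p$transform$rotation)
  ts <- lapply(poses, function(p) p$transform$translation)
  objective <- function(par) {
    tip <- par[1:3]; piv <- par[4:6]
    sum(vapply(seq_along(Rs), function(i) {
      sum((drop(Rs[[i]] %*% tip) + ts[[i]] - piv)^2)
    }, numeric(1)))
  }
  fit <- optim(rep(0, 6), objective, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-16,
                              ndeps = rep(1e-7, 6)))
  list(tip_offset = fit$par[1:3], pivot_point = fit$par[4:6],
       rms_residual = sqrt(fit$value / length(poses)))
}

# Textbook Welch statistic / Welch-Satterthwaite degrees of freedom.
oracle_welch <- function(g1, g2) {
  v1 <- var(g1) / length(g1)
  v2 <- var(g2) / length(g2)
  t_stat <- (mean(g1) - mean(g2)) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 /
    (v1^2 / (length(g1) - 1) + v2^2 / (length(g2) - 1))
  p <- 2 * pt(-abs(t_stat), df)
  list(statistic = t_stat, df = df, p_value = p)
}

# a unit vector perpendicular to d
vec3_perp <- function(d) {
  e <- if (abs(d[3]) < 0.9 * sqrt(sum(d^2))) c(0, 0, 1) else c(1, 0, 0)
  a <- c(d[2] * e[3] - d[3] * e[2],
         d[3] * e[1] - d[1] * e[3],
         d[1] * e[2] - d[2] * e[1])
  a / sqrt(sum(a^2))
}

random_rotation <- function() {
  q <- rnorm(4)
  quat_to_matrix(q / sqrt(sum(q^2)))
}

random_rigid <- function(scale = 100) {
  rigid_transform(random_rotation(), runif(3, -scale, scale))
}

# n well-spread non-collinear image-side fiducials
random_fiducials <- function(n = 5) {
  repeat {
    X <- matrix(runif(3 * n, -100, 100), n, 3)
    sv <- svd(sweep(X, 2, colMeans(X)))$d
    if (sv[2] / sv[1] > 1e-2) return(X)
  }
}

# synthetic pivoting pose set about a fixed tip/pivot
make_pivot_poses <- function(n, tip, pivot, sigma = 0) {
  lapply(seq_len(n), function(i) {
    R <- random_rotation()
    t <- pivot - drop(R %*% tip) + rnorm(3, 0, sigma)
    pose(i, "pointer", rigid_transform(R, t))
  })
}

expect_transform_equal <- function(a, b, tol = 1e-9) {
  # entry-wise rotation comparison: acos-based angles bottom out near
  # sqrt(machine eps), entries do not
  expect_lt(max(abs(a$rotation - b$rotation)), tol)
  expect_lt(max(abs(a$translation - b$translation)), tol)
}
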