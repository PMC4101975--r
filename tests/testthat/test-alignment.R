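frame_identity <- function() {
  build_cochlear_frame(landmark_set(R = c(5, 0, 0), C = c(0, 0, 0),
                                    A = c(0, 0, 4), I = c(4, 0, 0),
                                    side = "right"))
}

test_that("alignment angles are zero for a perfect plan and signed as documented", {
  fr <- frame_identity()
  anchor <- c(3, 0, -0.5)
  u <- c(0, 1, 0)  # ideal: in-plane, tangential at the anchor
  ang0 <- alignment_angles(u, u, fr, anchor)
  expect_equal(ang0$delta, 0)
  expect_equal(ang0$epsilon, 0)

  # tilt 10 deg toward -z (away from the membrane): delta = +10, epsilon = 0
  v_down <- c(0, cos(10 * pi / 180), -sin(10 * pi / 180))
  ang1 <- alignment_angles(v_down, u, fr, anchor)
  expect_equal(ang1$delta, 10, tolerance = 1e-9)
  expect_equal(ang1$epsilon, 0, tolerance = 1e-9)

  # rotate 5 deg in-plane toward the modiolar axis: epsilon = -5, delta = 0
  v_in <- c(-sin(5 * pi / 180), cos(5 * pi / 180), 0)
  ang2 <- alignment_angles(v_in, u, fr, anchor)
  expect_equal(ang2$delta, 0, tolerance = 1e-9)
  expect_equal(ang2$epsilon, -5, tolerance = 1e-9)
  # and laterally (away from the modiolus): positive epsilon
  v_out <- c(sin(5 * pi / 180), cos(5 * pi / 180), 0)
  expect_equal(alignment_angles(v_out, u, fr, anchor)$epsilon, 5,
               tolerance = 1e-9)

  expect_error(alignment_angles(c(0, 0, 1), u, fr, anchor), "in-plane")
})

test_that("alignment angles are invariant under a consistent rigid transform", {
  set.seed(41)
  fr_lm <- landmark_set(R = c(5, 0, 0), C = c(0, 0, 0), A = c(0.4, 0.1, 4),
                        I = c(4, 0, 0), side = "right")
  fr <- build_cochlear_frame(fr_lm)
  anchor <- c(2.5, 1.2, -0.4)
  u <- c(-0.3, 0.9, -0.1); u <- u / sqrt(sum(u^2))
  v <- c(-0.1, 0.95, -0.25); v <- v / sqrt(sum(v^2))
  ref <- alignment_angles(v, u, fr, anchor)
  for (i in 1:20) {
    Q <- random_rotation(); tv <- rnorm(3, sd = 10)
    lm2 <- landmark_set(Q %*% fr_lm$R + tv, Q %*% fr_lm$C + tv,
                        Q %*% fr_lm$A + tv, Q %*% fr_lm$I + tv, side = "right")
    got <- alignment_angles(Q %*% v, Q %*% u, build_cochlear_frame(lm2),
                            Q %*% anchor + tv)
    expect_equal(got$delta, ref$delta, tolerance = 1e-9)
    expect_equal(got$epsilon, ref$epsilon, tolerance = 1e-9)
  }
})

test_that("fiducial registration recovers exact correspondences and stays proper", {
  set.seed(42)
  pts <- matrix(rnorm(18, sd = 20), ncol = 3L)
  reg <- register_fiducials(pts, pts)
  expect_equal(reg$rotation, diag(3), tolerance = 1e-12)
  expect_equal(reg$translation, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(reg$fre, 0, tolerance = 1e-12)

  for (i in 1:100) {
    Q <- random_rotation(); tv <- rnorm(3, sd = 30)
    fixed <- sweep(pts %*% t(Q), 2L, tv, "+")
    reg <- register_fiducials(pts, fixed)
    expect_lt(max(abs(reg$rotation - Q)), 1e-9)
    expect_lt(max(abs(reg$translation - tv)), 1e-9)
    expect_lt(reg$fre, 1e-9)
    expect_equal(det(reg$rotation), 1, tolerance = 1e-9)
    expect_lt(max(abs(apply_transform(reg, pts) - fixed)), 1e-9)
  }

  expect_error(register_fiducials(pts[1:2, ], pts[1:2, ]), "at least 3")
  line <- cbind(1:5, 2 * (1:5), -(1:5))
  expect_error(register_fiducials(line, line), "collinear")
})

test_that("FRE under isotropic 0.1 mm noise on 6 fiducials has the expected scale", {
  set.seed(43)
  pts <- matrix(rnorm(18, sd = 20), ncol = 3L)
  fres <- vapply(1:100, function(i) {
    Q <- random_rotation(); tv <- rnorm(3, sd = 30)
    fixed <- sweep(pts %*% t(Q), 2L, tv, "+") + matrix(rnorm(18, sd = 0.1), ncol = 3L)
    reg <- register_fiducials(pts, fixed)
    expect_equal(det(reg$rotation), 1, tolerance = 1e-9)  # proper despite noise
    reg$fre
  }, numeric(1))
  # E[FRE] = sigma * sqrt((3n - 6) / n) ~ 0.14 mm for n = 6, sigma = 0.1
  expect_gt(mean(fres), 0.03)
  expect_lt(mean(fres), 0.2)
  expect_true(all(fres > 0.02 & fres < 0.3))
})

test_that("target error is the perpendicular distance to the drilled axis", {
  target <- c(2, 1, -0.5)
  expect_equal(target_error(target, target + c(1, 2, 3), c(1, 2, 3)), 0,
               tolerance = 1e-12)
  # parallel offset of 0.3 mm
  expect_equal(target_error(target, target + c(0, 0.3, 0), c(1, 0, 0)), 0.3)

  set.seed(44)
  for (i in 1:50) {
    p0 <- rnorm(3, sd = 5); d <- rand_unit()
    brute <- optimize(function(s) sqrt(sum((target - (p0 + s * d))^2)),
                      interval = c(-100, 100), tol = 1e-12)$objective
    expect_equal(target_error(target, p0, d), brute, tolerance = 1e-7)
  }
  expect_error(target_error(target, c(0, 0, 0), c(0, 0, 0)), "zero length")
})

test_that("membrane plane error matches the closed-form tilted-plane value", {
  # membrane exactly on z = 0
  th <- seq(0.5, 179.5, by = 0.01)
  flat <- cbind(3 * cos(th * pi / 180), 3 * sin(th * pi / 180), 0)
  res <- membrane_plane_error(flat)
  expect_equal(res$window_mean, 0)
  expect_true(all(res$profile$mean_abs_z_mm[res$profile$n > 0] == 0))

  # membrane on the plane z = x tan(2 deg): window mean over [45, 60] equals
  # the analytic mean of |rho cos(theta) tan(2 deg)|
  tilt <- tan(2 * pi / 180)
  tilted <- cbind(flat[, 1L], flat[, 2L], flat[, 1L] * tilt)
  got <- membrane_plane_error(tilted, theta_window = c(45, 60))$window_mean
  a1 <- 45 * pi / 180; a2 <- 60 * pi / 180
  analytic <- 3 * tilt * (sin(a2) - sin(a1)) / (a2 - a1)
  expect_equal(got, analytic, tolerance = 1e-3)

  # profile grows monotonically with |tilt|
  wm <- vapply(c(0, 1, 2, 4, 8), function(deg) {
    m <- cbind(flat[, 1L], flat[, 2L], flat[, 1L] * tan(deg * pi / 180))
    membrane_plane_error(m)$window_mean
  }, numeric(1))
  expect_true(all(diff(wm) > 0))

  expect_error(membrane_plane_error(flat, theta_window = c(60, 45)), "window")
})

test_that("angular insertion depth unwraps contact angles monotonically", {
  fr <- frame_identity()
  at <- function(deg) cbind(3 * cos(deg * pi / 180), 3 * sin(deg * pi / 180), -0.2)
  expect_equal(angular_insertion_depth(at(c(10, 90, 200, 310)), fr), 310)
  expect_equal(angular_insertion_depth(at(c(300, 350, 30)), fr), 390)
  expect_equal(angular_insertion_depth(at(45), fr), 45)
  expect_error(angular_insertion_depth(rbind(c(0, 0, 2)), fr), "z-axis")
})
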