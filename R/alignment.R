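# Planning and evaluation metrics: out-of-plane / in-plane alignment angles
# of a planned trajectory against the ideal tangent, point-based rigid
# fiducial registration, drilled-trajectory target error, basilar-membrane
# plane-approximation error and angular insertion depth.

#' Alignment angles between a planned and the ideal trajectory
#'
#' Decomposes the angular offset of a planned insertion direction from the
#' ideal (centerline-tangent) direction into two surgical components,
#' evaluated in the local cochlear frame at the shared cochleostomy target:
#'
#' * `delta` (out-of-plane, degrees): the difference of elevation angles
#'   above the basilar-membrane (x-y) plane,
#'   `asin(u_z) - asin(v_z)` for ideal `u` and planned `v`. Positive values
#'   dip the planned trajectory away from the membrane (toward -z); negative
#'   values indicate basilar-membrane collision risk.
#' * `epsilon` (in-plane, degrees): the signed angle between the in-plane
#'   projections of `v` and `u`, positive when `v` deviates laterally (away
#'   from the modiolar axis, toward the outer wall) and negative when it
#'   deviates toward the modiolus. The lateral reference is the radial
#'   direction at the anchor, orthogonalized against the in-plane ideal
#'   tangent.
#'
#' Both angles are zero when the planned and ideal directions coincide.
#'
#' @param planned_dir,ideal_dir unit direction vectors (world frame).
#' @param frame the [build_cochlear_frame()] of the case.
#' @param anchor the shared cochleostomy anchor point (world mm).
#' @return An object of class `alignment_angles`: list with `delta` and
#'   `epsilon` in degrees.
#' @export
alignment_angles <- function(planned_dir, ideal_dir, frame, anchor) {
  validate_cochlear_frame(frame)
  v <- dir_world_to_local(normalize(as_point3(planned_dir, "planned_dir")), frame)
  u <- dir_world_to_local(normalize(as_point3(ideal_dir, "ideal_dir")), frame)
  a <- world_to_local(as_point3(anchor, "anchor"), frame)

  clamp1 <- function(x) max(-1, min(1, x))
  delta <- rad2deg(asin(clamp1(u[3L])) - asin(clamp1(v[3L])))

  v_xy <- v[1:2]; u_xy <- u[1:2]
  if (vec_norm(v_xy) < 1e-9 || vec_norm(u_xy) < 1e-9) {
    stop("in-plane angle undefined: trajectory is parallel to the modiolar axis")
  }
  t_hat <- u_xy / vec_norm(u_xy)
  if (vec_norm(a[1:2]) < 1e-9) stop("in-plane angle undefined: anchor on the modiolar axis")
  r_hat <- a[1:2] / vec_norm(a[1:2])
  # lateral reference: radial direction orthogonalized against the tangent
  n_raw <- r_hat - sum(r_hat * t_hat) * t_hat
  if (vec_norm(n_raw) < 1e-9) {
    stop("in-plane angle undefined: radial direction parallel to the ideal tangent")
  }
  n_hat <- n_raw / vec_norm(n_raw)
  epsilon <- rad2deg(atan2(sum(v_xy * n_hat), sum(v_xy * t_hat)))

  structure(list(delta = delta, epsilon = epsilon), class = "alignment_angles")
}

#' @export
print.alignment_angles <- function(x, ...) {
  cat(sprintf("Trajectory alignment: delta = %+.2f deg (out-of-plane), epsilon = %+.2f deg (in-plane)\n",
              x$delta, x$epsilon))
  if (x$delta < 0) cat("  warning: negative delta indicates basilar-membrane collision risk\n")
  if (x$epsilon < 0) cat("  warning: negative epsilon indicates modiolus collision risk\n")
  invisible(x)
}

#' Point-based rigid registration of paired fiducials
#'
#' Least-squares rigid registration (Kabsch/Umeyama without scaling) of
#' paired fiducial points, e.g. bone-screw centers localized in the pre- and
#' postoperative scans. The estimated rotation is always proper
#' (det = +1, no reflection). The fiducial registration error (FRE) is the
#' root-mean-square residual after alignment.
#'
#' @param moving n x 3 matrix of points to be transformed (mm).
#' @param fixed n x 3 matrix of corresponding target points, same order.
#' @return An object of class `rigid_transform`: list with `rotation`
#'   (3 x 3, proper orthogonal), `translation` (length-3, mm) and `fre`
#'   (mm), such that `fixed ~ moving %*% t(rotation) + translation`.
#' @export
register_fiducials <- function(moving, fixed) {
  M <- as_points_matrix(moving, "moving")
  F <- as_points_matrix(fixed, "fixed")
  if (nrow(M) != nrow(F)) stop("moving and fixed must have the same number of points")
  if (nrow(M) < 3L) stop("need at least 3 fiducial pairs")
  cm <- colMeans(M); cf <- colMeans(F)
  Mc <- sweep(M, 2L, cm); Fc <- sweep(F, 2L, cf)
  sv <- svd(Mc)
  if (sv$d[2L] < 1e-9 * max(sv$d[1L], 1e-12)) {
    stop("fiducials are collinear: rotation is not uniquely determined")
  }
  H <- crossprod(Mc, Fc)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t <- cf - as.vector(R %*% cm)
  resid <- Fc - Mc %*% t(R)
  fre <- sqrt(mean(rowSums(resid^2)))
  structure(list(rotation = R, translation = t, fre = fre),
            class = "rigid_transform")
}

#' Apply a rigid transform to points
#'
#' @param transform a [register_fiducials()] result.
#' @param points length-3 point or n x 3 matrix.
#' @return Transformed points, same shape as the input.
#' @export
apply_transform <- function(transform, points) {
  stopifnot(inherits(transform, "rigid_transform"))
  single <- is.null(dim(points))
  p <- as_points_matrix(points, "points")
  out <- sweep(p %*% t(transform$rotation), 2L, transform$translation, FUN = "+")
  if (single) as.vector(out) else out
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("Rigid transform (Kabsch least squares)\n")
  ang <- rad2deg(acos(max(-1, min(1, (sum(diag(x$rotation)) - 1) / 2))))
  cat(sprintf("  rotation angle: %.3f deg; translation: (%.3f, %.3f, %.3f) mm\n",
              ang, x$translation[1], x$translation[2], x$translation[3]))
  cat(sprintf("  FRE: %.4g mm\n", x$fre))
  invisible(x)
}

#' Drilled-trajectory target error
#'
#' Perpendicular distance (mm) from the planned cochleostomy target to the
#' drilled trajectory axis — the distance at the axis point closest to the
#' planned target. Inputs must already be in a common frame (register first
#' with [register_fiducials()] if they are not).
#'
#' @param planned either an `insertion_trajectory` or a length-3 target
#'   point (mm).
#' @param axis_point a point on the drilled axis (mm).
#' @param axis_dir direction of the drilled axis (need not be unit length,
#'   but must be non-zero).
#' @return Distance in mm.
#' @export
target_error <- function(planned, axis_point, axis_dir) {
  target <- if (inherits(planned, "insertion_trajectory")) planned$target
            else as_point3(planned, "planned")
  p0 <- as_point3(axis_point, "axis_point")
  d <- as_point3(axis_dir, "axis_dir")
  if (vec_norm(d) < .Machine$double.eps) stop("drilled axis direction has zero length")
  d <- d / vec_norm(d)
  w <- target - p0
  vec_norm(w - sum(w * d) * d)
}

#' Basilar-membrane plane-approximation error
#'
#' Quantifies how far a basilar-membrane point set deviates from its modelled
#' location, the local x-y plane: per 5-degree angular bin the mean |z| of
#' the membrane points in the bin, plus the mean |z| over an angular window
#' (default 45-60 degrees, the region used for trajectory computation).
#'
#' @param membrane_points_local n x 3 matrix of membrane points in the
#'   cochlear frame (mm).
#' @param theta_window length-2 angular window in degrees within
#'   \[0, 180\].
#' @param delta_theta profile bin spacing (degrees), default 5.
#' @return A list with `profile` (data frame: `theta_deg`, `n`,
#'   `mean_abs_z_mm`) and `window_mean` (mm).
#' @export
membrane_plane_error <- function(membrane_points_local, theta_window = c(45, 60),
                                 delta_theta = 5) {
  p <- as_points_matrix(membrane_points_local, "membrane_points_local")
  if (length(theta_window) != 2L || theta_window[1L] >= theta_window[2L] ||
      theta_window[1L] < 0 || theta_window[2L] > 180) {
    stop("theta_window must be an increasing interval within [0, 180]")
  }
  theta <- basal_angle_of(p)
  z_abs <- abs(p[, 3L])

  centers <- seq(0, 180, by = delta_theta)
  idx <- round(theta / delta_theta) + 1L
  idx[idx < 1L] <- 1L; idx[idx > length(centers)] <- length(centers)
  keep <- theta <= 180 + delta_theta / 2
  means <- tapply(z_abs[keep], factor(centers[idx[keep]], levels = centers), mean)
  profile <- data.frame(theta_deg = centers,
                        n = as.integer(table(factor(centers[idx[keep]], levels = centers))),
                        mean_abs_z_mm = as.numeric(means))

  in_win <- theta >= theta_window[1L] & theta <= theta_window[2L]
  if (!any(in_win)) stop("no membrane points inside theta_window")
  list(profile = profile, window = theta_window,
       window_mean = mean(z_abs[in_win]))
}

#' Angular insertion depth of an electrode array
#'
#' Computes the basal angle of each contact, unwraps the sequence
#' monotonically starting from the most basal contact (adding 360 degrees at
#' each wrap) and returns the unwrapped angle of the most apical contact.
#' Contacts must be supplied in basal-to-apical order; no re-ordering is
#' attempted.
#'
#' @param contact_points ordered n x 3 matrix (or single point) of electrode
#'   contact positions (world mm).
#' @param frame the [build_cochlear_frame()] of the case.
#' @return Insertion depth in degrees.
#' @export
angular_insertion_depth <- function(contact_points, frame) {
  validate_cochlear_frame(frame)
  p <- world_to_local(as_points_matrix(contact_points, "contact_points"), frame)
  theta <- basal_angle_of(p)
  if (length(theta) == 1L) return(theta)
  unwrapped <- theta
  for (i in 2:length(theta)) {
    while (unwrapped[i] < unwrapped[i - 1L]) unwrapped[i] <- unwrapped[i] + 360
  }
  unwrapped[length(unwrapped)]
}
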