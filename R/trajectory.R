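# Ideal insertion trajectories: tangents of the centerline spline, with the
# cochleostomy target located on the labyrinth mesh by ray/triangle
# intersection (Moller-Trumbore, winding-agnostic, no backface culling).

# Ray parameter below which hits are treated as self-intersections.
T_EPS <- 1e-9

#' Intersect a ray with a single triangle
#'
#' Moller-Trumbore intersection. Winding-agnostic (no backface culling);
#' misses, rays parallel to the triangle plane and hits with ray parameter
#' `t <= 1e-9` return `NULL`. Degenerate (zero-area) triangles return `NULL`
#' with a warning.
#'
#' @param origin ray origin (length-3, mm).
#' @param direction unit direction vector.
#' @param triangle 3 x 3 matrix, one vertex per row.
#' @return `NULL` on a miss, otherwise a list with `t` (ray parameter, mm),
#'   `point` (hit position) and `barycentric` (length-3, sums to 1).
#' @export
ray_triangle_intersect <- function(origin, direction, triangle) {
  origin <- as_point3(origin, "origin")
  direction <- as_point3(direction, "direction")
  tri <- as_points_matrix(triangle, "triangle")
  if (nrow(tri) != 3L) stop("triangle must have exactly 3 vertices")

  e1 <- tri[2L, ] - tri[1L, ]
  e2 <- tri[3L, ] - tri[1L, ]
  if (vec_norm(cross3(e1, e2)) < 1e-12) {
    warning("degenerate triangle in ray_triangle_intersect")
    return(NULL)
  }
  pvec <- cross3(direction, e2)
  det <- sum(e1 * pvec)
  if (abs(det) < 1e-12) return(NULL)  # parallel to the triangle plane
  inv_det <- 1 / det
  tvec <- origin - tri[1L, ]
  u <- sum(tvec * pvec) * inv_det
  if (u < -1e-12 || u > 1 + 1e-12) return(NULL)
  qvec <- cross3(tvec, e1)
  v <- sum(direction * qvec) * inv_det
  if (v < -1e-12 || u + v > 1 + 1e-12) return(NULL)
  t <- sum(e2 * qvec) * inv_det
  if (t <= T_EPS) return(NULL)
  list(t = t, point = origin + t * direction, barycentric = c(1 - u - v, u, v))
}

# Vectorized Moller-Trumbore over all mesh faces; returns the nearest hit
# (list with t, point, barycentric, face_index) or NULL. Degenerate faces
# are skipped. Identical in result to looping ray_triangle_intersect over
# every face and taking the smallest t.
ray_mesh_first_hit <- function(origin, direction, mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1L], , drop = FALSE]
  e1 <- v[f[, 2L], , drop = FALSE] - a
  e2 <- v[f[, 3L], , drop = FALSE] - a

  px <- direction[2L] * e2[, 3L] - direction[3L] * e2[, 2L]
  py <- direction[3L] * e2[, 1L] - direction[1L] * e2[, 3L]
  pz <- direction[1L] * e2[, 2L] - direction[2L] * e2[, 1L]
  det <- e1[, 1L] * px + e1[, 2L] * py + e1[, 3L] * pz
  ok <- abs(det) >= 1e-12
  if (length(mesh$degenerate_faces) > 0L) ok[mesh$degenerate_faces] <- FALSE

  tx <- origin[1L] - a[, 1L]
  ty <- origin[2L] - a[, 2L]
  tz <- origin[3L] - a[, 3L]
  inv_det <- ifelse(ok, 1 / det, NA_real_)
  u <- (tx * px + ty * py + tz * pz) * inv_det
  ok <- ok & !is.na(u) & u >= -1e-12 & u <= 1 + 1e-12

  qx <- ty * e1[, 3L] - tz * e1[, 2L]
  qy <- tz * e1[, 1L] - tx * e1[, 3L]
  qz <- tx * e1[, 2L] - ty * e1[, 1L]
  vv <- (direction[1L] * qx + direction[2L] * qy + direction[3L] * qz) * inv_det
  ok <- ok & !is.na(vv) & vv >= -1e-12 & (u + vv) <= 1 + 1e-12

  tt <- (e2[, 1L] * qx + e2[, 2L] * qy + e2[, 3L] * qz) * inv_det
  ok <- ok & !is.na(tt) & tt > T_EPS
  if (!any(ok)) return(NULL)

  cand <- which(ok)
  best <- cand[which.min(tt[cand])]
  list(t = tt[best],
       point = origin + tt[best] * direction,
       barycentric = c(1 - u[best] - vv[best], u[best], vv[best]),
       face_index = best)
}

#' Cast an outward ray to the labyrinth surface
#'
#' From the centerline anchor, casts a ray along the *negative* insertion
#' direction (outward through the round-window region, the direction from
#' which the drill approaches) and returns the nearest surface hit, which is
#' the cochleostomy target. For closed shells with an inner and outer wall
#' layer the first hit is the inner (endosteal) surface.
#'
#' @param anchor point on the centerline (world mm).
#' @param insertion_dir unit insertion direction (world frame, toward
#'   increasing basal angle).
#' @param mesh the labyrinth [surface_mesh()] (world frame).
#' @return A list with `target` (world mm), `face_index` and `exit_distance`
#'   (mm), plus the hit `barycentric` coordinates.
#' @export
cast_to_surface <- function(anchor, insertion_dir, mesh) {
  anchor <- as_point3(anchor, "anchor")
  insertion_dir <- normalize(as_point3(insertion_dir, "insertion_dir"))
  stopifnot(inherits(mesh, "surface_mesh"))
  hit <- ray_mesh_first_hit(anchor, -insertion_dir, mesh)
  if (is.null(hit)) stop("trajectory does not exit through the surface")
  list(target = hit$point, face_index = hit$face_index,
       exit_distance = hit$t, barycentric = hit$barycentric)
}

#' Sweep cochleostomy angles and compute insertion trajectories
#'
#' For each cochleostomy angle `theta_c` on the grid `theta_step,
#' 2 * theta_step, ..., theta_max` (10 entries at the defaults of 2 and 20
#' degrees), takes the centerline tangent as the ideal insertion trajectory
#' and locates the cochleostomy target on the mesh with [cast_to_surface()].
#' `theta_c = 0` is excluded: that is the round window itself, not a
#' cochleostomy site.
#'
#' @param spline the [fit_centerline()] result (local frame).
#' @param mesh the labyrinth [surface_mesh()] (world frame).
#' @param frame the [build_cochlear_frame()] linking the two.
#' @param theta_step sweep step in degrees (default 2).
#' @param theta_max maximum cochleostomy angle in degrees (default 20).
#' @return A list of `insertion_trajectory` objects ordered by `theta_c`,
#'   each with fields `theta_c`, `anchor`, `insertion_dir`, `target` (all
#'   world mm), `face_index`, `exit_distance` and `barycentric`. Angles whose
#'   outward ray fails to exit the surface are omitted with a warning.
#' @export
plan_targets <- function(spline, mesh, frame, theta_step = 2, theta_max = 20) {
  stopifnot(inherits(spline, "centerline_spline"), inherits(mesh, "surface_mesh"))
  validate_cochlear_frame(frame)
  if (theta_step <= 0 || theta_max < theta_step) {
    stop("need 0 < theta_step <= theta_max")
  }
  grid <- seq(theta_step, theta_max, by = theta_step)
  check_spline_domain(spline, grid)

  plan <- list()
  for (theta_c in grid) {
    anchor_local <- spline_point(spline, theta_c)
    dir_local <- spline_tangent(spline, theta_c)
    anchor <- local_to_world(anchor_local, frame)
    insertion_dir <- dir_local_to_world(dir_local, frame)
    hit <- tryCatch(cast_to_surface(anchor, insertion_dir, mesh),
                    error = function(e) NULL)
    if (is.null(hit)) {
      warning(sprintf("theta_c = %g deg: trajectory does not exit the surface; omitted",
                      theta_c))
      next
    }
    plan[[length(plan) + 1L]] <- structure(
      list(theta_c = theta_c, anchor = anchor, insertion_dir = insertion_dir,
           target = hit$target, face_index = hit$face_index,
           exit_distance = hit$exit_distance, barycentric = hit$barycentric),
      class = "insertion_trajectory")
  }
  if (length(plan) == 0L) stop("no trajectory in the sweep exits the surface")
  plan
}

#' @export
print.insertion_trajectory <- function(x, ...) {
  cat(sprintf("Insertion trajectory at theta_C = %g deg\n", x$theta_c))
  cat(sprintf("  anchor (world mm): (%.3f, %.3f, %.3f)\n",
              x$anchor[1], x$anchor[2], x$anchor[3]))
  cat(sprintf("  insertion dir:     (%.4f, %.4f, %.4f)\n",
              x$insertion_dir[1], x$insertion_dir[2], x$insertion_dir[3]))
  cat(sprintf("  cochleostomy target: (%.3f, %.3f, %.3f) on face %d, exit %.3f mm\n",
              x$target[1], x$target[2], x$target[3], x$face_index, x$exit_distance))
  invisible(x)
}

#' Convert a trajectory plan to a data frame
#'
#' @param plan list of `insertion_trajectory` objects.
#' @return A data frame with one row per trajectory (theta_c, anchor, the
#'   insertion direction, target, face index and exit distance).
#' @export
plan_to_data_frame <- function(plan) {
  do.call(rbind, lapply(plan, function(tr) {
    data.frame(theta_c = tr$theta_c,
               anchor_x = tr$anchor[1L], anchor_y = tr$anchor[2L], anchor_z = tr$anchor[3L],
               dir_x = tr$insertion_dir[1L], dir_y = tr$insertion_dir[2L],
               dir_z = tr$insertion_dir[3L],
               target_x = tr$target[1L], target_y = tr$target[2L], target_z = tr$target[3L],
               face_index = tr$face_index, exit_distance = tr$exit_distance)
  }))
}
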