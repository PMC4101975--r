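# Synthetic cochlear phantom: a helico-spiral scala tympani tube with an
# analytic centerline, landmarks placed by construction, an analytic
# basilar-membrane point set and optional distractor structures. The phantom
# is built to satisfy the two modelling assumptions of the planning pipeline
# exactly at zero noise: the membrane lies in the z = 0 plane of the basal
# half turn, and the tube diameter equals the landmark distance |R - I| —
# so recovery errors measure the pipeline, not the phantom.

#' Specify a synthetic cochlear phantom
#'
#' The scala tympani centerline is a logarithmic spiral
#' `c(theta) = (rho(theta) cos(theta), rho(theta) sin(theta), z(theta))` with
#' `rho(theta) = a exp(-b theta)`. The basal half turn (theta <= 180 deg) is
#' near-planar: the tube center stays at constant depth
#' `-center_depth * tube_radius` below the membrane plane z = 0, so the top
#' of the tube pokes just above the plane and the membrane (the tube cap at
#' z = 0) is planar by construction. Beyond 180 degrees the centerline rises
#' with the given pitch. The tube radius tapers linearly toward the apex.
#'
#' @param base_radius spiral radius `a` at theta = 0 (mm, default 3).
#' @param radius_decay decay rate `b` per degree; default chosen so that
#'   `rho(360) = 0.6 * a`.
#' @param pitch vertical rise per turn for theta > 180 deg (mm, default 2.2).
#'   The default is the smallest round value for which the ascending turns
#'   clear the membrane plane z = 0 everywhere (tube bottom above the plane
#'   wherever the wrapped basal angle lies in the truncation half-space), so
#'   that only basal-ST surface can satisfy y > 0, z < 0.
#' @param tube_radius tube radius at the base (mm, default 0.6).
#' @param taper fractional linear reduction of the tube radius at the apex
#'   (default 0.5: apex tube radius is half the basal one).
#' @param turns total spiral extent in turns (default 2.5).
#' @param angular_resolution ring spacing along the spiral (deg, default 2).
#' @param circumferential_resolution vertices per ring (default 24).
#' @param center_depth tube-center depth below z = 0 for the basal half
#'   turn, as a fraction of `tube_radius` (default 0.8).
#' @param noise_sd isotropic Gaussian vertex noise (mm, default 0).
#' @param include_distractors add a vestibule-like blob at positive z (which
#'   the truncation rule must remove) and a small coplanar blob at negative z
#'   (which the width filter must remove).
#' @param side `"right"` (default) or `"left"`; a left phantom is the mirror
#'   image across the x-z plane.
#' @param seed RNG seed for the vertex noise.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(base_radius = 3.0,
                         radius_decay = log(1 / 0.6) / 360,
                         pitch = 2.2,
                         tube_radius = 0.6,
                         taper = 0.5,
                         turns = 2.5,
                         angular_resolution = 2,
                         circumferential_resolution = 24,
                         center_depth = 0.8,
                         noise_sd = 0,
                         include_distractors = FALSE,
                         side = c("right", "left"),
                         seed = 1L) {
  side <- match.arg(side)
  spec <- structure(
    list(base_radius = base_radius, radius_decay = radius_decay, pitch = pitch,
         tube_radius = tube_radius, taper = taper, turns = turns,
         angular_resolution = angular_resolution,
         circumferential_resolution = circumferential_resolution,
         center_depth = center_depth, noise_sd = noise_sd,
         include_distractors = include_distractors, side = side,
         seed = as.integer(seed)),
    class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  with(spec, {
    if (base_radius <= 0 || tube_radius <= 0) stop("radii must be positive")
    if (turns <= 0.5) stop("need more than half a turn")
    if (taper < 0 || taper >= 1) stop("taper must be in [0, 1)")
    if (center_depth <= 0 || center_depth >= 1) stop("center_depth must be in (0, 1)")
    if (angular_resolution <= 0 || circumferential_resolution < 8) {
      stop("resolutions too coarse")
    }
    if (noise_sd < 0) stop("noise_sd must be >= 0")
    theta <- seq(0, turns * 360, by = angular_resolution)
    rho <- base_radius * exp(-radius_decay * theta)
    r_tube <- tube_radius * (1 - taper * theta / (turns * 360))
    if (any(r_tube >= rho)) {
      stop("spec invariant violated: tube radius reaches the spiral axis (r >= rho)")
    }
  })
  # the ascending turns must clear the membrane plane: no ring beyond
  # three-quarters of a turn may contain surface points with y > 0 and
  # z < 0, otherwise non-basal tube surface wraps into basal-angle bins far
  # from its true position and contaminates the extracted cross sections.
  # (rings just past 180 deg are contiguous with the last basal section and
  # are exempt.) Ring points are c + r (cos(phi) N + sin(phi) B) with
  # B_z = 0, so z(phi) = z_c + r N_z cos(phi) and the test is a constrained
  # maximization of y over the phi arc where z < 0.
  theta <- seq(0, spec$turns * 360, by = spec$angular_resolution)
  asc <- theta[theta > 270]
  if (length(asc) > 0L) {
    rho <- phantom_rho(spec, asc)
    r_tube <- phantom_tube_r(spec, asc)
    z_center <- -spec$center_depth * spec$tube_radius +
      spec$pitch * (asc - 180) / 360
    tg <- phantom_tangent(spec, asc)
    B <- phantom_B(spec, asc)
    n_y <- -B[, 1L] * tg[, 3L]                       # (B x T)_y
    n_z <- B[, 1L] * tg[, 2L] - B[, 2L] * tg[, 1L]   # (B x T)_z
    c0 <- pmin(1, -z_center / (r_tube * n_z))        # z < 0 iff cos(phi) < c0
    A <- r_tube * n_y
    C <- r_tube * B[, 2L]
    M <- sqrt(A^2 + C^2)
    unconstrained <- A / pmax(M, 1e-300) <= c0
    y_max <- ifelse(unconstrained, M, A * c0 + abs(C) * sqrt(pmax(0, 1 - c0^2)))
    leaks <- c0 > -1 & rho * sin(deg2rad(asc)) + y_max > 0
    if (any(leaks)) {
      stop(paste0("spec invariant violated: ascending turns dip below the ",
                  "membrane plane inside the truncation half-space; ",
                  "increase pitch or reduce tube_radius/center_depth"))
    }
  }
  invisible(spec)
}

# Analytic centerline / radius / tangent helpers, right-ear orientation.
phantom_rho <- function(spec, theta) spec$base_radius * exp(-spec$radius_decay * theta)

phantom_tube_r <- function(spec, theta) {
  spec$tube_radius * (1 - spec$taper * theta / (spec$turns * 360))
}

phantom_z <- function(spec, theta) {
  z0 <- -spec$center_depth * spec$tube_radius
  ifelse(theta <= 180, z0, z0 + spec$pitch * (theta - 180) / 360)
}

phantom_centerline <- function(spec, theta) {
  rho <- phantom_rho(spec, theta)
  th <- deg2rad(theta)
  cbind(rho * cos(th), rho * sin(th), phantom_z(spec, theta))
}

# Unit tangent with respect to increasing theta (derivative per radian).
phantom_tangent <- function(spec, theta) {
  rho <- phantom_rho(spec, theta)
  th <- deg2rad(theta)
  k <- spec$radius_decay * 180 / pi         # d(rho)/d(theta_rad) = -k * rho
  dz <- ifelse(theta <= 180, 0, spec$pitch / (2 * pi))
  d <- cbind(-k * rho * cos(th) - rho * sin(th),
             -k * rho * sin(th) + rho * cos(th),
             dz)
  d / row_norms(d)
}

# Small UV-sphere mesh used for distractor blobs.
uv_sphere <- function(center, radius, stacks, slices) {
  verts <- matrix(c(0, 0, radius), nrow = 1L)
  for (i in seq_len(stacks - 1L)) {
    phi <- pi * i / stacks
    psi <- 2 * pi * (seq_len(slices) - 1L) / slices
    verts <- rbind(verts, cbind(radius * sin(phi) * cos(psi),
                                radius * sin(phi) * sin(psi),
                                radius * cos(phi)))
  }
  verts <- rbind(verts, c(0, 0, -radius))
  n <- nrow(verts)
  ring <- function(i) 1L + (i - 1L) * slices + seq_len(slices)
  faces <- NULL
  r1 <- ring(1L)
  faces <- rbind(faces, cbind(1L, r1, c(r1[-1L], r1[1L])))
  if (stacks > 2L) {
    for (i in seq_len(stacks - 2L)) {
      ra <- ring(i); rb <- ring(i + 1L)
      ra2 <- c(ra[-1L], ra[1L]); rb2 <- c(rb[-1L], rb[1L])
      faces <- rbind(faces, cbind(ra, rb, rb2), cbind(ra, rb2, ra2))
    }
  }
  rl <- ring(stacks - 1L)
  faces <- rbind(faces, cbind(n, c(rl[-1L], rl[1L]), rl))
  list(vertices = sweep(verts, 2L, center, FUN = "+"), faces = faces)
}

#' Generate a synthetic cochlear phantom
#'
#' Meshes a tube of radius `tube_radius` (linearly tapered) around the
#' analytic spiral centerline, closes both ends, places the four landmarks by
#' construction and returns the analytic ground truth. Landmarks: `C` at the
#' origin (basal modiolus), `A` on the modiolar axis at the apex height, `R`
#' at the membrane level directly above the basal end of the centerline, and
#' `I` one tube diameter inward of `R` — so the landmark width |R - I|
#' equals the ST width `2 * tube_radius` and the frame built from these
#' landmarks reproduces the membrane plane z = 0 exactly at zero noise.
#'
#' @param spec a [phantom_spec()].
#' @return A list with `mesh` (a [surface_mesh()]), `landmarks` (a
#'   [landmark_set()]) and `truth`: list with `centerline(theta)` and
#'   `tangent(theta)` functions (world frame, theta in degrees),
#'   `membrane_points` (world mm, basal half turn), `st_membership` (logical
#'   per mesh vertex: basal-ST tube surface or not) and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  validate_phantom_spec(spec)
  set.seed(spec$seed)

  theta_max <- spec$turns * 360
  theta <- seq(0, theta_max, by = spec$angular_resolution)
  m <- length(theta)
  nc <- spec$circumferential_resolution

  centers <- phantom_centerline(spec, theta)
  tangents <- phantom_tangent(spec, theta)
  r_tube <- phantom_tube_r(spec, theta)

  # ring frame: B = T x z_hat (horizontal), N = B x T (= z_hat on the basal
  # half turn where the tangent is horizontal)
  up <- c(0, 0, 1)
  Bv <- cbind(tangents[, 2L], -tangents[, 1L], 0)  # T x up
  Bv <- Bv / row_norms(Bv)
  Nv <- cbind(Bv[, 2L] * tangents[, 3L] - Bv[, 3L] * tangents[, 2L],
              Bv[, 3L] * tangents[, 1L] - Bv[, 1L] * tangents[, 3L],
              Bv[, 1L] * tangents[, 2L] - Bv[, 2L] * tangents[, 1L])

  phi <- 2 * pi * (seq_len(nc) - 1L) / nc
  verts <- matrix(0, nrow = m * nc, ncol = 3L)
  for (i in seq_len(m)) {
    ring <- centers[rep(i, nc), ] +
      r_tube[i] * (cos(phi) %o% Nv[i, ] + sin(phi) %o% Bv[i, ])
    verts[(i - 1L) * nc + seq_len(nc), ] <- ring
  }
  vertex_theta <- rep(theta, each = nc)

  # tube quads -> triangles
  faces <- NULL
  i0 <- rep(seq_len(m - 1L), each = nc)
  j0 <- rep(seq_len(nc), times = m - 1L)
  j1 <- ifelse(j0 == nc, 1L, j0 + 1L)
  a <- (i0 - 1L) * nc + j0
  b <- (i0 - 1L) * nc + j1
  cc <- i0 * nc + j1
  d <- i0 * nc + j0
  faces <- rbind(cbind(a, b, cc), cbind(a, cc, d))

  # end caps
  verts <- rbind(verts, centers[1L, ], centers[m, ])
  vertex_theta <- c(vertex_theta, theta[1L], theta[m])
  cap0 <- nrow(verts) - 1L
  cap1 <- nrow(verts)
  r0 <- seq_len(nc)
  r0n <- c(r0[-1L], r0[1L])
  faces <- rbind(faces, cbind(cap0, r0n, r0))
  rl <- (m - 1L) * nc + seq_len(nc)
  rln <- c(rl[-1L], rl[1L])
  faces <- rbind(faces, cbind(cap1, rl, rln))

  st_membership <- vertex_theta <= 180

  if (spec$include_distractors) {
    # vestibule-like blob entirely at positive z: the truncation rule must
    # remove it
    vest <- uv_sphere(center = c(2.0, 1.0, 1.5), radius = 1.2,
                      stacks = 6L, slices = 8L)
    # small coplanar blob below the membrane plane, radially outside the
    # basal turn at theta ~ 100 deg: only the width filter can remove it.
    # Placed 3.5 mm outside the ST wall: well beyond the |R - I| width bound
    # from the section centroid, but close enough that the blob's pull on
    # the initial centroid cannot push genuine tube points past the trim
    # radius
    ang <- deg2rad(100)
    cop_center <- c((phantom_rho(spec, 100) + 3.5) * cos(ang),
                    (phantom_rho(spec, 100) + 3.5) * sin(ang), -0.3)
    cop <- uv_sphere(center = cop_center, radius = 0.2, stacks = 2L, slices = 4L)
    for (blob in list(vest, cop)) {
      off <- nrow(verts)
      verts <- rbind(verts, blob$vertices)
      faces <- rbind(faces, blob$faces + off)
      st_membership <- c(st_membership, rep(FALSE, nrow(blob$vertices)))
    }
  }

  if (spec$noise_sd > 0) {
    verts <- verts + matrix(stats::rnorm(length(verts), sd = spec$noise_sd),
                            ncol = 3L)
  }

  # membrane ground truth: tube cap at z = 0 over the basal half turn
  th_mem <- theta[theta <= 180]
  cosphi <- (spec$center_depth * spec$tube_radius) / phantom_tube_r(spec, th_mem)
  phi_m <- acos(pmin(1, cosphi))
  cm <- phantom_centerline(spec, th_mem)
  rm <- phantom_tube_r(spec, th_mem)
  Bm <- phantom_B(spec, th_mem)
  s <- rm * sin(phi_m)                       # in-plane offset along B
  zo <- -spec$center_depth * spec$tube_radius + rm * cos(phi_m)  # = 0 exactly
  mem <- rbind(
    cbind(cm[, 1L] + s * Bm[, 1L], cm[, 2L] + s * Bm[, 2L], zo),
    cbind(cm[, 1L] - s * Bm[, 1L], cm[, 2L] - s * Bm[, 2L], zo))

  mirror <- spec$side == "left"
  flip_y <- function(p) {
    p[, 2L] <- -p[, 2L]
    p
  }
  if (mirror) {
    verts <- flip_y(verts)
    mem <- flip_y(mem)
  }

  landmarks <- landmark_set(
    R = c(phantom_rho(spec, 0), 0, 0),
    C = c(0, 0, 0),
    A = c(0, 0, phantom_z(spec, theta_max)),
    I = c(phantom_rho(spec, 0) - 2 * spec$tube_radius, 0, 0),
    side = spec$side)

  truth_centerline <- function(th) {
    p <- phantom_centerline(spec, th)
    if (mirror) flip_y(p) else p
  }
  truth_tangent <- function(th) {
    d <- phantom_tangent(spec, th)
    if (mirror) flip_y(d) else d
  }

  mesh <- surface_mesh(verts, faces,
                       provenance = sprintf("phantom(seed=%d, side=%s)",
                                            spec$seed, spec$side))
  list(mesh = mesh,
       landmarks = landmarks,
       truth = list(centerline = truth_centerline,
                    tangent = truth_tangent,
                    tube_radius = function(th) phantom_tube_r(spec, th),
                    membrane_points = mem,
                    st_membership = st_membership,
                    vertex_theta = vertex_theta,
                    spec = spec))
}

# horizontal binormal at theta (right-ear orientation), vectorized
phantom_B <- function(spec, theta) {
  tg <- phantom_tangent(spec, theta)
  B <- cbind(tg[, 2L], -tg[, 1L], 0)
  B / row_norms(B)
}

#' Run the full planning pipeline on a phantom and score it
#'
#' Generates the phantom, runs frame construction, truncation, cross-section
#' binning, spline fitting and the cochleostomy sweep, and compares the
#' result against the analytic ground truth.
#'
#' @param spec a [phantom_spec()].
#' @param config a [plan_config()].
#' @param eval_step grid spacing (deg) for centerline error evaluation.
#' @return A list with `centerline_mean_error_mm` / `centerline_max_error_mm`
#'   (distance from the fitted spline to the analytic centerline curve),
#'   `tangent_max_error_deg` (angular tangent error over the cochleostomy
#'   sweep angles), `target_surface_residual_mm` (largest distance of any
#'   cochleostomy target from the analytic tube surface), `n_sections`,
#'   `n_trajectories` and the full `result` of [plan_cochleostomy()].
#' @export
end_to_end_recovery <- function(spec, config = plan_config(), eval_step = 1) {
  ph <- generate_phantom(spec)
  res <- plan_cochleostomy(ph$mesh, ph$landmarks, config)

  # dense sample of the analytic curve for point-to-curve distances
  th_dense <- seq(-10, 200, by = 0.1)
  curve <- ph$truth$centerline(th_dense)
  r_dense <- ph$truth$tube_radius(pmax(th_dense, 0))

  th_eval <- seq(res$spline$domain[1L], res$spline$domain[2L], by = eval_step)
  pts_local <- spline_point(res$spline, th_eval)
  pts_world <- local_to_world(pts_local, res$frame)
  d2 <- outer(rowSums(pts_world^2), rep(1, nrow(curve))) -
    2 * pts_world %*% t(curve) +
    outer(rep(1, nrow(pts_world)), rowSums(curve^2))
  dmin <- sqrt(pmax(apply(d2, 1L, min), 0))

  sweep_theta <- vapply(res$plan, `[[`, numeric(1), "theta_c")
  tan_fit <- t(vapply(sweep_theta, function(th) {
    dir_local_to_world(spline_tangent(res$spline, th), res$frame)
  }, numeric(3)))
  tan_true <- ph$truth$tangent(sweep_theta)
  cosang <- pmin(1, pmax(-1, rowSums(tan_fit * tan_true)))
  tangent_err <- rad2deg(acos(cosang))

  # distance of a target to the analytic surface: the tube wall
  # (|distance to centerline - tube radius|) or the flat end cap at
  # theta = 0 (a disk of radius r(0) centered at c(0), normal = tangent),
  # whichever is closer
  cap_center <- as.vector(ph$truth$centerline(0))
  cap_normal <- as.vector(ph$truth$tangent(0))
  cap_r <- ph$truth$tube_radius(0)
  dist_to_cap <- function(p) {
    w <- p - cap_center
    h <- sum(w * cap_normal)
    radial <- vec_norm(w - h * cap_normal)
    sqrt(h^2 + max(0, radial - cap_r)^2)
  }
  target_resid <- vapply(res$plan, function(tr) {
    dt <- sqrt(colSums((t(curve) - tr$target)^2))
    j <- which.min(dt)
    min(abs(dt[j] - r_dense[j]), dist_to_cap(tr$target))
  }, numeric(1))

  list(centerline_mean_error_mm = mean(dmin),
       centerline_max_error_mm = max(dmin),
       tangent_max_error_deg = max(tangent_err),
       target_surface_residual_mm = max(target_resid),
       n_sections = length(res$sections),
       n_trajectories = length(res$plan),
       result = res)
}
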