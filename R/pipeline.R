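#' Planning configuration
#'
#' Bundles the tunable parameters of the planning pipeline: the angular bin
#' spacing of the radial cross sections (`delta_theta`, default 5 degrees),
#' the cochleostomy sweep step and maximum (`theta_step` 2 and `theta_max`
#' 20 degrees), the spline smoothing tolerance (`residual_tol`, default
#' 0.05 mm) and optionally the ear side override.
#'
#' @param delta_theta cross-section bin spacing, degrees (divisor of 180).
#' @param theta_step cochleostomy sweep step, degrees.
#' @param theta_max maximum cochleostomy angle, degrees.
#' @param residual_tol spline smoothing residual tolerance, mm.
#' @param side optional ear side override (`"left"`, `"right"`, `"auto"`);
#'   `NULL` keeps the side stored in the landmark file.
#' @param seed optional RNG seed recorded in the config (the planning
#'   pipeline itself is deterministic).
#' @return An object of class `plan_config`.
#' @export
plan_config <- function(delta_theta = 5, theta_step = 2, theta_max = 20,
                        residual_tol = 0.05, side = NULL, seed = NULL) {
  if (delta_theta <= 0 || theta_step <= 0 || residual_tol < 0) {
    stop("delta_theta and theta_step must be positive, residual_tol >= 0")
  }
  if (!(theta_step <= theta_max && theta_max <= 180)) {
    stop("need theta_step <= theta_max <= 180")
  }
  if (!is.null(side)) side <- match.arg(side, c("left", "right", "auto"))
  structure(list(delta_theta = delta_theta, theta_step = theta_step,
                 theta_max = theta_max, residual_tol = residual_tol,
                 side = side, seed = seed),
            class = "plan_config")
}

#' Run the full cochleostomy planning pipeline
#'
#' Chains the planning stages: build the local cochlear frame from the
#' landmarks, transform the mesh vertices into it, truncate to the basal
#' scala tympani (positive y, negative z), bin radial cross sections with
#' the width filter, fit the smoothed centerline spline, and sweep the
#' cochleostomy angles to locate targets on the mesh.
#'
#' @param mesh the labyrinth [surface_mesh()] (world mm).
#' @param landmarks a [landmark_set()] in the same frame.
#' @param config a [plan_config()].
#' @return An object of class `st_plan`: list with `frame`, `sections`,
#'   `spline`, `plan` (list of `insertion_trajectory`) and `counts` (points
#'   surviving each filter stage).
#' @export
plan_cochleostomy <- function(mesh, landmarks, config = plan_config()) {
  stopifnot(inherits(mesh, "surface_mesh"), inherits(landmarks, "landmark_set"),
            inherits(config, "plan_config"))
  if (!is.null(config$side) && config$side != landmarks$side) {
    landmarks <- landmark_set(landmarks$R, landmarks$C, landmarks$A,
                              landmarks$I, side = config$side)
  }
  frame <- build_cochlear_frame(landmarks, st_hint_points = mesh$vertices)
  vlocal <- world_to_local(mesh$vertices, frame)
  trunc <- truncate_to_basal_st(vlocal)
  sections <- bin_cross_sections(trunc, delta_theta = config$delta_theta,
                                 st_width = frame$st_width)
  spline <- fit_centerline(sections, residual_tol = config$residual_tol)
  plan <- plan_targets(spline, mesh, frame,
                       theta_step = config$theta_step,
                       theta_max = config$theta_max)
  counts <- list(
    n_vertices = nrow(mesh$vertices),
    n_after_truncation = nrow(trunc),
    n_in_sections = sum(vapply(sections, function(s) length(s$member_indices),
                               integer(1))),
    n_removed_by_width = sum(vapply(sections, `[[`, integer(1),
                                    "n_removed_by_width")),
    n_sections = length(sections),
    n_trajectories = length(plan))
  structure(list(frame = frame, sections = sections, spline = spline,
                 plan = plan, counts = counts, config = config),
            class = "st_plan")
}

#' @export
print.st_plan <- function(x, ...) {
  cat("Scala tympani cochleostomy plan\n")
  with(x$counts, {
    cat(sprintf("  vertices: %d -> %d after truncation; %d in %d sections (%d removed by width filter)\n",
                n_vertices, n_after_truncation, n_in_sections, n_sections,
                n_removed_by_width))
  })
  cat(sprintf("  spline: theta in [%g, %g] deg, max residual %.4g mm\n",
              x$spline$domain[1L], x$spline$domain[2L], x$spline$max_residual))
  cat(sprintf("  %d trajectories at theta_C = %s deg\n",
              length(x$plan),
              paste(vapply(x$plan, `[[`, numeric(1), "theta_c"), collapse = ", ")))
  invisible(x)
}
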