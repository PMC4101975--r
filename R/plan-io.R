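# JSON plan files and CSV section export.

PLAN_SCHEMA_VERSION <- "1.0"

#' Write an insertion plan to JSON
#'
#' Serializes a list of insertion trajectories (see [plan_targets()])
#' together with the cochlear frame that produced them. Per trajectory the
#' file records the cochleostomy angle `theta_c` (degrees), the centerline
#' anchor point (world mm), the insertion direction (world unit vector, from
#' cochleostomy toward deeper angles), the cochleostomy target on the mesh
#' (world mm), the hit face index (1-based) and the exit distance (mm).
#'
#' @param plan a non-empty list of `insertion_trajectory` objects.
#' @param frame the [build_cochlear_frame()] used for planning.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_plan <- function(plan, frame, path) {
  if (length(plan) == 0L) stop("nothing to write: empty plan")
  stopifnot(all(vapply(plan, inherits, logical(1), "insertion_trajectory")))
  validate_cochlear_frame(frame)
  obj <- list(
    schema = "cochleoplan-plan",
    schema_version = PLAN_SCHEMA_VERSION,
    frame = list(
      origin = frame$origin,
      x_axis = frame$x_axis, y_axis = frame$y_axis, z_axis = frame$z_axis,
      handedness = frame$handedness, st_width = frame$st_width),
    trajectories = lapply(plan, function(tr) {
      list(theta_c = tr$theta_c, anchor = tr$anchor,
           insertion_dir = tr$insertion_dir, target = tr$target,
           face_index = tr$face_index, exit_distance = tr$exit_distance)
    }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an insertion plan from JSON
#'
#' @param path a file written by [write_plan()].
#' @return A list with `frame` (a `cochlear_frame`) and `plan` (list of
#'   `insertion_trajectory` objects).
#' @export
read_plan <- function(path) {
  if (!file.exists(path)) stop(sprintf("plan file not found: %s", path))
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  if (!identical(obj$schema, "cochleoplan-plan")) {
    stop(sprintf("'%s' is not a cochleoplan plan file", path))
  }
  fr <- obj$frame
  frame <- structure(
    list(origin = as.numeric(fr$origin),
         x_axis = as.numeric(fr$x_axis),
         y_axis = as.numeric(fr$y_axis),
         z_axis = as.numeric(fr$z_axis),
         rotation = cbind(as.numeric(fr$x_axis), as.numeric(fr$y_axis),
                          as.numeric(fr$z_axis), deparse.level = 0),
         handedness = fr$handedness,
         st_width = fr$st_width,
         side = if (is.null(fr$side)) "auto" else fr$side),
    class = "cochlear_frame")
  plan <- lapply(obj$trajectories, function(tr) {
    structure(
      list(theta_c = tr$theta_c,
           anchor = as.numeric(tr$anchor),
           insertion_dir = as.numeric(tr$insertion_dir),
           target = as.numeric(tr$target),
           face_index = tr$face_index,
           exit_distance = tr$exit_distance),
      class = "insertion_trajectory")
  })
  list(frame = frame, plan = plan)
}

#' Export cross sections to CSV
#'
#' Writes one row per radial cross section: `theta_deg`, `n_points`,
#' `n_removed_by_width` and the centroid coordinates in the local frame (mm).
#'
#' @param sections list of `cross_section` objects from
#'   [bin_cross_sections()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_sections_csv <- function(sections, path) {
  df <- sections_to_data_frame(sections)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

sections_to_data_frame <- function(sections) {
  data.frame(
    theta_deg = vapply(sections, `[[`, numeric(1), "theta"),
    n_points = vapply(sections, function(s) length(s$member_indices), integer(1)),
    n_removed_by_width = vapply(sections, `[[`, integer(1), "n_removed_by_width"),
    centroid_x = vapply(sections, function(s) s$centroid[1L], numeric(1)),
    centroid_y = vapply(sections, function(s) s$centroid[2L], numeric(1)),
    centroid_z = vapply(sections, function(s) s$centroid[3L], numeric(1)))
}
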