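#' Build the local cochlear coordinate system
#'
#' Constructs an orthonormal frame with its origin at the basal center of the
#' modiolus (`C`). The x-axis runs from `C` through the round-window landmark
#' `R` (so the round window sits at the 0-degree reference angle), and the
#' z-axis is the component of `(A - C)` orthogonal to the x-axis
#' (Gram-Schmidt), pointing toward the cochlear apex. The y-axis completes a
#' right-handed frame (`y = z x x`) and is flipped for left ears so that the
#' basal scala tympani always occupies positive local y; the flip is recorded
#' in `handedness`.
#'
#' The basilar membrane is modelled as the local x-y plane of this frame:
#' truncating the labyrinth surface to positive y and negative z isolates the
#' basal-turn scala tympani below the membrane.
#'
#' Orientation resolution: if `landmarks$side` is `"left"` or `"right"` the
#' flip is determined by the side alone. With `side = "auto"`,
#' `st_hint_points` must be supplied (typically all labyrinth mesh vertices);
#' the points within 2 mm of `R` are inspected and the y-axis is flipped when
#' fewer than half of them have positive local y.
#'
#' @param landmarks a [landmark_set()].
#' @param st_hint_points optional n x 3 matrix of labyrinth surface points
#'   (world mm) used to resolve orientation when `side = "auto"`.
#' @return An object of class `cochlear_frame` with fields `origin`,
#'   `x_axis`, `y_axis`, `z_axis` (unit vectors, world frame), `rotation`
#'   (3 x 3 matrix with the axes as columns), `handedness` (+1 or -1) and
#'   `st_width` (mm).
#' @examples
#' lm <- landmark_set(R = c(5, 0, 0), C = c(0, 0, 0),
#'                    A = c(0, 0, 4), I = c(4, 0, 0), side = "right")
#' fr <- build_cochlear_frame(lm)
#' world_to_local(lm$R, fr)  # (5, 0, 0)
#' @export
build_cochlear_frame <- function(landmarks, st_hint_points = NULL) {
  stopifnot(inherits(landmarks, "landmark_set"))
  validate_landmark_set(landmarks)

  x_axis <- normalize(landmarks$R - landmarks$C)
  ac <- landmarks$A - landmarks$C
  z_raw <- ac - sum(ac * x_axis) * x_axis
  z_axis <- normalize(z_raw)
  y_axis <- cross3(z_axis, x_axis)
  handedness <- 1

  flip <- switch(landmarks$side,
    right = FALSE,
    left  = TRUE,
    auto  = {
      if (is.null(st_hint_points)) {
        stop("side = 'auto' requires st_hint_points (labyrinth vertices) or an explicit side")
      }
      pts <- as_points_matrix(st_hint_points, "st_hint_points")
      d <- row_norms(sweep(pts, 2L, landmarks$R))
      near <- pts[d <= 2, , drop = FALSE]
      if (nrow(near) == 0L) {
        stop("no st_hint_points within 2 mm of R; supply an explicit side")
      }
      y_local <- as.vector(sweep(near, 2L, landmarks$C) %*% y_axis)
      mean(y_local > 0) < 0.5
    })
  if (flip) {
    y_axis <- -y_axis
    handedness <- -1
  }

  structure(
    list(origin = landmarks$C,
         x_axis = x_axis, y_axis = y_axis, z_axis = z_axis,
         rotation = cbind(x_axis, y_axis, z_axis, deparse.level = 0),
         handedness = handedness,
         st_width = landmarks$st_width,
         side = landmarks$side),
    class = "cochlear_frame")
}

validate_cochlear_frame <- function(frame) {
  if (!inherits(frame, "cochlear_frame")) stop("not a cochlear_frame")
  R <- frame$rotation
  if (max(abs(crossprod(R) - diag(3))) > 1e-9) stop("frame axes are not orthonormal")
  if (abs(abs(det(R)) - 1) > 1e-9) stop("frame rotation is not orthogonal")
  invisible(frame)
}

#' @export
print.cochlear_frame <- function(x, ...) {
  cat("Local cochlear coordinate system\n")
  cat(sprintf("  origin (C): (%.3f, %.3f, %.3f) mm\n",
              x$origin[1], x$origin[2], x$origin[3]))
  for (ax in c("x_axis", "y_axis", "z_axis")) {
    cat(sprintf("  %s: (%.4f, %.4f, %.4f)\n", ax, x[[ax]][1], x[[ax]][2], x[[ax]][3]))
  }
  cat(sprintf("  handedness: %+d; ST width: %.3f mm\n", x$handedness, x$st_width))
  invisible(x)
}

#' Transform points between world and local cochlear coordinates
#'
#' `world_to_local()` maps world points into the frame
#' (`p_local = t(rotation) %*% (p - origin)`); `local_to_world()` is the
#' exact inverse.
#'
#' @param points a length-3 point or n x 3 matrix.
#' @param frame a [build_cochlear_frame()] result.
#' @return Points in the same shape as the input.
#' @export
world_to_local <- function(points, frame) {
  validate_cochlear_frame(frame)
  single <- is.null(dim(points))
  p <- as_points_matrix(points, "points")
  out <- sweep(p, 2L, frame$origin) %*% frame$rotation
  if (single) as.vector(out) else out
}

#' @rdname world_to_local
#' @export
local_to_world <- function(points, frame) {
  validate_cochlear_frame(frame)
  single <- is.null(dim(points))
  p <- as_points_matrix(points, "points")
  out <- sweep(p %*% t(frame$rotation), 2L, frame$origin, FUN = "+")
  if (single) as.vector(out) else out
}

# Rotate a direction vector (no translation) into / out of the local frame.
dir_world_to_local <- function(d, frame) as.vector(d %*% frame$rotation)
dir_local_to_world <- function(d, frame) as.vector(frame$rotation %*% d)

#' Basal turn angle of local points
#'
#' The basal turn angle theta is the in-plane angle about the modiolar
#' (local z) axis, measured from the +x axis (the round window, theta = 0)
#' toward +y, in degrees in \[0, 360).
#'
#' @param points_local a length-3 point or n x 3 matrix in the local frame.
#' @return numeric vector of angles (degrees).
#' @export
basal_angle_of <- function(points_local) {
  p <- as_points_matrix(points_local, "points_local")
  r2 <- p[, 1L]^2 + p[, 2L]^2
  if (any(r2 <= 0)) stop("basal angle undefined for points on the z-axis")
  theta <- rad2deg(atan2(p[, 2L], p[, 1L]))
  theta %% 360
}
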