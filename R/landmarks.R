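#' Create a cochlear landmark set
#'
#' Bundles the four anatomical landmarks used to construct the local cochlear
#' coordinate system: the round-window center at the bony overhang (`R`), the
#' basal center of the modiolus (`C`), the apical center of the modiolus
#' (`A`) and the inner-wall border at the 0-degree reference angle (`I`).
#' All landmarks are 3D points in the same world frame, in millimetres.
#'
#' The distance between `R` and `I` is taken as an upper bound on the width
#' of the scala tympani in the basal turn and drives the per-section width
#' filter during centerline extraction.
#'
#' @param R,C,A,I numeric length-3 points (mm, world frame).
#' @param side ear side, one of `"left"`, `"right"` or `"auto"`. With
#'   `"auto"` the frame orientation is resolved from labyrinth vertices near
#'   the round window (see [build_cochlear_frame()]).
#' @return An object of class `landmark_set` with fields `R`, `C`, `A`, `I`,
#'   `side` and `st_width` (= |R - I|, mm).
#' @examples
#' lm <- landmark_set(R = c(5, 0, 0), C = c(0, 0, 0),
#'                    A = c(0, 0, 4), I = c(4, 0, 0), side = "right")
#' lm$st_width  # 1 mm
#' @export
landmark_set <- function(R, C, A, I, side = c("auto", "left", "right")) {
  side <- match.arg(side)
  R <- as_point3(R, "R"); C <- as_point3(C, "C")
  A <- as_point3(A, "A"); I <- as_point3(I, "I")
  lm <- structure(
    list(R = R, C = C, A = A, I = I, side = side,
         st_width = vec_norm(R - I)),
    class = "landmark_set")
  validate_landmark_set(lm)
  lm
}

# Invariants that make the frame constructible:
#  |R - C| > 0.5 mm, |A - C| > 0.5 mm, angle(R - C, A - C) >= 10 deg,
#  |R - I| > 0.
validate_landmark_set <- function(lm) {
  rc <- lm$R - lm$C
  ac <- lm$A - lm$C
  if (vec_norm(rc) < .Machine$double.eps) stop("degenerate landmarks: R and C coincide")
  if (vec_norm(lm$R - lm$I) <= 0) stop("degenerate landmarks: R and I coincide (|R - I| must be > 0)")
  if (vec_norm(rc) <= 0.5) stop("degenerate landmarks: |R - C| must exceed 0.5 mm")
  if (vec_norm(ac) <= 0.5) stop("degenerate landmarks: |A - C| must exceed 0.5 mm")
  ang <- rad2deg(acos(max(-1, min(1, sum(normalize(rc) * normalize(ac))))))
  if (ang < 10) {
    stop(sprintf(
      "degenerate landmarks: angle between (R - C) and (A - C) is %.2f deg (must be >= 10 deg)",
      ang))
  }
  invisible(lm)
}

#' @export
print.landmark_set <- function(x, ...) {
  cat("Cochlear landmark set (mm, world frame)\n")
  for (k in c("R", "C", "A", "I")) {
    cat(sprintf("  %s: (%.3f, %.3f, %.3f)\n", k, x[[k]][1], x[[k]][2], x[[k]][3]))
  }
  cat(sprintf("  side: %s; ST width |R - I|: %.3f mm\n", x$side, x$st_width))
  invisible(x)
}

#' Read cochlear landmarks from a JSON file
#'
#' The file must be a JSON object with keys `"R"`, `"C"`, `"A"`, `"I"` (each
#' a numeric 3-array, mm, world frame) and an optional `"side"` field
#' (`"left"`, `"right"` or `"auto"`).
#'
#' @param path path to the JSON file.
#' @return A [landmark_set()].
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) stop(sprintf("landmark file not found: %s", path))
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  for (k in c("R", "C", "A", "I")) {
    if (is.null(obj[[k]])) stop(sprintf("landmark file is missing key '%s'", k))
    if (!is.numeric(obj[[k]]) || length(obj[[k]]) != 3L) {
      stop(sprintf("landmark '%s' must be a numeric 3-array", k))
    }
  }
  side <- if (is.null(obj$side)) "auto" else obj$side
  landmark_set(R = obj$R, C = obj$C, A = obj$A, I = obj$I, side = side)
}

#' Write cochlear landmarks to a JSON file
#'
#' @param landmarks a [landmark_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(landmarks, path) {
  stopifnot(inherits(landmarks, "landmark_set"))
  obj <- list(R = landmarks$R, C = landmarks$C, A = landmarks$A,
              I = landmarks$I, side = landmarks$side)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
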