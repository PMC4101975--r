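#' Create a triangulated surface mesh
#'
#' A lightweight triangle-soup container for segmented labyrinth surfaces:
#' vertices in millimetres (any world frame) and 1-based triangular face
#' indices. Face winding is not normalized; all downstream ray/triangle
#' operations are winding-agnostic. Zero-area (degenerate) triangles are
#' flagged but kept, so face indices remain stable.
#'
#' @param vertices n x 3 numeric matrix (mm).
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @param provenance free-text label recording where the mesh came from.
#' @return An object of class `surface_mesh` with fields `vertices`, `faces`,
#'   `provenance` and `degenerate_faces` (indices of zero-area triangles).
#' @export
surface_mesh <- function(vertices, faces, provenance = "unknown") {
  vertices <- as_points_matrix(vertices, "vertices")
  faces <- as.matrix(faces)
  if (ncol(faces) != 3L) stop("faces must have 3 columns")
  storage.mode(faces) <- "integer"
  if (nrow(vertices) == 0L || nrow(faces) == 0L) stop("empty mesh (no vertices or no faces)")
  if (any(faces < 1L) || any(faces > nrow(vertices))) {
    stop(sprintf("face indices out of range [1, %d]", nrow(vertices)))
  }
  dimnames(faces) <- NULL

  a <- vertices[faces[, 1L], , drop = FALSE]
  e1 <- vertices[faces[, 2L], , drop = FALSE] - a
  e2 <- vertices[faces[, 3L], , drop = FALSE] - a
  nx <- e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L]
  ny <- e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L]
  nz <- e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L]
  area2 <- sqrt(nx^2 + ny^2 + nz^2)
  degenerate <- which(area2 < 1e-12)
  if (length(degenerate) > 0L) {
    warning(sprintf("mesh contains %d degenerate (zero-area) face(s)", length(degenerate)))
  }

  structure(
    list(vertices = vertices, faces = faces, provenance = provenance,
         degenerate_faces = degenerate),
    class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("Surface mesh: %d vertices, %d faces (%d degenerate)\n",
              nrow(x$vertices), nrow(x$faces), length(x$degenerate_faces)))
  cat(sprintf("  provenance: %s\n", x$provenance))
  bb <- apply(x$vertices, 2L, range)
  cat(sprintf("  bounds (mm): x [%.2f, %.2f], y [%.2f, %.2f], z [%.2f, %.2f]\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  invisible(x)
}

# TRUE when every edge is shared by exactly two faces (closed 2-manifold).
is_watertight <- function(mesh) {
  f <- mesh$faces
  edges <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
  key <- paste(pmin(edges[, 1L], edges[, 2L]), pmax(edges[, 1L], edges[, 2L]))
  all(table(key) == 2L)
}

# Apply a rigid transform (rotation Q, translation t) to a mesh.
transform_mesh <- function(mesh, Q, t = c(0, 0, 0)) {
  v <- sweep(mesh$vertices %*% t(Q), 2L, t, FUN = "+")
  surface_mesh(v, mesh$faces, provenance = mesh$provenance)
}
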