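# Internal vector/matrix helpers shared across modules. All coordinates are
# millimetres; points are length-3 numeric vectors or n x 3 matrices.

vec_norm <- function(v) sqrt(sum(v * v))

normalize <- function(v) {
  n <- vec_norm(v)
  if (n < .Machine$double.eps) stop("cannot normalize a zero-length vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

# Coerce a point argument to a length-3 numeric vector.
as_point3 <- function(p, name = deparse(substitute(p))) {
  p <- as.numeric(p)
  if (length(p) != 3L || any(!is.finite(p))) {
    stop(sprintf("'%s' must be a finite 3D point", name))
  }
  p
}

# Coerce a point-set argument to an n x 3 matrix (a single point becomes 1 x 3).
as_points_matrix <- function(p, name = deparse(substitute(p))) {
  if (is.null(dim(p))) {
    if (length(p) == 3L) p <- matrix(as.numeric(p), nrow = 1L)
    else stop(sprintf("'%s' must be a 3-vector or an n x 3 matrix", name))
  }
  p <- as.matrix(p)
  if (ncol(p) != 3L) stop(sprintf("'%s' must have 3 columns (x, y, z)", name))
  storage.mode(p) <- "double"
  if (any(!is.finite(p))) stop(sprintf("'%s' contains non-finite coordinates", name))
  dimnames(p) <- NULL
  p
}

deg2rad <- function(deg) deg * pi / 180
rad2deg <- function(rad) rad * 180 / pi

# Row-wise Euclidean norms of an n x 3 matrix.
row_norms <- function(m) sqrt(rowSums(m * m))
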