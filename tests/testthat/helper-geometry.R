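# Shared geometry helpers and independent oracles for the test suite.

# uniform random rotation matrix (proper orthogonal)
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 1L] <- -Q[, 1L]
  Q
}

rand_unit <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

# random valid landmark set (side = right)
random_landmarks <- function() {
  C <- rnorm(3, sd = 10)
  d1 <- rand_unit()
  repeat {
    d2 <- rand_unit()
    ang <- acos(max(-1, min(1, sum(d1 * d2)))) * 180 / pi
    if (ang > 15 && ang < 165) break
  }
  R <- C + runif(1, 1, 5) * d1
  A <- C + runif(1, 1, 5) * d2
  I <- R - runif(1, 0.5, 2) * d1
  landmark_set(R = R, C = C, A = A, I = I, side = "right")
}

# minimal section objects for fit_centerline
make_sections <- function(theta, centroids) {
  lapply(seq_along(theta), function(k) {
    structure(list(theta = theta[k],
                   member_indices = integer(0),
                   centroid = centroids[k, ],
                   n_removed_by_width = 0L),
              class = "cross_section")
  })
}

# Independent first-hit oracle: plane intersection + barycentric coordinates
# from Gram-matrix dot products (a different algebraic route than
# Moller-Trumbore). Returns list(face_index, t) or NULL. Tolerances match the
# implementation's inclusive boundary conventions.
oracle_ray_mesh <- function(origin, direction, mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1L], , drop = FALSE]
  e1 <- v[f[, 2L], , drop = FALSE] - a
  e2 <- v[f[, 3L], , drop = FALSE] - a
  nx <- e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L]
  ny <- e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L]
  nz <- e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L]
  # skip degenerate faces entirely
  area2 <- sqrt(nx^2 + ny^2 + nz^2)
  denom <- nx * direction[1L] + ny * direction[2L] + nz * direction[3L]
  numer <- nx * (a[, 1L] - origin[1L]) + ny * (a[, 2L] - origin[2L]) +
    nz * (a[, 3L] - origin[3L])
  # Moller-Trumbore's det = dot(d x e2, e1) = dot(n, d); use the same
  # parallel cutoff so boundary behavior matches
  ok <- abs(denom) >= 1e-12 & area2 >= 1e-12
  t <- ifelse(ok, numer / denom, NA_real_)
  ok <- ok & !is.na(t) & t > 1e-9
  px <- origin[1L] + t * direction[1L] - a[, 1L]
  py <- origin[2L] + t * direction[2L] - a[, 2L]
  pz <- origin[3L] + t * direction[3L] - a[, 3L]
  d11 <- rowSums(e1 * e1); d22 <- rowSums(e2 * e2); d12 <- rowSums(e1 * e2)
  dw1 <- px * e1[, 1L] + py * e1[, 2L] + pz * e1[, 3L]
  dw2 <- px * e2[, 1L] + py * e2[, 2L] + pz * e2[, 3L]
  det_g <- d11 * d22 - d12^2
  u <- (d22 * dw1 - d12 * dw2) / det_g
  w <- (d11 * dw2 - d12 * dw1) / det_g
  ok <- ok & u >= -1e-12 & w >= -1e-12 & (u + w) <= 1 + 1e-12
  if (!any(ok, na.rm = TRUE)) return(NULL)
  cand <- which(ok)
  best <- cand[which.min(t[cand])]
  list(face_index = best, t = t[best])
}

# closed torus mesh: circle of radius big_r in the z = 0 plane, tube radius
# tube_r
make_torus <- function(big_r = 3, tube_r = 0.6, nu = 360L, nv = 48L) {
  us <- 2 * pi * (seq_len(nu) - 1L) / nu
  vs <- 2 * pi * (seq_len(nv) - 1L) / nv
  verts <- matrix(0, nu * nv, 3L)
  for (i in seq_len(nu)) {
    u <- us[i]
    ring <- cbind((big_r + tube_r * cos(vs)) * cos(u),
                  (big_r + tube_r * cos(vs)) * sin(u),
                  tube_r * sin(vs))
    verts[(i - 1L) * nv + seq_len(nv), ] <- ring
  }
  i0 <- rep(seq_len(nu), each = nv)
  j0 <- rep(seq_len(nv), times = nu)
  i1 <- ifelse(i0 == nu, 1L, i0 + 1L)
  j1 <- ifelse(j0 == nv, 1L, j0 + 1L)
  a <- (i0 - 1L) * nv + j0
  b <- (i1 - 1L) * nv + j0
  cc <- (i1 - 1L) * nv + j1
  d <- (i0 - 1L) * nv + j1
  surface_mesh(verts, rbind(cbind(a, b, cc), cbind(a, cc, d)),
               provenance = "torus")
}

# coarse phantom spec used where mesh size matters more than fidelity
coarse_phantom_spec <- function(...) {
  phantom_spec(angular_resolution = 15, circumferential_resolution = 10, ...)
}
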