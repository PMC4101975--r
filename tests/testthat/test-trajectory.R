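test_that("single ray/triangle intersection follows Moller-Trumbore conventions", {
  tri <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  hit <- ray_triangle_intersect(c(0.25, 0.25, 1), c(0, 0, -1), tri)
  expect_equal(hit$t, 1)
  expect_equal(hit$point, c(0.25, 0.25, 0))
  expect_equal(sum(hit$barycentric), 1, tolerance = 1e-12)

  # ray parallel to the triangle plane misses
  expect_null(ray_triangle_intersect(c(0.25, 0.25, 1), c(1, 0, 0), tri))
  # behind the origin
  expect_null(ray_triangle_intersect(c(0.25, 0.25, 1), c(0, 0, 1), tri))
  # winding-agnostic: reversed triangle gives the same hit
  hit2 <- ray_triangle_intersect(c(0.25, 0.25, 1), c(0, 0, -1), tri[c(1, 3, 2), ])
  expect_equal(hit2$t, 1)
  # degenerate triangle warns and returns no hit
  expect_warning(
    res <- ray_triangle_intersect(c(0, 0, 1), c(0, 0, -1),
                                  rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))),
    "degenerate")
  expect_null(res)
})

test_that("vectorized first-hit equals the independent plane-based oracle", {
  ph <- generate_phantom(coarse_phantom_spec())
  mesh <- ph$mesh
  set.seed(31)
  n <- 1000L
  origins <- matrix(rnorm(3 * n, sd = 3), ncol = 3L)
  n_hit <- 0L
  for (i in seq_len(n)) {
    d <- rand_unit()
    got <- cochleoplan:::ray_mesh_first_hit(origins[i, ], d, mesh)
    want <- oracle_ray_mesh(origins[i, ], d, mesh)
    if (is.null(want)) {
      expect_null(got)
    } else {
      n_hit <- n_hit + 1L
      expect_equal(got$face_index, want$face_index)
      expect_equal(got$t, want$t, tolerance = 1e-9)
    }
  }
  expect_gt(n_hit, 100L)  # the comparison actually exercised hits
})

test_that("cast_to_surface recovers the analytic tangential chord of a torus", {
  torus <- make_torus(big_r = 3, tube_r = 0.6, nu = 360L, nv = 48L)
  th <- 10 * pi / 180
  anchor <- c(3 * cos(th), 3 * sin(th), 0)
  tangent <- c(-sin(th), cos(th), 0)
  hit <- cast_to_surface(anchor, tangent, torus)
  chord <- sqrt((3 + 0.6)^2 - 3^2)  # in-plane tangential chord
  expect_equal(hit$exit_distance, chord, tolerance = 5e-3)
  expect_equal(hit$target, anchor - hit$exit_distance * tangent, tolerance = 1e-9)

  # anchor outside a closed mesh pointing away: no exit
  expect_error(cast_to_surface(c(10, 0, 0), c(-1, 0, 0), torus), "does not exit")
})

test_that("the cochleostomy sweep has the documented grid and target invariants", {
  ph <- generate_phantom(phantom_spec())
  res <- plan_cochleostomy(ph$mesh, ph$landmarks)
  expect_length(res$plan, 10L)
  expect_equal(vapply(res$plan, `[[`, numeric(1), "theta_c"), seq(2, 20, 2))

  for (tr in res$plan) {
    expect_gt(tr$exit_distance, 0)
    # target = anchor - exit_distance * insertion_dir
    expect_equal(tr$target, tr$anchor - tr$exit_distance * tr$insertion_dir,
                 tolerance = 1e-9)
    # barycentric coordinates identify a point on the hit triangle
    b <- tr$barycentric
    expect_equal(sum(b), 1, tolerance = 1e-9)
    expect_true(all(b >= -1e-9 & b <= 1 + 1e-9))
    tri <- ph$mesh$vertices[ph$mesh$faces[tr$face_index, ], , drop = FALSE]
    expect_equal(as.vector(t(tri) %*% b), tr$target, tolerance = 1e-9)
  }

  res2 <- plan_cochleostomy(ph$mesh, ph$landmarks,
                            plan_config(theta_step = 20, theta_max = 20))
  expect_length(res2$plan, 1L)
  expect_equal(res2$plan[[1L]]$theta_c, 20)
})

test_that("planning is covariant under rigid transformation of mesh and landmarks", {
  # a touch of vertex noise keeps every vertex strictly off the truncation
  # boundary planes, where membership would otherwise be decided by rotation
  # round-off
  ph <- generate_phantom(coarse_phantom_spec(noise_sd = 0.01, seed = 3))
  res <- plan_cochleostomy(ph$mesh, ph$landmarks,
                           plan_config(theta_step = 5, theta_max = 20))
  set.seed(32)
  Q <- random_rotation()
  tv <- rnorm(3, sd = 8)
  mesh2 <- cochleoplan:::transform_mesh(ph$mesh, Q, tv)
  lm <- ph$landmarks
  lm2 <- landmark_set(Q %*% lm$R + tv, Q %*% lm$C + tv, Q %*% lm$A + tv,
                      Q %*% lm$I + tv, side = lm$side)
  res2 <- plan_cochleostomy(mesh2, lm2, plan_config(theta_step = 5, theta_max = 20))
  expect_length(res2$plan, length(res$plan))
  for (i in seq_along(res$plan)) {
    expect_equal(res2$plan[[i]]$target,
                 as.vector(Q %*% res$plan[[i]]$target + tv), tolerance = 1e-6)
    expect_equal(res2$plan[[i]]$insertion_dir,
                 as.vector(Q %*% res$plan[[i]]$insertion_dir), tolerance = 1e-6)
  }
})
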