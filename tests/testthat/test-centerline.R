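test_that("truncation keeps exactly the points with y > 0 and z < 0", {
  pts <- rbind(c(1, 1, -1), c(1, -1, -1), c(1, 1, 1))
  out <- truncate_to_basal_st(pts)
  expect_equal(nrow(out), 1L)
  expect_equal(as.vector(out[1L, ]), c(1, 1, -1))
  expect_equal(attr(out, "indices"), 1L)

  # boundary convention: points on either plane are excluded
  expect_error(truncate_to_basal_st(rbind(c(1, 0, -1), c(1, 1, 0))),
               "no basal ST")
})

test_that("width filter trims distant blobs and leaves tight clusters alone", {
  set.seed(21)
  tight <- matrix(rnorm(300, sd = 0.13), ncol = 3L)  # radius well under 1
  tight <- tight[sqrt(rowSums(tight^2)) < 0.4, , drop = FALSE]
  out <- width_filter(tight, st_width = 1)
  expect_equal(nrow(out), nrow(tight))
  expect_equal(attr(out, "n_removed"), 0L)

  main <- matrix(rnorm(240, sd = 0.15), ncol = 3L)
  main <- main[sqrt(rowSums(main^2)) < 0.4, , drop = FALSE]
  outlier <- sweep(matrix(rnorm(18, sd = 0.1), ncol = 3L), 2L, c(5, 0, 0), "+")
  both <- rbind(main, outlier)
  filtered <- width_filter(both, st_width = 1)
  kept <- attr(filtered, "kept")
  expect_true(all(kept[seq_len(nrow(main))]))
  expect_false(any(kept[nrow(main) + seq_len(nrow(outlier))]))

  single <- matrix(c(3, 2, -1), nrow = 1L)
  expect_equal(nrow(width_filter(single, st_width = 0.5)), 1L)

  # two far-apart points: both farther than st_width from their midpoint
  expect_error(width_filter(rbind(c(0, 0, 0), c(5, 0, 0)), st_width = 1),
               "collapsed")
})

test_that("points are assigned to the nearest bin center and centroids are plain means", {
  # a point at basal angle 2.4 deg goes to the bin centered at 0
  p <- c(3 * cos(2.4 * pi / 180), 3 * sin(2.4 * pi / 180), -0.5)
  pts <- rbind(p,
               c(0, 3, -0.6),
               c(2, 2, -0.4),
               c(-3, 0.05, -0.2))
  # enough sections requires >= 4 bins; check assignment attribute
  secs <- bin_cross_sections(pts, delta_theta = 5, st_width = 10)
  expect_equal(attr(secs, "assignment"),
               c(0, 90, 45, 180))

  # uniformly sampled ring at theta = 90 centered at (0, 3, -0.6)
  phi <- 2 * pi * (0:35) / 36
  ring <- cbind(0, 3 + 0.3 * cos(phi), -0.6 + 0.3 * sin(phi))
  filler <- rbind(c(3, 0.2, -0.5), c(2, 2, -0.5), c(-2, 2, -0.5))
  secs2 <- bin_cross_sections(rbind(ring, filler), delta_theta = 5, st_width = 5)
  s90 <- secs2[[which(vapply(secs2, `[[`, numeric(1), "theta") == 90)]]
  expect_equal(s90$centroid, c(0, 3, -0.6), tolerance = 1e-9)
  # centroid equals the brute-force arithmetic mean of its members
  all_pts <- rbind(ring, filler)
  expect_equal(s90$centroid,
               colMeans(all_pts[s90$member_indices, , drop = FALSE]))

  expect_error(bin_cross_sections(pts[1:2, ], delta_theta = 5, st_width = 10),
               "insufficient sections")
  expect_error(bin_cross_sections(pts, delta_theta = 7, st_width = 10),
               "divisor")
})

test_that("interpolating spline reproduces centroids exactly at the knots", {
  th <- seq(0, 90, by = 10)
  Y <- cbind(3 + 0.01 * th - 1e-4 * th^2 + 2e-6 * th^3,
             0.05 * th + 3e-6 * th^3,
             -0.6 + 1e-3 * th)
  sp <- fit_centerline(make_sections(th, Y), residual_tol = 0)
  expect_lt(max(abs(spline_point(sp, sp$theta) - Y)), 1e-9)
  expect_equal(sp$max_residual, 0)
})

test_that("smoothed spline recovers a circle and respects the residual bound", {
  th <- seq(0, 180, by = 5)
  circ <- cbind(3 * cos(th * pi / 180), 3 * sin(th * pi / 180), 0)
  sp <- fit_centerline(make_sections(th, circ), residual_tol = 0.05)
  expect_lt(max(abs(spline_point(sp, 90) - c(0, 3, 0))), 1e-3)
  expect_lte(sp$max_residual, 0.05 + 1e-12)

  # noisy centroids: the smoothing criterion keeps the max residual in bound
  set.seed(22)
  noisy <- circ + matrix(rnorm(length(circ), sd = 0.05), ncol = 3L)
  spn <- fit_centerline(make_sections(th, noisy), residual_tol = 0.05)
  expect_lte(spn$max_residual, 0.05 + 1e-12)

  expect_error(fit_centerline(make_sections(th[1:3], circ[1:3, ])), "few sections")
  expect_error(fit_centerline(make_sections(rev(th), circ)), "increasing")
})

test_that("tangents match the analytic circle derivative and finite differences", {
  th <- seq(0, 180, by = 5)
  circ <- cbind(3 * cos(th * pi / 180), 3 * sin(th * pi / 180), 0)
  sp <- fit_centerline(make_sections(th, circ), residual_tol = 0.05)
  expect_lt(max(abs(spline_tangent(sp, 90) - c(-1, 0, 0))), 1e-3)

  set.seed(23)
  th_r <- runif(100, 1, 179)
  tans <- spline_tangent(sp, th_r)
  h <- 0.01
  fd <- spline_point(sp, th_r + h) - spline_point(sp, th_r - h)
  fd <- fd / sqrt(rowSums(fd^2))
  ang <- acos(pmin(1, rowSums(tans * fd))) * 180 / pi
  expect_lt(max(ang), 0.01)
})

test_that("straight-line centroids give a constant tangent and no extrapolation", {
  th <- seq(0, 50, by = 5)
  k <- seq_along(th) - 1
  line <- cbind(2 + 0.05 * k, 1 + 0.02 * k, -0.5 - 0.01 * k)
  sp <- fit_centerline(make_sections(th, line), residual_tol = 0)
  tans <- spline_tangent(sp, c(5, 17, 33, 49))
  expect_lt(max(abs(sweep(tans, 2L, tans[1L, ]))), 1e-9)

  expect_error(spline_point(sp, 60), "domain")
  expect_error(spline_tangent(sp, -1), "domain")
})
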