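# Scala tympani centerline extraction: truncation to the basal ST, radial
# cross-section binning with a width filter, and a smoothed cubic spline
# through the section centroids.

#' Truncate a local point cloud to the basal scala tympani
#'
#' Keeps exactly the points with positive local y and negative local z. The
#' local x-y plane models the basilar membrane, so negative z selects the
#' scala tympani below it; positive y restricts to the first basal half turn
#' (basal angles strictly inside 0-180 degrees). Inequalities are strict:
#' points on either plane are excluded.
#'
#' @param points_local n x 3 matrix in the cochlear frame (mm).
#' @return The selected rows, with an `"indices"` attribute giving their row
#'   numbers in the input.
#' @export
truncate_to_basal_st <- function(points_local) {
  p <- as_points_matrix(points_local, "points_local")
  keep <- which(p[, 2L] > 0 & p[, 3L] < 0)
  if (length(keep) == 0L) {
    stop(paste0("no basal ST surface found after truncation (no points with ",
                "y > 0 and z < 0); check the frame orientation / ear side"))
  }
  out <- p[keep, , drop = FALSE]
  attr(out, "indices") <- keep
  out
}

#' Trim section points that violate the scala tympani width bound
#'
#' Enforces the modelling assumption that the ST cross-section width does not
#' exceed `st_width` (the landmark distance |R - I|): iteratively computes
#' the centroid of the kept points, discards points farther than `st_width`
#' from it, and repeats until no point is removed. The kept set shrinks
#' monotonically, so the iteration terminates.
#'
#' @param section_points n x 3 matrix (local mm) of one section's points.
#' @param st_width width bound in mm (> 0).
#' @return The kept rows, with attributes `"kept"` (logical vector over the
#'   input rows) and `"n_removed"`.
#' @export
width_filter <- function(section_points, st_width) {
  p <- as_points_matrix(section_points, "section_points")
  if (!is.numeric(st_width) || st_width <= 0) stop("st_width must be > 0")
  keep <- rep(TRUE, nrow(p))
  repeat {
    if (!any(keep)) stop("section collapsed under width filter")
    centroid <- colMeans(p[keep, , drop = FALSE])
    d <- row_norms(sweep(p, 2L, centroid))
    new_keep <- keep & (d <= st_width)
    if (identical(new_keep, keep)) break
    keep <- new_keep
  }
  if (!any(keep)) stop("section collapsed under width filter")
  out <- p[keep, , drop = FALSE]
  attr(out, "kept") <- keep
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Extract radial cross sections of the basal scala tympani
#'
#' Partitions the truncated ST points into radial cross sections about the
#' modiolar axis: each point is assigned to the nearest bin center on the
#' grid `theta = 0, delta_theta, ..., 180` degrees by its basal angle (a
#' strict partition; no point is lost or double-counted). The width filter is
#' then applied per bin, bins left empty are dropped, and the centroid of
#' each surviving bin is the arithmetic mean of its member points.
#'
#' @param points_local n x 3 matrix of truncated ST points (local mm).
#' @param delta_theta angular bin spacing in degrees (must divide 180);
#'   default 5.
#' @param theta_range angular range covered by the bins; fixed grid over
#'   `[0, 180]` by default (the first basal half turn).
#' @param st_width width bound passed to [width_filter()] (mm).
#' @return A list of `cross_section` objects (fields `theta`,
#'   `member_indices`, `centroid`, `n_removed_by_width`), ordered by theta,
#'   with an `"assignment"` attribute giving each input point's bin center.
#' @export
bin_cross_sections <- function(points_local, delta_theta = 5,
                               theta_range = c(0, 180), st_width) {
  p <- as_points_matrix(points_local, "points_local")
  if (delta_theta <= 0 || abs(180 / delta_theta - round(180 / delta_theta)) > 1e-9) {
    stop("delta_theta must be a positive divisor of 180")
  }
  if (!isTRUE(all.equal(theta_range, c(0, 180)))) {
    if (theta_range[1L] < 0 || theta_range[2L] > 180 || theta_range[1L] >= theta_range[2L]) {
      stop("theta_range must be an increasing interval within [0, 180]")
    }
  }
  centers <- seq(theta_range[1L], theta_range[2L], by = delta_theta)
  theta <- basal_angle_of(p)

  # Nearest-center assignment on the circle; ties go to the lower center.
  idx <- round((theta - centers[1L]) / delta_theta) + 1L
  idx[idx < 1L] <- 1L
  idx[idx > length(centers)] <- length(centers)

  sections <- vector("list", length(centers))
  for (k in seq_along(centers)) {
    members <- which(idx == k)
    if (length(members) == 0L) next
    filtered <- width_filter(p[members, , drop = FALSE], st_width)
    kept <- members[attr(filtered, "kept")]
    if (length(kept) == 0L) next
    sections[[k]] <- structure(
      list(theta = centers[k],
           member_indices = kept,
           centroid = colMeans(p[kept, , drop = FALSE]),
           n_removed_by_width = attr(filtered, "n_removed")),
      class = "cross_section")
  }
  sections <- sections[!vapply(sections, is.null, logical(1))]
  if (length(sections) < 4L) {
    stop(sprintf("insufficient sections for spline: %d surviving bins (need >= 4)",
                 length(sections)))
  }
  attr(sections, "assignment") <- centers[idx]
  sections
}

#' Fit the smoothed cubic-spline centerline
#'
#' Fits a smoothed cubic spline through the section centroids,
#' parameterized by basal angle. Knots are placed at each centroid's actual
#' basal angle (falling back to the nominal bin centers if those are not
#' strictly increasing). Smoothing is performed on the cylindrical
#' components of the centroids — in-plane radius and height against basal
#' angle — where the mid-scala course is a slowly varying function, so the
#' natural boundary conditions of the smoothing spline do not flatten the
#' strongly curved spiral near the ends of the domain. The smoothing penalty
#' is the largest one for which the maximum 3D residual at the knots stays
#' within `residual_tol`; the smoothed curve is then re-expressed as
#' per-coordinate cubic splines of (x, y, z) against theta on a dense knot
#' grid. `residual_tol = 0` yields a direct per-coordinate interpolating
#' cubic spline through the centroids.
#'
#' @param sections list of `cross_section` objects with strictly increasing
#'   theta (at least 4).
#' @param residual_tol maximum allowed distance (mm) between the spline and
#'   any centroid; default 0.05.
#' @return An object of class `centerline_spline` with fields `theta`
#'   (knot parameters, degrees), `fitted` (smoothed knot positions, n x 3
#'   local mm), `domain`, `residual_tol` and `max_residual`.
#' @export
fit_centerline <- function(sections, residual_tol = 0.05) {
  if (length(sections) < 4L) stop("too few sections: need >= 4 to fit a cubic spline")
  nominal <- vapply(sections, `[[`, numeric(1), "theta")
  if (any(diff(nominal) <= 0)) stop("section angles must be strictly increasing")
  if (residual_tol < 0) stop("residual_tol must be >= 0")
  Y <- t(vapply(sections, `[[`, numeric(3), "centroid"))

  # prefer the centroids' actual basal angles as knot parameters: with
  # partially filled boundary bins the nominal bin center can sit a couple
  # of degrees away from where the centroid actually lies
  th_act <- basal_angle_of(Y)
  theta <- if (all(diff(th_act) > 0)) th_act else nominal

  if (residual_tol == 0) {
    fitted <- Y
    splines <- lapply(1:3, function(j) {
      stats::splinefun(theta, Y[, j], method = "fmm")
    })
  } else {
    rho <- sqrt(Y[, 1L]^2 + Y[, 2L]^2)
    z <- Y[, 3L]
    fit_rz <- function(lambda) {
      sr <- stats::smooth.spline(theta, rho, lambda = lambda,
                                 all.knots = TRUE, keep.data = FALSE)
      sz <- stats::smooth.spline(theta, z, lambda = lambda,
                                 all.knots = TRUE, keep.data = FALSE)
      list(sr = sr, sz = sz,
           resid = max(sqrt((stats::predict(sr, theta)$y - rho)^2 +
                            (stats::predict(sz, theta)$y - z)^2)))
    }
    # lambda upper bound 1e3: already the straight-trend limit, while the
    # penalized system stays numerically well conditioned
    lo <- -14; hi <- 3
    if (fit_rz(10^lo)$resid <= residual_tol) {
      if (fit_rz(10^hi)$resid <= residual_tol) {
        lo <- hi
      } else {
        for (i in seq_len(60L)) {
          mid <- (lo + hi) / 2
          if (fit_rz(10^mid)$resid <= residual_tol) lo <- mid else hi <- mid
        }
      }
      best <- fit_rz(10^lo)
      # densify the smoothed cylindrical curve and re-express it as
      # per-coordinate cubic splines of (x, y, z) against theta; the grid
      # contains every knot, and regular grid points too close to a knot are
      # dropped so no near-duplicate abscissae enter the interpolant
      grid <- seq(theta[1L], theta[length(theta)], by = 0.5)
      near_knot <- vapply(grid, function(g) min(abs(g - theta)) < 0.1, logical(1))
      th_dense <- sort(c(theta, grid[!near_knot]))
      rho_d <- stats::predict(best$sr, th_dense)$y
      z_d <- stats::predict(best$sz, th_dense)$y
      X <- cbind(rho_d * cos(deg2rad(th_dense)), rho_d * sin(deg2rad(th_dense)), z_d)
      splines <- lapply(1:3, function(j) {
        stats::splinefun(th_dense, X[, j], method = "fmm")
      })
      fitted <- X[match(theta, th_dense), , drop = FALSE]
    } else {
      # even near-interpolating smoothing violates the tolerance; fall back
      # to direct interpolation of the raw centroids
      fitted <- Y
      splines <- lapply(1:3, function(j) {
        stats::splinefun(theta, Y[, j], method = "fmm")
      })
    }
  }

  structure(
    list(theta = theta,
         fitted = fitted,
         splines = splines,
         domain = range(theta),
         residual_tol = residual_tol,
         max_residual = max(row_norms(fitted - Y))),
    class = "centerline_spline")
}

#' @export
print.centerline_spline <- function(x, ...) {
  cat(sprintf("ST centerline spline: %d knots, theta in [%g, %g] deg\n",
              length(x$theta), x$domain[1L], x$domain[2L]))
  cat(sprintf("  smoothing residual: max %.4g mm (tolerance %.4g mm)\n",
              x$max_residual, x$residual_tol))
  invisible(x)
}

check_spline_domain <- function(spline, theta) {
  eps <- 1e-9
  if (any(theta < spline$domain[1L] - eps | theta > spline$domain[2L] + eps)) {
    stop(sprintf("theta outside the spline domain [%g, %g] (no extrapolation)",
                 spline$domain[1L], spline$domain[2L]))
  }
}

#' Evaluate the centerline spline
#'
#' `spline_point()` returns the 3D centerline position at basal angle
#' `theta`; `spline_tangent()` returns the unit tangent (normalized
#' derivative with respect to theta, oriented toward increasing theta, i.e.
#' deeper insertion). Angles outside the fitted domain raise an error.
#'
#' @param spline a [fit_centerline()] result.
#' @param theta basal angle(s) in degrees within the spline domain.
#' @return For a single angle a length-3 vector, otherwise an n x 3 matrix
#'   (local frame, mm; tangents are unit vectors).
#' @export
spline_point <- function(spline, theta) {
  stopifnot(inherits(spline, "centerline_spline"))
  check_spline_domain(spline, theta)
  out <- vapply(spline$splines, function(f) f(theta), numeric(length(theta)))
  if (length(theta) == 1L) as.vector(out) else matrix(out, ncol = 3L)
}

#' @rdname spline_point
#' @export
spline_tangent <- function(spline, theta) {
  stopifnot(inherits(spline, "centerline_spline"))
  check_spline_domain(spline, theta)
  d <- vapply(spline$splines, function(f) f(theta, deriv = 1L), numeric(length(theta)))
  d <- matrix(d, ncol = 3L)
  len <- row_norms(d)
  if (any(len < .Machine$double.eps)) stop("degenerate tangent (zero derivative)")
  out <- d / len
  if (length(theta) == 1L) as.vector(out) else out
}
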