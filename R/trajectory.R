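## MT trajectory analysis: minimax bundle center, zenith normalization of
## the fiber axis by exhaustive Euler-rotation grid search, spherical
## angles, plane intersections and angle-vs-distance regression.

## ---- smallest enclosing circle (exact minimax 1-center) ----

circ2 <- function(a, b) {
  list(c = (a + b) / 2, r = sqrt(sum((a - b)^2)) / 2)
}

circ3 <- function(a, b, c) {
  d <- 2 * (a[1] * (b[2] - c[2]) + b[1] * (c[2] - a[2]) + c[1] * (a[2] - b[2]))
  if (abs(d) < 1e-12) {
    ## collinear: fall back to widest pair
    cands <- list(circ2(a, b), circ2(a, c), circ2(b, c))
    return(cands[[which.max(vapply(cands, `[[`, numeric(1), "r"))]])
  }
  a2 <- sum(a^2); b2 <- sum(b^2); c2 <- sum(c^2)
  ux <- (a2 * (b[2] - c[2]) + b2 * (c[2] - a[2]) + c2 * (a[2] - b[2])) / d
  uy <- (a2 * (c[1] - b[1]) + b2 * (a[1] - c[1]) + c2 * (b[1] - a[1])) / d
  ctr <- c(ux, uy)
  list(c = ctr, r = sqrt(sum((a - ctr)^2)))
}

in_circ <- function(circ, p, eps = 1e-9) {
  sqrt(sum((p - circ$c)^2)) <= circ$r + eps
}

min_circle <- function(pts) {
  n <- nrow(pts)
  if (n == 1) return(list(c = pts[1, ], r = 0))
  circ <- circ2(pts[1, ], pts[2, ])
  if (n == 2) return(circ)
  for (i in 3:n) {
    if (in_circ(circ, pts[i, ])) next
    circ <- circ2(pts[1, ], pts[i, ])
    for (j in 2:(i - 1)) {
      if (in_circ(circ, pts[j, ])) next
      circ <- circ2(pts[j, ], pts[i, ])
      if (j > 1) for (k in seq_len(j - 1)) {
        if (!in_circ(circ, pts[k, ])) {
          circ <- circ3(pts[k, ], pts[j, ], pts[i, ])
        }
      }
    }
  }
  circ
}

#' Minimax (farthest-point) center of a fiber cross-section
#'
#' The bundle center is the point minimizing the maximum distance to all MT
#' positions -- the 1-center objective solved by farthest-point clustering
#' with k = 1, i.e. the center of the smallest enclosing circle (computed
#' exactly by the incremental Welzl construction).
#'
#' @param points Cross-section table or 2-column matrix (nm).
#' @return List with `center` (x, y), `radius_nm` (minimax value) and
#'   `distances_nm` (per-MT distance from the center).
#' @export
bundle_center <- function(points) {
  xy <- as_xy(points)
  circ <- min_circle(xy)
  d <- sqrt((xy[, 1] - circ$c[1])^2 + (xy[, 2] - circ$c[2])^2)
  list(center = unname(circ$c), radius_nm = circ$r, distances_nm = unname(d))
}

## ---- Euler rotations ----

rot_x <- function(g) matrix(c(1, 0, 0, 0, cos(g), sin(g), 0, -sin(g), cos(g)), 3)
rot_y <- function(b) matrix(c(cos(b), 0, -sin(b), 0, 1, 0, sin(b), 0, cos(b)), 3)
rot_z <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3)

#' Euler rotation matrix (z, then y, then x)
#'
#' Right-handed rotation applied to column vectors as
#' `v' = Rx(gamma) Ry(beta) Rz(alpha) v`: the z-rotation acts first, then y,
#' then x. Applying the z-rotation first lets the (alpha, beta) pair carry
#' any direction with polar angle <= pi/2 to the zenith, which is what the
#' normalization search requires.
#'
#' @param alpha,beta,gamma Rotation angles (radians) about z, y, x.
#' @return 3x3 orthonormal matrix.
#' @export
euler_rotation <- function(alpha, beta, gamma = 0) {
  rot_x(gamma) %*% rot_y(beta) %*% rot_z(alpha)
}

## Extract an n x 3 matrix of unit MT directions from common inputs.
mt_directions <- function(x) {
  if (is.matrix(x) && ncol(x) == 3) {
    d <- x
  } else if (inherits(x, "fiber_model")) {
    m <- x$mts
    d <- cbind(m$top_x_nm - m$bot_x_nm, m$top_y_nm - m$bot_y_nm,
               m$top_z_nm - m$bot_z_nm)
  } else if (is.data.frame(x) && all(c("dir_x", "dir_y", "dir_z") %in% names(x))) {
    d <- cbind(x$dir_x, x$dir_y, x$dir_z)
  } else if (is.data.frame(x) && all(c("bot_x_nm", "top_x_nm") %in% names(x))) {
    d <- cbind(x$top_x_nm - x$bot_x_nm, x$top_y_nm - x$bot_y_nm,
               x$top_z_nm - x$bot_z_nm)
  } else {
    stop_kf("cannot extract MT directions from this input")
  }
  nrm <- sqrt(rowSums(d^2))
  if (any(nrm == 0)) stop_kf("zero-length MT direction")
  d / nrm
}

#' Zenith-normalize fiber orientation by exhaustive rotation search
#'
#' Finds the Euler rotation (alpha about z applied first, then beta about y;
#' gamma fixed at 0) that makes the fiber point most nearly at the zenith:
#' the objective is the summed magnitude of the x-y projections of the
#' rotated unit MT directions, minimized by exhaustive grid search over
#' alpha in `[0, 2*pi]`, beta in `[0, pi/2]` at `step_rad` resolution
#' (default 1 degree). Ties are broken towards the smallest beta, then
#' smallest alpha, so an already-normalized fiber returns the identity.
#'
#' @param vectors A `fiber_model`, the tibble from [generate_mt_vectors()],
#'   or an n x 3 matrix of direction vectors.
#' @param step_rad Grid step in radians.
#' @return List with `alpha`, `beta` (radians), `objective` (summed
#'   projection at the optimum), `rotation` (3x3 matrix) and `rotated`
#'   (n x 3 rotated unit directions).
#' @export
normalize_orientation <- function(vectors, step_rad = pi / 180) {
  assert_scalar_num(step_rad, "step_rad", positive = TRUE)
  v <- mt_directions(vectors)
  alphas <- seq(0, 2 * pi, by = step_rad)
  betas <- seq(0, pi / 2 + 1e-12, by = step_rad)
  cb <- cos(betas); sb <- sin(betas)

  obj <- matrix(NA_real_, length(alphas), length(betas))
  for (ai in seq_along(alphas)) {
    a <- alphas[ai]
    u1 <- cos(a) * v[, 1] - sin(a) * v[, 2]
    u2 <- sin(a) * v[, 1] + cos(a) * v[, 2]
    xp <- outer(cb, u1) + outer(sb, v[, 3])     # n_beta x n
    yp2 <- matrix(u2^2, length(betas), nrow(v), byrow = TRUE)
    obj[ai, ] <- rowSums(sqrt(xp^2 + yp2))
  }
  best <- min(obj)
  cand <- which(obj <= best + 1e-9, arr.ind = TRUE)
  pick <- cand[order(cand[, 2], cand[, 1]), , drop = FALSE][1, ]
  alpha <- alphas[pick[1]]; beta <- betas[pick[2]]
  R <- euler_rotation(alpha, beta)
  list(alpha = alpha, beta = beta,
       objective = obj[pick[1], pick[2]],
       rotation = R,
       rotated = t(R %*% t(v)))
}

#' Spherical angles of normalized MT directions
#'
#' Polar angle `theta = acos(z / r)` in `[0, pi]` (deviation from the fiber
#' axis after normalization) and quadrant-aware azimuthal angle
#' `phi = atan2(y, x)` in `(-pi, pi]` (`phi = 0` when x = y = 0).
#'
#' @param vectors n x 3 matrix of (rotated) direction vectors, or any input
#'   accepted by [normalize_orientation()].
#' @return Tibble (`r`, `theta_rad`, `phi_rad`).
#' @export
spherical_angles <- function(vectors) {
  v <- if (is.matrix(vectors) && ncol(vectors) == 3) vectors else mt_directions(vectors)
  r <- sqrt(rowSums(v^2))
  theta <- acos(pmin(1, pmax(-1, v[, 3] / r)))
  phi <- atan2(v[, 2], v[, 1])
  phi[v[, 1] == 0 & v[, 2] == 0] <- 0
  tibble::tibble(r = r, theta_rad = theta, phi_rad = phi)
}

#' Intersections of MT vectors with a reference x-y plane
#'
#' Each unit MT direction, anchored at a common origin, is extended to the
#' x-y plane at `z_plane_nm` (100 nm by convention); the Cartesian
#' intersection coordinates visualize trajectory deviation. Directions with
#' non-positive z cannot intersect the plane and are excluded (counted).
#'
#' @param vectors n x 3 matrix of rotated directions (or input accepted by
#'   [mt_directions] extraction).
#' @param z_plane_nm Plane height in nm.
#' @return List with `points` (tibble `ix_nm`, `iy_nm`, `radius_nm`) and
#'   `n_excluded`.
#' @export
plane_intersections <- function(vectors, z_plane_nm = 100) {
  v <- if (is.matrix(vectors) && ncol(vectors) == 3) vectors else mt_directions(vectors)
  ok <- v[, 3] > 0
  s <- z_plane_nm / v[ok, 3]
  ix <- v[ok, 1] * s
  iy <- v[ok, 2] * s
  list(points = tibble::tibble(ix_nm = ix, iy_nm = iy,
                               radius_nm = sqrt(ix^2 + iy^2)),
       n_excluded = sum(!ok))
}

#' Fraction of MT vectors intersecting the plane near its center
#'
#' Proportion of plane intersections at radial distance strictly less than
#' `threshold_nm` from the plane center: the fraction of near-parallel MTs.
#'
#' @param intersections Output of [plane_intersections()].
#' @param threshold_nm Radial cutoff (strict `<`), default 10 nm.
#' @return Proportion in `[0, 1]`.
#' @export
radial_fraction <- function(intersections, threshold_nm = 10) {
  r <- intersections$points$radius_nm
  if (length(r) == 0) return(NA_real_)
  mean(r < threshold_nm)
}

#' Ordinary least-squares regression of an angle on center distance
#'
#' @param angle_rad Per-MT angle (theta or phi).
#' @param distance_nm Per-MT distance from the bundle center.
#' @return List with `slope`, `intercept`, `r_squared`, `slope_se` and the
#'   95% confidence interval of the slope; all `NA` (flagged by
#'   `degenerate = TRUE`) when the distance has zero variance or n < 3.
#' @export
angle_distance_regression <- function(angle_rad, distance_nm) {
  if (length(angle_rad) < 3 || stats::var(distance_nm) == 0) {
    return(list(slope = NA_real_, intercept = NA_real_, r_squared = NA_real_,
                slope_se = NA_real_, conf_low = NA_real_, conf_high = NA_real_,
                degenerate = TRUE))
  }
  fit <- stats::lm(angle_rad ~ distance_nm)
  ## summary.lm warns on residual-free (perfect) fits; those are legitimate
  ## inputs here (exactly linear or constant angles)
  sm <- suppressWarnings(summary(fit))
  ci <- suppressWarnings(stats::confint(fit, "distance_nm", level = 0.95))
  r2 <- sm$r.squared
  if (stats::var(angle_rad) == 0) r2 <- 0   # constant angle: no trend
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = r2,
       slope_se = sm$coefficients["distance_nm", "Std. Error"],
       conf_low = ci[1], conf_high = ci[2],
       degenerate = FALSE)
}

#' Full trajectory analysis of one fiber
#'
#' Runs the minimax bundle center, zenith normalization, spherical angles,
#' plane intersection scatter and the angle-vs-distance regressions.
#'
#' @param fiber A `fiber_model` (or tibble from [generate_mt_vectors()]).
#' @param step_rad Rotation-search grid step.
#' @param z_plane_nm Reference plane height.
#' @param threshold_nm Radial cutoff for the near-parallel fraction.
#' @return Object of class `trajectory_stats`: per-MT tibble `per_mt`
#'   (theta, phi, distance from center, intersection coordinates, within
#'   flag) plus fiber-level `alpha`, `beta`, `objective`,
#'   `fraction_within`, `median_theta_rad`, `reg_theta`, `reg_phi`,
#'   `n_excluded`.
#' @export
trajectory_stats <- function(fiber, step_rad = pi / 180, z_plane_nm = 100,
                             threshold_nm = 10) {
  pts <- if (inherits(fiber, "fiber_model")) fiber$mts else fiber
  ctr <- bundle_center(pts)
  norm <- normalize_orientation(fiber, step_rad = step_rad)
  ang <- spherical_angles(norm$rotated)
  inter <- plane_intersections(norm$rotated, z_plane_nm = z_plane_nm)
  frac <- radial_fraction(inter, threshold_nm = threshold_nm)

  keep <- norm$rotated[, 3] > 0
  ix <- rep(NA_real_, nrow(ang)); iy <- rep(NA_real_, nrow(ang))
  ix[keep] <- inter$points$ix_nm; iy[keep] <- inter$points$iy_nm
  per_mt <- tibble::tibble(
    mt_id = if (!is.null(pts$mt_id)) pts$mt_id else seq_len(nrow(ang)),
    theta_rad = ang$theta_rad,
    phi_rad = ang$phi_rad,
    dist_center_nm = ctr$distances_nm,
    ix_nm = ix, iy_nm = iy,
    within_threshold = !is.na(ix) & sqrt(ix^2 + iy^2) < threshold_nm
  )
  structure(list(
    per_mt = per_mt,
    center = ctr$center,
    alpha = norm$alpha, beta = norm$beta, objective = norm$objective,
    fraction_within = frac,
    median_theta_rad = stats::median(ang$theta_rad),
    reg_theta = angle_distance_regression(ang$theta_rad, ctr$distances_nm),
    reg_phi = angle_distance_regression(ang$phi_rad, ctr$distances_nm),
    n_excluded = inter$n_excluded,
    z_plane_nm = z_plane_nm, threshold_nm = threshold_nm
  ), class = "trajectory_stats")
}

#' @export
print.trajectory_stats <- function(x, ...) {
  cat(sprintf("<trajectory_stats> %d MTs: rotation (a=%.3f, b=%.3f), median theta %.3f rad, fraction within %g nm = %.2f\n",
              nrow(x$per_mt), x$alpha, x$beta, x$median_theta_rad,
              x$threshold_nm, x$fraction_within))
  invisible(x)
}
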