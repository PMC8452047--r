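#' One-dimensional home base (confidence band)
#'
#' The home base of a single emotion dimension is the confidence band
#' `mean +/- t * sqrt(var / N)`, where `var` is the population
#' (divide-by-N) variance of the series, and `t` is the two-sided
#' t-distribution critical value at the requested coverage with `N - 1`
#' degrees of freedom (quantile at `1 - (1 - confidence) / 2`). With the
#' default 68% coverage the band is roughly one standard error wide on each
#' side. A zero-variance series yields a degenerate band of width 0.
#'
#' @param series Numeric vector (typically a rolling trajectory component),
#'   length >= 2.
#' @param confidence Coverage level in (0, 1); default 0.68.
#' @return A `ued_band` object with fields `mean`, `half_width`, `lower`,
#'   `upper`, `confidence`, `n`, `variance`, `t_crit`.
#' @examples
#' home_base_1d(c(0.4, 0.6))
#' @export
home_base_1d <- function(series, confidence = 0.68) {
  confidence <- check_confidence(confidence)
  series <- series[!is.na(series)]
  n <- length(series)
  if (n < 2L) abort("`series` must contain at least 2 values.")
  m <- mean(series)
  s2 <- pop_var(series)
  t_crit <- stats::qt(1 - (1 - confidence) / 2, df = n - 1)
  hw <- t_crit * sqrt(s2 / n)
  structure(
    list(mean = m, half_width = hw, lower = m - hw, upper = m + hw,
         confidence = confidence, n = n, variance = s2, t_crit = t_crit),
    class = "ued_band"
  )
}

#' @export
print.ued_band <- function(x, ...) {
  cat(sprintf("Home base band (%.0f%%): [%.4f, %.4f]  mean %.4f, n %d\n",
              100 * x$confidence, x$lower, x$upper, x$mean, x$n))
  invisible(x)
}

#' Two-dimensional home base (covariance confidence ellipse)
#'
#' Fits the covariance confidence ellipse of a valence-arousal trajectory:
#' center at the component means, axes along the eigenvectors of the
#' population (divide-by-N) covariance matrix, semi-axis lengths
#' `sqrt(psi * lambda_j)` where `psi` is the chi-square(2 df) quantile at the
#' requested coverage (about 2.2789 at 68%) and `lambda_1 >= lambda_2` are
#' the covariance eigenvalues. A point `x` is inside the ellipse when the
#' quadratic form in principal-axis coordinates,
#' `((x - c) . e1)^2 / (psi lambda_1) + ((x - c) . e2)^2 / (psi lambda_2)`,
#' is at most 1.
#'
#' @param points A data frame with columns `v` and `a` (e.g. a trajectory
#'   from [rolling_trajectory()]), at least 3 rows with non-degenerate
#'   covariance.
#' @param confidence Coverage level in (0, 1); default 0.68.
#' @param tol Eigenvalues below `tol` are treated as degenerate (default
#'   1e-12).
#' @return A `home_base_ellipse` object with fields `center` (length-2,
#'   valence then arousal), `eigenvalues` (decreasing), `eigenvectors`
#'   (columns e1, e2, orthonormal), `psi`, `semi_major`, `semi_minor`,
#'   `theta` (major-axis angle, radians), `confidence`, `n`.
#' @export
home_base_2d <- function(points, confidence = 0.68, tol = 1e-12) {
  confidence <- check_confidence(confidence)
  stopifnot(all(c("v", "a") %in% names(points)))
  x <- cbind(points$v, points$a)
  x <- x[stats::complete.cases(x), , drop = FALSE]
  n <- nrow(x)
  if (n < 3L) abort("At least 3 trajectory points are required.")
  ctr <- colMeans(x)
  xc <- sweep(x, 2L, ctr)
  covm <- crossprod(xc) / n
  eg <- eigen(covm, symmetric = TRUE)
  if (eg$values[2] < tol) {
    # name the axis the deficient direction is closest to
    dir2 <- eg$vectors[, 2]
    axis <- if (abs(dir2[1]) >= abs(dir2[2])) "valence" else "arousal"
    abort(sprintf(
      "Degenerate trajectory geometry: no variation along the %s-dominated direction (eigenvalue %.3g < %g).",
      axis, eg$values[2], tol
    ))
  }
  vecs <- eg$vectors
  # deterministic eigenvector signs: largest-magnitude component positive
  for (j in 1:2) {
    k <- which.max(abs(vecs[, j]))
    if (vecs[k, j] < 0) vecs[, j] <- -vecs[, j]
  }
  psi <- stats::qchisq(confidence, df = 2)
  structure(
    list(
      center = stats::setNames(ctr, c("v", "a")),
      eigenvalues = eg$values,
      eigenvectors = vecs,
      psi = psi,
      semi_major = sqrt(psi * eg$values[1]),
      semi_minor = sqrt(psi * eg$values[2]),
      theta = atan2(vecs[2, 1], vecs[1, 1]),
      confidence = confidence,
      n = n
    ),
    class = "home_base_ellipse"
  )
}

#' @export
print.home_base_ellipse <- function(x, ...) {
  cat(sprintf(
    "Home base ellipse (%.0f%%): center (%.4f, %.4f), semi-axes %.4f / %.4f, theta %.3f rad, n %d\n",
    100 * x$confidence, x$center[1], x$center[2],
    x$semi_major, x$semi_minor, x$theta, x$n
  ))
  invisible(x)
}

# quadratic form of points relative to an ellipse; <= 1 means inside
ellipse_qform <- function(ellipse, v, a) {
  dv <- unname(v - ellipse$center[[1]])
  da <- unname(a - ellipse$center[[2]])
  e <- ellipse$eigenvectors
  u1 <- dv * e[1, 1] + da * e[2, 1]
  u2 <- dv * e[1, 2] + da * e[2, 2]
  u1^2 / (ellipse$psi * ellipse$eigenvalues[1]) +
    u2^2 / (ellipse$psi * ellipse$eigenvalues[2])
}

#' Ellipse membership
#'
#' A point is inside the home base when its quadratic form is at most 1; the
#' boundary counts as inside (a tolerance of 1e-12 absorbs the sqrt/square
#' round trip for points constructed exactly on the boundary).
#'
#' @param ellipse A `home_base_ellipse`.
#' @param v,a Numeric vectors of valence and arousal coordinates.
#' @return Logical vector.
#' @export
ellipse_contains <- function(ellipse, v, a) {
  ellipse_qform(ellipse, v, a) <= 1 + 1e-12
}

#' Distance from the home-base perimeter
#'
#' Distance from a point to the ellipse boundary. The default `"radial"`
#' convention measures along the ray from the ellipse center through the
#' point: if `r(u)` is the boundary radius in the point's direction `u`, the
#' distance is `max(0, |p - center| - r(u))`. It is 0 for points inside,
#' continuous, equals `|p - center| - radius` exactly in the circular limit,
#' and preserves the ordering of points along a single excursion ray. The
#' `"nearest"` method instead returns the exact orthogonal distance to the
#' closest boundary point (root-solved to ~1e-9).
#'
#' @param ellipse A `home_base_ellipse`.
#' @param v,a Numeric vectors of coordinates.
#' @param method `"radial"` (default) or `"nearest"`.
#' @return Numeric vector of non-negative distances.
#' @export
perimeter_distance <- function(ellipse, v, a, method = c("radial", "nearest")) {
  method <- match.arg(method)
  dv <- unname(v - ellipse$center[[1]])
  da <- unname(a - ellipse$center[[2]])
  if (method == "radial") {
    len <- sqrt(dv^2 + da^2)
    q <- ellipse_qform(ellipse, v, a)
    # boundary radius along the ray: r = len / sqrt(q); distance = len - r
    out <- ifelse(q <= 1 + 1e-12 | len == 0, 0, len * (1 - 1 / sqrt(q)))
    pmax(out, 0)
  } else {
    A <- ellipse$semi_major
    B <- ellipse$semi_minor
    e <- ellipse$eigenvectors
    p1 <- abs(dv * e[1, 1] + da * e[2, 1])
    p2 <- abs(dv * e[1, 2] + da * e[2, 2])
    mapply(function(x1, x2) nearest_ellipse_distance(x1, x2, A, B), p1, p2)
  }
}

# Exact distance from a point (x1, x2) in the first quadrant of principal-axis
# coordinates to the axis-aligned ellipse (x/A)^2 + (y/B)^2 = 1; 0 if inside.
nearest_ellipse_distance <- function(x1, x2, A, B) {
  if ((x1 / A)^2 + (x2 / B)^2 <= 1 + 1e-12) return(0)
  f <- function(s) (A * x1 / (s + A^2))^2 + (B * x2 / (s + B^2))^2 - 1
  hi <- A * sqrt(x1^2 + x2^2) # f(hi) < 0 for any outside point
  while (f(hi) > 0) hi <- hi * 2
  s <- stats::uniroot(f, c(0, hi), tol = 1e-12)$root
  bx <- A^2 * x1 / (s + A^2)
  by <- B^2 * x2 / (s + B^2)
  sqrt((x1 - bx)^2 + (x2 - by)^2)
}

#' Boundary coordinates of a home-base ellipse
#'
#' Evaluates the ellipse perimeter on a parameter grid, e.g. for plotting.
#'
#' @param ellipse A `home_base_ellipse`.
#' @param n Number of boundary points.
#' @return A tibble with columns `v`, `a`.
#' @export
ellipse_boundary <- function(ellipse, n = 361L) {
  th <- seq(0, 2 * pi, length.out = n)
  e <- ellipse$eigenvectors
  u1 <- ellipse$semi_major * cos(th)
  u2 <- ellipse$semi_minor * sin(th)
  tibble::tibble(
    v = ellipse$center[1] + u1 * e[1, 1] + u2 * e[1, 2],
    a = ellipse$center[2] + u1 * e[2, 1] + u2 * e[2, 2]
  )
}
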