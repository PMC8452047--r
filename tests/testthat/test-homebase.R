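test_that("1-D band matches the closed-form t critical value (df = 1 is Cauchy)", {
  hb <- home_base_1d(c(0.4, 0.6), confidence = 0.68)
  expect_equal(hb$variance, 0.01) # population denominator
  t_oracle <- tan(pi * (0.84 - 0.5)) # Cauchy quantile at 1 - (1-0.68)/2
  expect_equal(hb$t_crit, t_oracle, tolerance = 1e-12)
  expect_equal(hb$half_width, t_oracle * sqrt(0.01 / 2), tolerance = 1e-12)
  expect_equal(hb$half_width, 0.1286, tolerance = 1e-3)
  expect_equal(hb$lower, hb$mean - hb$half_width)
  expect_equal(hb$upper, hb$mean + hb$half_width)
})

test_that("1-D band degenerates to width zero for a constant series and errors for N < 2", {
  hb <- home_base_1d(rep(0.5, 20))
  expect_equal(c(hb$lower, hb$upper), c(0.5, 0.5))
  expect_error(home_base_1d(0.5), "at least 2")
})

test_that("4-point fixture reproduces the hand eigendecomposition exactly", {
  pts <- tibble::tibble(v = c(0, 1, 0, 1), a = c(0, 0, 1, 1))
  ell <- home_base_2d(pts, confidence = 0.68)
  expect_equal(unname(ell$center), c(0.5, 0.5), tolerance = 1e-15)
  expect_equal(ell$eigenvalues, c(0.25, 0.25), tolerance = 1e-15)
  expect_equal(ell$psi, stats::qchisq(0.68, 2), tolerance = 1e-15)
  expect_equal(ell$semi_major, ell$semi_minor, tolerance = 1e-15)
  expect_equal(ell$semi_major, sqrt(stats::qchisq(0.68, 2) * 0.25),
               tolerance = 1e-15)
  # orthonormal eigenvectors
  expect_equal(crossprod(ell$eigenvectors), diag(2), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("isotropic Gaussian cloud yields near-equal semi-axes of sigma * sqrt(psi)", {
  withr::with_seed(101, {
    pts <- tibble::tibble(v = rnorm(5000, 0.5, 0.1), a = rnorm(5000, 0.5, 0.1))
  })
  ell <- home_base_2d(pts)
  expected <- 0.1 * sqrt(stats::qchisq(0.68, 2))
  expect_equal(ell$semi_major, expected, tolerance = 0.05)
  expect_equal(ell$semi_minor, expected, tolerance = 0.05)
})

test_that("degenerate geometry errors name the deficient axis", {
  pts <- tibble::tibble(v = c(0.1, 0.2, 0.3, 0.4), a = rep(0.5, 4))
  expect_error(home_base_2d(pts), "arousal")
  same <- tibble::tibble(v = rep(0.5, 5), a = rep(0.5, 5))
  expect_error(home_base_2d(same), "Degenerate")
})

test_that("membership uses the quadratic form with an inclusive boundary", {
  ell <- manual_ellipse(c(0.5, 0.5), A = 0.2, B = 0.1, theta = pi / 7)
  e1 <- ell$eigenvectors[, 1]
  expect_true(ellipse_contains(ell, 0.5, 0.5))
  on_boundary <- ell$center + ell$semi_major * e1
  expect_true(ellipse_contains(ell, on_boundary[1], on_boundary[2]))
  outside <- ell$center + 2 * ell$semi_major * e1
  expect_false(ellipse_contains(ell, outside[1], outside[2]))
})

test_that("perimeter distance has the circle closed form and axis-aligned values", {
  circ <- unit_circle_ellipse()
  expect_equal(perimeter_distance(circ, 2, 0), 1.0, tolerance = 1e-12)
  expect_equal(perimeter_distance(circ, 0, -3), 2.0, tolerance = 1e-12)
  expect_equal(perimeter_distance(circ, 0.5, 0), 0)

  ell <- manual_ellipse(c(0, 0), A = 2, B = 1)
  expect_equal(perimeter_distance(ell, 0, 3), 2.0, tolerance = 1e-12)
  expect_equal(perimeter_distance(ell, -4, 0), 2.0, tolerance = 1e-12)
  # circular limit: radial equals |p - c| - r for random points
  withr::with_seed(5, {
    p <- matrix(rnorm(40, 0, 2), ncol = 2)
  })
  d <- perimeter_distance(circ, p[, 1], p[, 2])
  expect_equal(d, pmax(0, sqrt(p[, 1]^2 + p[, 2]^2) - 1), tolerance = 1e-12)
})

test_that("radial distance matches the dense ray-sampling oracle on rotated ellipses", {
  withr::with_seed(23, {
    for (rep in 1:5) {
      ell <- manual_ellipse(runif(2), A = runif(1, 0.2, 0.5),
                            B = runif(1, 0.05, 0.2), theta = runif(1, 0, pi))
      pts <- matrix(ell$center + rnorm(20, 0, 1), ncol = 2, byrow = FALSE)
      for (i in seq_len(nrow(pts))) {
        expect_equal(
          perimeter_distance(ell, pts[i, 1], pts[i, 2]),
          oracle_radial_distance(ell, pts[i, ]),
          tolerance = 1e-6
        )
      }
    }
  })
})

test_that("nearest-point distance agrees with radial on axes and is never larger", {
  ell <- manual_ellipse(c(0, 0), A = 2, B = 1, theta = 0.4)
  withr::with_seed(29, {
    p <- matrix(rnorm(60, 0, 3), ncol = 2)
  })
  rad <- perimeter_distance(ell, p[, 1], p[, 2], method = "radial")
  near <- perimeter_distance(ell, p[, 1], p[, 2], method = "nearest")
  expect_true(all(near <= rad + 1e-9))
  circ <- unit_circle_ellipse()
  expect_equal(perimeter_distance(circ, 2, 2, method = "nearest"),
               sqrt(8) - 1, tolerance = 1e-8)
})

test_that("ellipse fitting is affine-consistent (translation and scaling)", {
  withr::with_seed(31, {
    pts <- tibble::tibble(v = rnorm(400, 0.5, 0.08), a = rnorm(400, 0.4, 0.03))
  })
  base <- home_base_2d(pts)
  shifted <- home_base_2d(dplyr::mutate(pts, v = v + 0.1, a = a - 0.05))
  expect_equal(unname(shifted$center), unname(base$center) + c(0.1, -0.05),
               tolerance = 1e-12)
  expect_equal(shifted$semi_major, base$semi_major, tolerance = 1e-12)
  scaled <- home_base_2d(dplyr::mutate(pts, v = 2 * v, a = 2 * a))
  expect_equal(scaled$semi_major, 2 * base$semi_major, tolerance = 1e-12)
  expect_equal(scaled$semi_minor, 2 * base$semi_minor, tolerance = 1e-12)
})

test_that("tidy and glance expose the ellipse export layout", {
  pts <- tibble::tibble(v = c(0, 1, 0, 1), a = c(0, 0.2, 1, 0.9))
  ell <- home_base_2d(pts)
  td <- tidy(ell)
  expect_named(td, c("cv", "ca", "semi_major", "semi_minor", "theta", "psi",
                     "confidence"))
  gl <- glance(ell)
  expect_equal(gl$area, pi * ell$semi_major * ell$semi_minor)
})
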