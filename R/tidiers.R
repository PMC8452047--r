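#' Tidy a 1-D home-base band
#'
#' @param x A `ued_band`.
#' @param ... Unused.
#' @return A one-row tibble with `mean`, `lower`, `upper`, `half_width`,
#'   `confidence`, `n`.
#' @export
tidy.ued_band <- function(x, ...) {
  tibble::tibble(mean = x$mean, lower = x$lower, upper = x$upper,
                 half_width = x$half_width, confidence = x$confidence,
                 n = x$n)
}

#' @rdname tidy.ued_band
#' @export
glance.ued_band <- function(x, ...) {
  tibble::tibble(n = x$n, variance = x$variance, t_crit = x$t_crit,
                 confidence = x$confidence)
}

#' Tidy a home-base ellipse
#'
#' @param x A `home_base_ellipse`.
#' @param ... Unused.
#' @return A one-row tibble with center coordinates, semi-axes, orientation,
#'   chi-square scale and coverage (the ellipse-export layout
#'   `cv,ca,semi_major,semi_minor,theta,psi,confidence`).
#' @export
tidy.home_base_ellipse <- function(x, ...) {
  tibble::tibble(
    cv = unname(x$center[1]), ca = unname(x$center[2]),
    semi_major = x$semi_major, semi_minor = x$semi_minor,
    theta = x$theta, psi = x$psi, confidence = x$confidence
  )
}

#' @rdname tidy.home_base_ellipse
#' @export
glance.home_base_ellipse <- function(x, ...) {
  tibble::tibble(
    n = x$n, lambda1 = x$eigenvalues[1], lambda2 = x$eigenvalues[2],
    area = pi * x$semi_major * x$semi_minor, confidence = x$confidence
  )
}

#' Tidy a trend curve
#'
#' @param x A `ued_trend`.
#' @param ... Unused.
#' @return The fitted curve on a 1001-point grid (`t`, `fitted`).
#' @export
tidy.ued_trend <- function(x, ...) {
  evaluate_trend(x)
}

#' @rdname tidy.ued_trend
#' @export
glance.ued_trend <- function(x, ...) {
  tibble::tibble(n = x$n, k = x$k, sp = unname(x$sp),
                 residual_scale = x$residual_scale)
}
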