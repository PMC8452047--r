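#' Speaker pairs eligible for discordance analysis
#'
#' Speakers qualify when they have at least one token in the first
#' `edge_fraction` and at least one in the last `edge_fraction` of the movie
#' (on movie-global normalized time), so paired speakers span approximately
#' the same narrative length. Returns all unordered pairs of qualifying
#' speakers per movie.
#'
#' @param words A word table from [build_narratives()] (needs `movie_id`,
#'   `speaker`, `t`).
#' @param edge_fraction Fraction of narrative time defining the edges
#'   (default 0.10).
#' @return A tibble with columns `movie_id`, `speaker_a`, `speaker_b`
#'   (`speaker_a < speaker_b`).
#' @export
eligible_pairs <- function(words, edge_fraction = 0.10) {
  stopifnot(edge_fraction > 0, edge_fraction < 0.5)
  qual <- words |>
    dplyr::group_by(.data$movie_id, .data$speaker) |>
    dplyr::summarise(
      early = any(.data$t < edge_fraction),
      late = any(.data$t > 1 - edge_fraction),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$early & .data$late)
  qual |>
    dplyr::group_by(.data$movie_id) |>
    dplyr::group_modify(function(df, key) {
      sp <- sort(df$speaker)
      if (length(sp) < 2L) {
        return(tibble::tibble(speaker_a = character(), speaker_b = character()))
      }
      cmb <- utils::combn(sp, 2L)
      tibble::tibble(speaker_a = cmb[1, ], speaker_b = cmb[2, ])
    }) |>
    dplyr::ungroup()
}

# per-speaker mean (v, a) on a normalized-time bin grid, with interior gaps
# linearly interpolated; leading/trailing empty bins stay NA.
bin_trajectory <- function(traj, n_bins) {
  bin <- pmin(pmax(ceiling(traj$t * n_bins), 1L), n_bins)
  agg <- tibble::tibble(bin = bin, v = traj$v, a = traj$a) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(v = mean(.data$v), a = mean(.data$a), n = dplyr::n(),
                     .groups = "drop")
  out <- tibble::tibble(bin = seq_len(n_bins)) |>
    dplyr::left_join(agg, by = "bin") |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L))
  occ <- which(!is.na(out$v))
  if (length(occ) == 0L) abort("Trajectory occupies no time bins.")
  if (length(occ) >= 2L) {
    rng <- occ[1]:occ[length(occ)]
    out$v[rng] <- stats::approx(occ, out$v[occ], xout = rng)$y
    out$a[rng] <- stats::approx(occ, out$a[occ], xout = rng)$y
  }
  out
}

#' Pairwise discordance series
#'
#' Discordance between two speakers at matched narrative time: each speaker's
#' trajectory is averaged within `n_bins` equal bins of movie-global
#' normalized time (bin `k` covers `((k-1)/G, k/G]`, centers at
#' `(k - 0.5)/G`); interior empty bins are filled by linear interpolation
#' between neighboring occupied bins, while bins before a speaker's first or
#' after their last occupied bin stay missing. The per-bin discordance is the
#' Euclidean distance between the two binned (v, a) positions; it is
#' symmetric in the pair.
#'
#' @param traj_a,traj_b Trajectory tibbles (columns `t`, `v`, `a`) on the
#'   same movie-global time axis.
#' @param n_bins Number of time bins (default 100).
#' @return A tibble with columns `bin`, `t` (bin center), `distance`
#'   (`NA` where either speaker is missing), `v_a`, `a_a`, `v_b`, `a_b`,
#'   `n_a`, `n_b` (per-bin support counts).
#' @export
discordance_series <- function(traj_a, traj_b, n_bins = 100L) {
  n_bins <- check_window(n_bins)
  ba <- bin_trajectory(traj_a, n_bins)
  bb <- bin_trajectory(traj_b, n_bins)
  tibble::tibble(
    bin = ba$bin,
    t = (ba$bin - 0.5) / n_bins,
    distance = sqrt((ba$v - bb$v)^2 + (ba$a - bb$a)^2),
    v_a = ba$v, a_a = ba$a, v_b = bb$v, a_b = bb$a,
    n_a = ba$n, n_b = bb$n
  )
}

#' Rolling emotion-word-density arc
#'
#' A trailing `window`-word rolling percentage of category-flagged tokens
#' over ALL of a speaker's tokens (the denominator includes words absent from
#' the lexicon, consistent with [emotion_word_density()]), timestamped at the
#' window's last token's normalized time.
#'
#' @param words One speaker's word table rows (needs `token`, `t`).
#' @param lexicon An `emotion_lexicon`.
#' @param category A single category from [EMOTION_CATEGORIES].
#' @param window Rolling window in tokens (default 30).
#' @return A tibble with columns `t`, `density` (percent); zero rows plus a
#'   warning when the speaker has fewer tokens than `window`.
#' @export
density_arc <- function(words, lexicon, category, window = 30L) {
  stopifnot(inherits(lexicon, "emotion_lexicon"), length(category) == 1L)
  if (!category %in% EMOTION_CATEGORIES) {
    abort(sprintf("Unknown emotion category '%s'.", category))
  }
  window <- check_window(window)
  n <- nrow(words)
  if (n < window) {
    warn(sprintf("Fewer tokens (%d) than the density window (%d); empty arc.",
                 n, window))
    return(tibble::tibble(t = double(), density = double()))
  }
  vocab <- lexicon$word[lexicon$emotion == category]
  flag <- as.numeric(tolower(words$token) %in% vocab)
  tibble::tibble(
    t = words$t[window:n],
    density = 100 * zoo::rollmean(flag, window, align = "left")
  )
}

#' Fit a smooth trend curve
#'
#' Penalized cubic regression spline (a Generalized Additive Model) of `y` on
#' normalized time `x`, with the smoothing parameter chosen by generalized
#' cross-validation unless `sp` is supplied. Used to describe the shape of
#' density or discordance arcs and to locate their extrema.
#'
#' @param x Numeric vector of normalized times; needs at least 20 distinct
#'   points spanning at least half of \[0, 1\].
#' @param y Numeric response of the same length.
#' @param k Spline basis dimension (default 10).
#' @param sp Optional fixed smoothing parameter.
#' @return A `ued_trend` object wrapping the fitted [mgcv::gam()] model.
#' @export
fit_trend <- function(x, y, k = 10L, sp = NULL) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(unique(x)) < 2L) abort("Degenerate `x`: all values equal.")
  if (length(x) < 20L) abort("At least 20 points are required to fit a trend.")
  if (diff(range(x)) < 0.5) {
    abort("`x` must span at least half of the [0, 1] interval.")
  }
  k <- min(k, length(unique(x)))
  fit <- mgcv::gam(y ~ s(x, k = k, bs = "cr"), method = "GCV.Cp", sp = sp,
                   data = data.frame(x = x, y = y))
  structure(
    list(fit = fit, sp = fit$sp, k = k, n = length(x),
         residual_scale = sqrt(mean(stats::residuals(fit)^2))),
    class = "ued_trend"
  )
}

#' Evaluate a trend curve
#'
#' @param trend A `ued_trend` from [fit_trend()].
#' @param t Evaluation grid on \[0, 1\] (default 1001 equispaced points).
#' @return A tibble with columns `t`, `fitted`.
#' @export
evaluate_trend <- function(trend, t = seq(0, 1, length.out = 1001L)) {
  stopifnot(inherits(trend, "ued_trend"))
  tibble::tibble(
    t = t,
    fitted = as.numeric(stats::predict(trend$fit, newdata = data.frame(x = t)))
  )
}

#' @export
print.ued_trend <- function(x, ...) {
  cat(sprintf("Penalized-spline trend: n %d, k %d, sp %.4g, residual scale %.4g\n",
              x$n, x$k, x$sp, x$residual_scale))
  invisible(x)
}

#' Locate a trend extremum
#'
#' Argmax or argmin of the fitted trend over a 1001-point grid on \[0, 1\].
#' Extrema landing on the grid boundary are flagged `boundary = TRUE`; a
#' curve whose fitted range is below `1e-9` is flagged as having no distinct
#' extremum.
#'
#' @param trend A `ued_trend`.
#' @param kind `"max"` or `"min"`.
#' @return A one-row tibble with `t`, `value`, `boundary`, `distinct`.
#' @export
locate_extremum <- function(trend, kind = c("max", "min")) {
  kind <- match.arg(kind)
  ev <- evaluate_trend(trend)
  distinct <- diff(range(ev$fitted)) >= 1e-9
  i <- if (kind == "max") which.max(ev$fitted) else which.min(ev$fitted)
  tibble::tibble(
    t = ev$t[i],
    value = ev$fitted[i],
    boundary = i == 1L || i == nrow(ev),
    distinct = distinct
  )
}

#' Pearson correlation between aligned series
#'
#' Standard Pearson correlation over aligned, non-missing positions of two
#' series on a common grid (e.g. a discordance series and a density arc
#' binned on the same narrative-time grid).
#'
#' @param x,y Numeric vectors of equal length.
#' @return A single correlation value; `NA` (with a warning) when fewer than
#'   3 complete pairs remain or either series is constant.
#' @export
correlate_series <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) {
    warn("Fewer than 3 aligned points; correlation not available.")
    return(NA_real_)
  }
  if (pop_sd(x) == 0 || pop_sd(y) == 0) {
    warn("Constant series; correlation not available.")
    return(NA_real_)
  }
  stats::cor(x, y)
}

#' Permutation check for a time trend
#'
#' Descriptive alternative to formal mixed-model inference: the observed
#' linear slope of `y` on `x` is compared with slopes under random
#' permutation of `y`, giving a two-sided permutation p-value for "any
#' systematic time trend".
#'
#' @param x,y Numeric vectors.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed.
#' @return A one-row tibble with `slope`, `p_value`, `n_perm`.
#' @export
trend_permutation <- function(x, y, n_perm = 999L, seed = 1L) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  slope <- function(yy) stats::cov(x, yy) / stats::var(x)
  obs <- slope(y)
  perm <- withr::with_seed(seed, {
    replicate(n_perm, slope(sample(y)))
  })
  tibble::tibble(
    slope = obs,
    p_value = (1 + sum(abs(perm) >= abs(obs))) / (n_perm + 1),
    n_perm = n_perm
  )
}
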