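# Shared numeric helpers. The variance convention throughout the package is
# the population (divide-by-N) form; home-base widths and variability both
# depend on it, so it lives in one place.

pop_var <- function(x) {
  n <- length(x)
  if (n < 1L) return(NA_real_)
  m <- mean(x)
  sum((x - m)^2) / n
}

pop_sd <- function(x) sqrt(pop_var(x))

#' Normalized narrative time
#'
#' Maps a 0-based word position onto (0, 1) as `(position + 0.5) / total`,
#' so the first word of a narrative sits at `0.5 / total` rather than 0 and a
#' single-word narrative lands at 0.5. Positions are on the movie-global
#' token axis by default, which makes different speakers' trajectories
#' directly comparable.
#'
#' @param position Integer vector of 0-based word positions.
#' @param total Total token count of the axis (must be positive).
#' @return Numeric vector in (0, 1).
#' @examples
#' normalized_time(0L, 10L)  # 0.05
#' normalized_time(9L, 10L)  # 0.95
#' @export
normalized_time <- function(position, total) {
  if (length(total) != 1L || is.na(total) || total <= 0) {
    abort("`total` must be a single positive count.")
  }
  if (any(position < 0 | position >= total, na.rm = TRUE)) {
    abort("`position` must satisfy 0 <= position < total.")
  }
  (position + 0.5) / total
}

# stopifnot-style scalar checks with readable messages
check_window <- function(window) {
  if (length(window) != 1L || is.na(window) || window < 1) {
    abort("`window` must be a single integer >= 1.")
  }
  as.integer(window)
}

check_confidence <- function(confidence) {
  if (length(confidence) != 1L || is.na(confidence) ||
      confidence <= 0 || confidence >= 1) {
    abort("`confidence` must be a single value strictly between 0 and 1.")
  }
  confidence
}
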