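#' Emotion word density
#'
#' Percentage of a speaker's tokens associated with an emotion category. The
#' denominator is the full token count, including words absent from the
#' lexicon.
#'
#' @param tokens Character vector of a speaker's tokens, in order.
#' @param lexicon An `emotion_lexicon`.
#' @param category One of [EMOTION_CATEGORIES], or a vector of them.
#' @return A tibble with columns `category`, `density` (percent in
#'   \[0, 100\]); densities are `NA` for an empty token vector.
#' @examples
#' \dontrun{
#' emotion_word_density(tokens, emolex, c("positive", "negative"))
#' }
#' @export
emotion_word_density <- function(tokens, lexicon, category = EMOTION_CATEGORIES) {
  stopifnot(inherits(lexicon, "emotion_lexicon"))
  bad <- setdiff(category, EMOTION_CATEGORIES)
  if (length(bad) > 0L) {
    abort(sprintf("Unknown emotion category '%s'.", bad[1]))
  }
  n <- length(tokens)
  dens <- purrr::map_dbl(category, function(cat) {
    if (n == 0L) return(NA_real_)
    vocab <- lexicon$word[lexicon$emotion == cat]
    100 * sum(tolower(tokens) %in% vocab) / n
  })
  tibble::tibble(category = category, density = dens)
}

#' Dimensional emotion density (mean valence and arousal)
#'
#' The valence and arousal scores act as weights on word occurrences, so the
#' dimensional density is simply the mean valence and mean arousal over the
#' lexicon-covered words.
#'
#' @param scored A scored-word tibble from [score_words()] (needs `valence`,
#'   `arousal`).
#' @return A one-row tibble with `mean_valence`, `mean_arousal`, `n_vad_words`
#'   (`NA` means when there are no covered words).
#' @export
dimensional_density <- function(scored) {
  n <- nrow(scored)
  tibble::tibble(
    mean_valence = if (n > 0L) mean(scored$valence) else NA_real_,
    mean_arousal = if (n > 0L) mean(scored$arousal) else NA_real_,
    n_vad_words = n
  )
}

#' Emotional variability
#'
#' Variability of an emotional-state series is its standard deviation with
#' the population (divide-by-N) denominator. In two dimensions it is the
#' average of the valence and arousal SDs.
#'
#' @param series Numeric vector.
#' @return A single non-negative value (`NA` for an empty series).
#' @examples
#' emo_variability(c(0.4, 0.6))  # 0.1
#' @export
emo_variability <- function(series) {
  series <- series[!is.na(series)]
  if (length(series) < 1L) return(NA_real_)
  pop_sd(series)
}

#' @rdname emo_variability
#' @param traj A trajectory tibble with columns `v`, `a`.
#' @export
emo_variability_2d <- function(traj) {
  (emo_variability(traj$v) + emo_variability(traj$a)) / 2
}

#' Detect displacements from the home base
#'
#' A displacement is a completed excursion of the trajectory outside the
#' home-base ellipse: a maximal run of consecutive outside points bounded by
#' inside points on both sides. For each run the peak is the outside point
#' with the largest perimeter distance (earliest index on ties);
#' `rise_words = peak_index - exit_index` (exit = last inside point before
#' the run) and `recovery_words = return_index - peak_index` (return = first
#' inside point after), both counted in VAD words and both at least 1. Rise
#' and recovery rates divide the peak distance by those word counts. Runs
#' touching either end of the trajectory are returned with `truncated = TRUE`
#' (their missing exit/return fields are `NA`) and are excluded from profile
#' averages.
#'
#' @param traj A single speaker's trajectory tibble with columns `index`,
#'   `v`, `a` (consecutive points one VAD word apart).
#' @param home A `home_base_ellipse` for the same speaker.
#' @return A tibble with one row per displacement: `exit_index`,
#'   `first_out_index`, `peak_index`, `return_index`, `length`,
#'   `peak_distance`, `rise_words`, `recovery_words`, `rise_rate`,
#'   `recovery_rate`, `truncated`. Zero rows when the trajectory never leaves
#'   the home base.
#' @export
detect_displacements <- function(traj, home) {
  stopifnot(inherits(home, "home_base_ellipse"))
  empty <- tibble::tibble(
    exit_index = integer(), first_out_index = integer(),
    peak_index = integer(), return_index = integer(),
    length = integer(), peak_distance = double(),
    rise_words = integer(), recovery_words = integer(),
    rise_rate = double(), recovery_rate = double(), truncated = logical()
  )
  n <- nrow(traj)
  if (n == 0L) return(empty)
  inside <- ellipse_contains(home, traj$v, traj$a)
  dist <- perimeter_distance(home, traj$v, traj$a)
  runs <- rle(!inside)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  out_runs <- which(runs$values)
  if (length(out_runs) == 0L) return(empty)
  purrr::map_dfr(out_runs, function(r) {
    s <- starts[r]; e <- ends[r] # row positions of the outside run
    trunc_start <- s == 1L
    trunc_end <- e == n
    d <- dist[s:e]
    peak_row <- s - 1L + which.max(d) # which.max takes the earliest tie
    exit_row <- if (trunc_start) NA_integer_ else s - 1L
    return_row <- if (trunc_end) NA_integer_ else e + 1L
    rise <- if (trunc_start) NA_integer_ else traj$index[peak_row] - traj$index[exit_row]
    reco <- if (trunc_end) NA_integer_ else traj$index[return_row] - traj$index[peak_row]
    tibble::tibble(
      exit_index = if (trunc_start) NA_integer_ else traj$index[exit_row],
      first_out_index = traj$index[s],
      peak_index = traj$index[peak_row],
      return_index = if (trunc_end) NA_integer_ else traj$index[return_row],
      length = e - s + 1L,
      peak_distance = dist[peak_row],
      rise_words = as.integer(rise),
      recovery_words = as.integer(reco),
      rise_rate = dist[peak_row] / rise,
      recovery_rate = dist[peak_row] / reco,
      truncated = trunc_start || trunc_end
    )
  })
}

#' Per-speaker UED profile
#'
#' Assembles all utterance-emotion-dynamics metrics for one speaker:
#' categorical emotion word densities, mean valence/arousal, 1-D home-base
#' bands, the 2-D home-base ellipse, variability, and displacement summaries.
#' Home-base and variability statistics are computed on the rolling
#' trajectory by default (`stat_basis = "trajectory"`); set
#' `stat_basis = "raw"` to use the raw word scores instead. Displacement
#' averages cover non-truncated displacements only and are reported as `NA`
#' when fewer than `min_displacements` are available. A trajectory with
#' degenerate geometry (e.g. zero variance) yields zero displacements and
#' `NA` ellipse fields rather than an error.
#'
#' @param words One speaker's rows of a word table from [build_narratives()].
#' @param vad A `vad_lexicon`.
#' @param emolex An `emotion_lexicon`, or `NULL` to skip categorical
#'   densities.
#' @param window Rolling window (default 10).
#' @param confidence Home-base coverage (default 0.68).
#' @param min_displacements Minimum usable displacements for reporting rate
#'   and distance averages (default 5).
#' @param stat_basis `"trajectory"` (default) or `"raw"`.
#' @return A one-row tibble (see Details for columns); `displacements` holds
#'   the full displacement table as a list-column.
#' @export
summarize_profile <- function(words, vad, emolex = NULL, window = 10L,
                              confidence = 0.68, min_displacements = 5L,
                              stat_basis = c("trajectory", "raw")) {
  stat_basis <- match.arg(stat_basis)
  window <- check_window(window)
  stopifnot(length(unique(words$speaker)) <= 1L)
  scored <- score_words(words, vad)
  dd <- dimensional_density(scored)
  base <- tibble::tibble(
    movie_id = words$movie_id[1] %||% NA_character_,
    speaker = words$speaker[1] %||% NA_character_,
    n_turns = length(unique(words$turn_index)),
    n_tokens = nrow(words)
  )
  dens <- if (!is.null(emolex)) {
    emotion_word_density(words$token, emolex) |>
      dplyr::mutate(category = paste0("density_", .data$category)) |>
      tidyr::pivot_wider(names_from = "category", values_from = "density")
  } else {
    NULL
  }
  traj <- rolling_trajectory(scored, window)
  basis <- if (stat_basis == "trajectory") {
    tibble::tibble(v = traj$v, a = traj$a)
  } else {
    tibble::tibble(v = scored$valence, a = scored$arousal)
  }
  nb <- nrow(basis)
  var_v <- if (nb >= 1L) emo_variability(basis$v) else NA_real_
  var_a <- if (nb >= 1L) emo_variability(basis$a) else NA_real_
  band_v <- if (nb >= 2L) home_base_1d(basis$v, confidence) else NULL
  band_a <- if (nb >= 2L) home_base_1d(basis$a, confidence) else NULL
  ell <- NULL
  if (nb >= 3L) {
    ell <- tryCatch(home_base_2d(basis, confidence), error = function(e) NULL)
  }
  disp <- if (!is.null(ell) && nrow(traj) > 0L) {
    detect_displacements(traj, ell)
  } else {
    detect_displacements(tibble::tibble(index = integer(), v = double(), a = double()),
                         structure(list(center = c(v = 0.5, a = 0.5),
                                        eigenvalues = c(1, 1),
                                        eigenvectors = diag(2), psi = 1,
                                        semi_major = 1, semi_minor = 1,
                                        theta = 0, confidence = confidence, n = 0L),
                                   class = "home_base_ellipse"))
  }
  usable <- disp[!disp$truncated, ]
  n_us <- nrow(usable)
  avail <- n_us >= min_displacements
  out <- dplyr::bind_cols(
    base,
    tibble::tibble(n_vad_words = dd$n_vad_words,
                   mean_valence = dd$mean_valence,
                   mean_arousal = dd$mean_arousal),
    if (!is.null(dens)) dens,
    tibble::tibble(
      hb_v_lower = band_v$lower %||% NA_real_,
      hb_v_upper = band_v$upper %||% NA_real_,
      hb_a_lower = band_a$lower %||% NA_real_,
      hb_a_upper = band_a$upper %||% NA_real_,
      hb_center_v = if (!is.null(ell)) ell$center[1] else NA_real_,
      hb_center_a = if (!is.null(ell)) ell$center[2] else NA_real_,
      hb_semi_major = if (!is.null(ell)) ell$semi_major else NA_real_,
      hb_semi_minor = if (!is.null(ell)) ell$semi_minor else NA_real_,
      hb_theta = if (!is.null(ell)) ell$theta else NA_real_,
      variability_v = var_v,
      variability_a = var_a,
      variability_2d = (var_v + var_a) / 2,
      displacement_count = sum(!disp$truncated),
      n_truncated_displacements = sum(disp$truncated),
      n_usable_displacements = n_us,
      mean_displacement_length = if (avail) mean(usable$length) else NA_real_,
      mean_peak_distance = if (avail) mean(usable$peak_distance) else NA_real_,
      mean_rise_rate = if (avail) mean(usable$rise_rate) else NA_real_,
      mean_recovery_rate = if (avail) mean(usable$recovery_rate) else NA_real_
    )
  )
  out$displacements <- list(disp)
  out
}

#' UED profiles for every main character
#'
#' Full pipeline from a turns table to one profile row per main character:
#' select speakers with at least `min_turns` turns, build narratives, and
#' summarize each.
#'
#' @param turns A turns tibble from [read_transcript()].
#' @param vad A `vad_lexicon`.
#' @param emolex An `emotion_lexicon` (optional).
#' @param min_turns Main-character threshold (default 50).
#' @param lemmatizer Passed to [tokenize_text()].
#' @inheritParams summarize_profile
#' @return A tibble with one row per (movie, main character).
#' @export
ued_profiles <- function(turns, vad, emolex = NULL, min_turns = 50L,
                         window = 10L, confidence = 0.68,
                         min_displacements = 5L,
                         stat_basis = c("trajectory", "raw"),
                         lemmatizer = NULL) {
  stat_basis <- match.arg(stat_basis)
  mains <- select_main_characters(turns, min_turns)
  if (nrow(mains) == 0L) {
    warn("No speaker meets the main-character turn threshold; empty profile table.")
    return(tibble::tibble(movie_id = character(), speaker = character()))
  }
  words <- build_narratives(turns, mains, lemmatizer)
  words |>
    dplyr::group_by(.data$movie_id, .data$speaker) |>
    dplyr::group_split() |>
    purrr::map_dfr(summarize_profile, vad = vad, emolex = emolex,
                   window = window, confidence = confidence,
                   min_displacements = min_displacements,
                   stat_basis = stat_basis) |>
    dplyr::left_join(mains, by = c("movie_id", "speaker"),
                     suffix = c("", ".sel")) |>
    dplyr::select(-dplyr::any_of("n_turns.sel"))
}
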