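#' Score narrative words against a dimensional lexicon
#'
#' Order-preserving filter of a word table to the lexicon-covered words, with
#' valence and arousal attached. Only these "VAD words" contribute to
#' emotional trajectories; `vad_ordinal` numbers them 0-based within each
#' speaker.
#'
#' @param words A word table from [build_narratives()] (or any tibble with
#'   `movie_id`, `speaker`, `token`, `global_pos`, `t`).
#' @param lexicon A `vad_lexicon`.
#' @return The covered rows with added columns `valence`, `arousal`,
#'   `vad_ordinal`.
#' @export
score_words <- function(words, lexicon) {
  stopifnot(inherits(lexicon, "vad_lexicon"))
  sc <- get_scores(lexicon, words$token)
  words |>
    dplyr::mutate(valence = sc$valence, arousal = sc$arousal) |>
    dplyr::filter(!is.na(.data$valence)) |>
    dplyr::group_by(.data$movie_id, .data$speaker) |>
    dplyr::mutate(vad_ordinal = seq_len(dplyr::n()) - 1L) |>
    dplyr::ungroup()
}

#' Rolling valence-arousal trajectory
#'
#' Applies a trailing rolling mean of `window` words to each speaker's
#' scored-word sequence. Point `k` (0-based) averages scored words
#' `k .. k + window - 1` and is anchored at the position (and normalized
#' time) of the window's last word, so the trajectory is causal: it uses only
#' words already uttered. Only full windows are emitted; a speaker with fewer
#' scored words than `window` yields no points and a "narrative too short"
#' warning.
#'
#' @param scored Output of [score_words()].
#' @param window Rolling window length in words (default 10).
#' @return A tibble with columns `movie_id`, `speaker`, `index` (0-based
#'   trajectory point index = VAD ordinal of the window's first word),
#'   `global_pos`, `t`, `v`, `a`; `v` and `a` are the window means.
#' @export
rolling_trajectory <- function(scored, window = 10L) {
  window <- check_window(window)
  scored |>
    dplyr::group_by(.data$movie_id, .data$speaker) |>
    dplyr::group_modify(function(df, key) {
      n <- nrow(df)
      if (n < window) {
        warn(sprintf(
          "Narrative too short for speaker '%s' (%d VAD words < window %d); empty trajectory.",
          key$speaker, n, window
        ))
        return(tibble::tibble(index = integer(), global_pos = integer(),
                              t = double(), v = double(), a = double()))
      }
      tibble::tibble(
        index = 0:(n - window),
        global_pos = df$global_pos[window:n],
        t = df$t[window:n],
        v = zoo::rollmean(df$valence, window, align = "left"),
        a = zoo::rollmean(df$arousal, window, align = "left")
      )
    }) |>
    dplyr::ungroup()
}
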